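test_that("ordered quantile transform matches normal quantiles and preserves ranks", {
  out <- orq_transform(c(10, 3, 7, 1, 5))
  expect_equal(out, c(1.2816, -0.5244, 0.5244, -1.2816, 0), tolerance = 1e-4)
  set.seed(1)
  x <- rnorm(50)
  expect_equal(cor(x, orq_transform(x), method = "spearman"), 1)
  expect_warning(z <- orq_transform(c(2, 2)), "constant")
  expect_equal(z, c(0, 0))
  expect_error(orq_transform(5), "two values")
  expect_error(orq_transform(c(1, Inf)), "finite")
})

test_that("repeated-measures ANOVA matches the aov error-strata oracle", {
  set.seed(42)
  d <- expand.grid(subject_id = paste0("s", 1:6),
                   treatment = c("NP", "FOS"),
                   timepoint_h = c(12, 24), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 10) + rep(rnorm(6, 0, 2), 4) +
    ifelse(d$treatment == "FOS", 3, 0)
  res <- rm_anova_two_way(d, response = "y")
  fit <- summary(stats::aov(y ~ treatment * factor(timepoint_h) +
                              Error(factor(subject_id) / (treatment * factor(timepoint_h))),
                            data = d))
  get_f <- function(stratum) fit[[stratum]][[1]][1, c("F value", "Pr(>F)")]
  oracle <- rbind(get_f("Error: factor(subject_id):treatment"),
                  get_f("Error: factor(subject_id):factor(timepoint_h)"),
                  get_f("Error: factor(subject_id):treatment:factor(timepoint_h)"))
  expect_equal(res$F, oracle[, 1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$p, oracle[, 2], tolerance = 1e-10, ignore_attr = TRUE)

  # ORQ pre-transform keeps the partition well-defined and rank-driven
  orq_res <- rm_anova_two_way(d, response = "y", orq = TRUE)
  expect_true(all(is.finite(orq_res$F)))
  expect_true(all(orq_res$p >= 0 & orq_res$p <= 1))

  d$y <- 5
  expect_error(rm_anova_two_way(d, response = "y"), "degenerate")
  expect_error(rm_anova_two_way(d[-1, ], response = "y"), "unbalanced")
})

test_that("additive simulated data give uniform interaction p-values", {
  pv <- vapply(1:60, function(s) {
    set.seed(s)
    d <- expand.grid(subject_id = paste0("s", 1:8),
                     treatment = c("NP", "FOS", "XOS"),
                     timepoint_h = c(12, 24, 36), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d)) + rep(rnorm(8, 0, 2), 9) +
      ifelse(d$treatment == "NP", 0, 2) + 0.1 * d$timepoint_h
    rm_anova_two_way(d, response = "y")$p[3]
  }, 0)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Dunnett with one treatment arm reduces to the pooled t-test", {
  set.seed(3)
  x <- rnorm(14)
  g <- rep(c("NP", "FOS"), each = 7)
  d <- dunnett_vs_control(x, g)
  tt <- t.test(x[g == "FOS"], x[g == "NP"], var.equal = TRUE)
  expect_equal(d$p_adj, tt$p.value, tolerance = 1e-12)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-12)
})

test_that("Dunnett adjusted p matches multivariate-t and multcomp oracles", {
  # fixed worked dataset: 3 treatment arms + control, 4 observations each
  y <- c(5.1, 4.8, 5.3, 5.0,   # NP
         6.0, 6.4, 5.8, 6.1,   # A
         5.2, 5.5, 5.0, 5.1,   # B
         7.2, 6.8, 7.0, 7.4)   # C
  g <- rep(c("NP", "A", "B", "C"), each = 4)
  d <- dunnett_vs_control(y, g)

  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  oracle <- vapply(d$t, function(ti) {
    set.seed(99)
    1 - as.numeric(mvtnorm::pmvt(lower = rep(-abs(ti), 3),
                                 upper = rep(abs(ti), 3), df = 12, corr = corr,
                                 algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                                maxpts = 2e6)))
  }, 0)
  expect_equal(d$p_adj, oracle, tolerance = 1e-3)

  df <- data.frame(y = y, g = factor(g, levels = c("NP", "A", "B", "C")))
  mc <- multcomp::glht(stats::aov(y ~ g, df),
                       linfct = multcomp::mcp(g = "Dunnett"))
  mp <- summary(mc, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(d$p_adj[match(c("A", "B", "C"), d$treatment)],
               as.numeric(mp), tolerance = 1e-3)

  expect_error(dunnett_vs_control(rep(1, 8), rep(c("NP", "A"), each = 4)),
               "variance")
})

test_that("phenotype labels obey the significance-and-direction rule", {
  p <- sim_params(seed = 1)
  co <- simulate_scfa(p)
  res <- assign_phenotypes(co$scfa)
  ph <- res$phenotypes
  # label/statistic consistency on every output row
  expect_true(all((ph$label == "R") ==
                    (ph$p_adj < 0.05 & ph$mean_delta_ab_mM > 0)))

  # overwhelming effect in one arm
  d <- expand.grid(subject_id = "s1", treatment = c("NP", "XOS"),
                   replicate = 1:2, timepoint_h = c(12, 24, 36, 48),
                   stringsAsFactors = FALSE)
  set.seed(8)
  d$acetate_mM <- ifelse(d$treatment == "XOS", 30, 10) + rnorm(nrow(d), 0, 1)
  d$butyrate_mM <- rnorm(nrow(d), 5, 1)
  strong <- assign_phenotypes(d)$phenotypes
  expect_identical(strong$label, "R")

  # exactly zero difference between arms -> NR (values vary over time only)
  d$acetate_mM <- c(10.2, 10.8, 9.9, 10.4)[match(d$timepoint_h, c(12, 24, 36, 48))]
  d$butyrate_mM <- c(5.1, 4.9, 5.2, 5.0)[match(d$timepoint_h, c(12, 24, 36, 48))]
  null <- assign_phenotypes(d)$phenotypes
  expect_identical(null$label, "NR")

  expect_error(assign_phenotypes(d[d$treatment != "NP", ]), "missing the NP")
})

test_that("raising a responder's acetate+butyrate never flips R to NR", {
  p <- sim_params(seed = 5, n_subjects = 6)
  co <- simulate_scfa(p)
  base <- assign_phenotypes(co$scfa)$phenotypes
  r <- base[base$label == "R", ][1, ]
  d <- co$scfa
  sel <- d$subject_id == r$subject_id & d$treatment == r$substrate
  for (bump in c(2, 10, 30)) {
    d2 <- d
    d2$acetate_mM[sel] <- d2$acetate_mM[sel] + bump
    ph2 <- assign_phenotypes(d2)$phenotypes
    expect_identical(ph2$label[ph2$subject_id == r$subject_id &
                                 ph2$substrate == r$substrate], "R")
  }
})

test_that("boxplot outlier scan flags by the 1.5 IQR rule", {
  res <- outlier_scan(c(1, 2, 3, 4, 100))
  expect_identical(res$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(res$extreme, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(outlier_scan(c(1, 2, 3, 4))$outlier))
  expect_false(any(outlier_scan(rep(7, 10))$outlier))
})

test_that("spearman matrix computes rank correlations with BH adjustment", {
  res <- spearman_matrix(data.frame(a = c(1, 2, 3)), data.frame(b = c(3, 1, 2)))
  expect_equal(res$rho, -0.5)
  x <- 1:10
  expect_equal(spearman_matrix(data.frame(x), data.frame(y = x^3))$rho, 1)
  expect_equal(spearman_matrix(data.frame(x), data.frame(y = rev(x)))$rho, -1)
  cons <- spearman_matrix(data.frame(x), data.frame(y = rep(1, 10)))
  expect_true(is.na(cons$rho))
  # BH applied across the full pair family
  set.seed(2)
  m <- spearman_matrix(as.data.frame(matrix(rnorm(30), 10)),
                       as.data.frame(matrix(rnorm(30), 10)))
  expect_equal(m$p_adj, p.adjust(m$p, "BH"))
})
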