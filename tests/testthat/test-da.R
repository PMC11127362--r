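test_that("median-of-ratios size factors match the worked example", {
  m <- matrix(c(2, 4, 4, 8, 6, 12), nrow = 3, byrow = TRUE)
  expect_equal(unname(size_factors(m)), c(0.7071, 1.4142), tolerance = 1e-4)
  expect_equal(unname(size_factors(cbind(c(5, 9, 2), c(5, 9, 2)))), c(1, 1))
  # scale equivariance: scaling one sample by c multiplies its factor by c
  # relative to the others (the geometric-mean reference rescales jointly)
  m2 <- m; m2[, 2] <- m2[, 2] * 10
  s1 <- size_factors(m); s2 <- size_factors(m2)
  expect_equal(s2[2] / s2[1], 10 * s1[2] / s1[1], tolerance = 1e-12)
  expect_warning(size_factors(matrix(c(0, 3, 5, 0), 2)), "positive")
})

test_that("size factors agree with the DESeq2 reference on random matrices", {
  set.seed(7)
  cts <- matrix(rnbinom(300 * 8, mu = 100, size = 5), 300, 8)
  expect_equal(unname(size_factors(cts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cts)),
               tolerance = 1e-10)
})

test_that("scaling one sample leaves fold-change estimates unchanged", {
  set.seed(10)
  cts <- matrix(rnbinom(200 * 12, mu = 50, size = 5), 200, 12,
                dimnames = list(paste0("g", 1:200), NULL))
  lab <- rep(c("NR", "R"), each = 6)
  a <- nb_wald_test(cts, lab, ref = "NR")
  cts2 <- cts; cts2[, 3] <- cts2[, 3] * 7
  b <- nb_wald_test(cts2, lab, ref = "NR")
  # invariance is exact for the quasi-Poisson limit and approximate under
  # re-estimated NB dispersion: bounded drift, no systematic shift
  expect_lt(max(abs(a$log2fc - b$log2fc), na.rm = TRUE), 0.1)
  expect_lt(median(abs(a$log2fc - b$log2fc), na.rm = TRUE), 0.01)
  # Wald z sign equals log2fc sign
  ok <- a$tested & abs(a$log2fc) > 1e-12
  expect_true(all(sign(a$wald_z[ok]) == sign(a$log2fc[ok])))
})

test_that("NB Wald test is calibrated under the null and detects planted FC", {
  set.seed(42)
  n <- 30; G <- 2000
  mu <- outer(rlnorm(G, log(50), 1), runif(n, 0.5, 2))
  cts <- matrix(rnbinom(G * n, mu = mu, size = 1 / 0.2), G, n,
                dimnames = list(paste0("g", 1:G), NULL))
  lab <- rep(c("NR", "R"), each = 15)
  da <- nb_wald_test(cts, lab, ref = "NR")
  expect_equal(mean(da$p[da$tested] < 0.05), 0.05, tolerance = 0.2)

  # exchangeability: permuted copies of the same group
  expect_lt(abs(median(da$log2fc[da$tested])), 0.1)
  expect_lt(median(abs(da$wald_z[da$tested])), 1)

  # power: planted log2FC = 2 in 50 genes
  idx <- 1:50
  mu2 <- mu; mu2[idx, lab == "R"] <- mu2[idx, lab == "R"] * 4
  cts2 <- matrix(rnbinom(G * n, mu = mu2, size = 1 / 0.2), G, n,
                 dimnames = list(paste0("g", 1:G), NULL))
  da2 <- nb_wald_test(cts2, lab, ref = "NR")
  expect_gte(mean(da2$q[idx] < 0.05, na.rm = TRUE), 0.9)
  expect_lt(abs(median(da2$log2fc[idx]) - 2), 0.3)

  # all-zero genes are flagged, low-mean genes filtered
  cts3 <- rbind(zero = 0L, cts[1:20, ])
  da3 <- nb_wald_test(cts3, lab, ref = "NR")
  expect_false(da3$tested[1])
  expect_true(is.na(da3$p[1]))
  expect_error(nb_wald_test(cts[, 1:4], rep(c("NR", "R"), 2)), "n >= 3")
})

test_that("chi-square goodness of fit matches hand arithmetic", {
  res <- chisq_gof(c(30, 6))
  expect_equal(res$chisq, 16)
  expect_equal(res$df, 1)
  expect_equal(res$p, 6.334e-5, tolerance = 1e-3)
  expect_equal(chisq_gof(c(18, 18))$chisq, 0)
  expect_equal(chisq_gof(c(18, 18))$p, 1)
  expect_equal(chisq_gof(c(10, 20, 30), c(1, 2, 3) / 6)$chisq, 0)
  expect_error(chisq_gof(c(30, 6), c(1, 0)), "positive")
})

test_that("wilcoxon rank-sum is exact for small untied samples", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # power at a 3-sigma shift
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    wilcoxon_rank_sum(rnorm(20), rnorm(20, 3))$p < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.99)
})

test_that("Holm and BH adjustments follow the step procedures", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "holm"), c(0.03, 0.04, 0.04))
  expect_equal(adjust_p(0.013, "holm"), 0.013)
  expect_equal(adjust_p(0.013, "BH"), 0.013)
  expect_equal(adjust_p(rep(0.02, 5), "BH"), rep(0.02, 5))
  set.seed(1)
  p <- runif(20)
  bh <- adjust_p(p, "BH")
  expect_true(all(bh <= 1))
  expect_true(all(diff(bh[order(p)]) >= -1e-15))
  expect_error(adjust_p(c(0.5, 1.2)), "0, 1")
})
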