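#' Analysis configuration for phenotyping
#'
#' @param alpha Significance level for responder calls (default 0.05).
#' @param adjust_method Multiplicity adjustment for diagnostic tables:
#'   `"holm"` or `"BH"`.
#' @param sidedness `"two"` (default) or `"greater"` for the Dunnett
#'   contrasts.
#' @param average_replicates Average duplicate fermentations before ANOVA
#'   (default TRUE); set FALSE to treat replicates as observations.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, adjust_method = c("holm", "BH"),
                            sidedness = c("two", "greater"),
                            average_replicates = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(alpha = alpha, adjust_method = match.arg(adjust_method),
              sidedness = match.arg(sidedness),
              average_replicates = isTRUE(average_replicates))
  class(cfg) <- "analysis_config"
  cfg
}

#' Ordered quantile (rank-based inverse normal) transform
#'
#' Maps values to normal quantiles at p = (rank - 0.5)/n using average ranks
#' for ties. Strictly rank-preserving; used to bring SCFA concentrations to
#' approximate normality before ANOVA-class models.
#'
#' @param values Numeric vector, n >= 2, finite.
#' @return Transformed vector of the same length.
#' @export
orq_transform <- function(values) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("constant input: all ranks tie, returning zeros")
    return(rep(0, length(values)))
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Two-way repeated-measures ANOVA (treatment x time, within-subject)
#'
#' Classical univariate within-subject partitioning: every effect is tested
#' against its interaction with subject. Replicates must be averaged first
#' (the grid must be balanced: one value per subject x treatment x time).
#' The interaction p-value lets the caller decide whether averaging over
#' timepoints is justified before phenotyping.
#'
#' @param data Data frame with columns `subject_id`, `treatment`,
#'   `timepoint_h` and the response named by `response`.
#' @param response Column name of the response (default the acetate+butyrate
#'   sum computed on the fly when `data` carries `acetate_mM`/`butyrate_mM`).
#' @param orq Apply the ordered quantile transform ([orq_transform()]) to the
#'   response before partitioning, to satisfy normality assumptions on
#'   skewed concentration data (default FALSE).
#' @return Tibble with one row per effect (`treatment`, `time`,
#'   `treatment:time`): degrees of freedom, sums of squares, F and p.
#' @export
rm_anova_two_way <- function(data, response = "ab_sum", orq = FALSE) {
  d <- as.data.frame(data)
  if (!response %in% names(d) && all(c("acetate_mM", "butyrate_mM") %in% names(d))) {
    d$ab_sum <- d$acetate_mM + d$butyrate_mM
    if ("replicate" %in% names(d)) {
      d <- stats::aggregate(ab_sum ~ subject_id + treatment + timepoint_h, d, mean)
    }
    response <- "ab_sum"
  }
  d$subject_id <- factor(d$subject_id)
  d$treatment <- factor(d$treatment)
  d$time <- factor(d$timepoint_h)
  tab <- table(d$subject_id, d$treatment, d$time)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    cells <- apply(bad, 1, function(i) paste(dimnames(tab)[[1]][i[1]],
                                             dimnames(tab)[[2]][i[2]],
                                             dimnames(tab)[[3]][i[3]], sep = "/"))
    stop("unbalanced subject x treatment x time grid; offending cells: ",
         paste(utils::head(cells, 5), collapse = ", "), call. = FALSE)
  }
  y <- d[[response]]
  if (stats::var(y) < .Machine$double.eps) {
    stop("degenerate variance: response is constant", call. = FALSE)
  }
  if (isTRUE(orq)) y <- orq_transform(y)
  ss <- function(x) sum(x^2)
  gm <- mean(y)
  mean_by <- function(...) stats::ave(y, ..., FUN = mean)
  m_s <- mean_by(d$subject_id); m_a <- mean_by(d$treatment); m_b <- mean_by(d$time)
  m_ab <- mean_by(d$treatment, d$time)
  m_sa <- mean_by(d$subject_id, d$treatment)
  m_sb <- mean_by(d$subject_id, d$time)
  ns <- nlevels(d$subject_id); na <- nlevels(d$treatment); nb <- nlevels(d$time)
  ss_a <- ss(m_a - gm); ss_b <- ss(m_b - gm)
  ss_ab <- ss(m_ab - m_a - m_b + gm)
  ss_sa <- ss(m_sa - m_s - m_a + gm)
  ss_sb <- ss(m_sb - m_s - m_b + gm)
  ss_sab <- ss(y - m_sa - m_sb - m_ab + m_s + m_a + m_b - gm)
  df <- list(a = na - 1, b = nb - 1, ab = (na - 1) * (nb - 1),
             sa = (ns - 1) * (na - 1), sb = (ns - 1) * (nb - 1),
             sab = (ns - 1) * (na - 1) * (nb - 1))
  eff <- function(name, ssn, dfn, sse, dfe) {
    f <- (ssn / dfn) / (sse / dfe)
    tibble::tibble(effect = name, df = dfn, df_error = dfe, ss = ssn,
                   ss_error = sse, F = f, p = stats::pf(f, dfn, dfe, lower.tail = FALSE))
  }
  rbind(eff("treatment", ss_a, df$a, ss_sa, df$sa),
        eff("time", ss_b, df$b, ss_sb, df$sb),
        eff("treatment:time", ss_ab, df$ab, ss_sab, df$sab))
}

# Two-sided Dunnett tail probability for a balanced design (k treatment
# arms of size n against a control of size n0): P(max_i |T_i| > t) where
# T_i = (Xbar_i - Xbar_0) / (sigma_hat sqrt(1/n + 1/n0)). Conditioning on
# the control-arm mean (standard normal z) and the pooled-SD ratio
# u = sigma_hat/sigma (scaled chi with nu df) factorizes the treatment
# arms, leaving a smooth 2-D integral evaluated by nested adaptive
# quadrature to ~1e-9.
dunnett_balanced_grid <- function(nu, n_z = 48, n_v = 48) {
  gz <- pracma::gaussLegendre(n_z, -8, 8)
  gv <- pracma::gaussLegendre(n_v, 0, 1)
  # map the pooled-SD ratio through its own quantile function so the
  # v-integral runs over (0, 1) with unit weight
  list(z = gz$x, wz = gz$w * stats::dnorm(gz$x),
       u = sqrt(stats::qchisq(gv$x, nu) / nu), wv = gv$w)
}

dunnett_p_balanced <- function(tval, k, n, n0, grid) {
  if (!is.finite(tval)) return(if (tval > 0) 0 else 1)
  tval <- abs(tval)
  half <- tval * grid$u * sqrt(1 / n + 1 / n0)   # length n_v
  zc <- grid$z / sqrt(n0)                        # length n_z
  up <- stats::pnorm(sqrt(n) * outer(zc, half, "+"))
  lo <- stats::pnorm(sqrt(n) * outer(zc, half, function(a, b) a - b))
  acc <- as.numeric(crossprod(grid$wz, (up - lo)^k) %*% grid$wv)
  min(1, max(0, 1 - acc))
}

# Deterministic multivariate-t rectangle probability: the quasi-Monte-Carlo
# integrator consumes the R RNG, so run it under a fixed seed and restore
# the caller's RNG state afterwards. Used as the fallback for unbalanced or
# one-sided families.
pmvt_det <- function(lower, upper, df, corr, abseps = 1e-6) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(20240601L)
  as.numeric(mvtnorm::pmvt(lower = lower, upper = upper, df = df, corr = corr,
                           algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                          maxpts = 50000L)))
}

#' Dunnett many-to-one comparisons against a shared control
#'
#' Computes t_i = (mean_i - mean_0) / SE with the pooled within-group error
#' variance and adjusts family-wise via the equicorrelated multivariate t
#' distribution with correlation sqrt(lambda_i lambda_j),
#' lambda_i = n_i / (n_i + n_0) (1/2 for balanced designs). For balanced
#' two-sided families the tail probability is computed by deterministic
#' nested quadrature (conditioning on the control mean and the pooled-SD
#' ratio factorizes the arms); unbalanced or one-sided families fall back
#' to quasi-Monte-Carlo integration of the multivariate t under a fixed
#' internal seed. With a single treatment arm the adjusted p reduces
#' exactly to the ordinary pooled two-sample t-test.
#'
#' @param values Numeric response vector.
#' @param group Group labels, same length; must include `control`.
#' @param control Label of the control group (default "NP").
#' @param config An [analysis_config()].
#' @return Tibble: one row per treatment group with estimate (mean
#'   difference), t statistic, degrees of freedom and adjusted p.
#' @export
dunnett_vs_control <- function(values, group, control = "NP",
                               config = analysis_config()) {
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' not found", call. = FALSE)
  g <- split(values, group)
  if (any(lengths(g) < 2)) stop("need >= 2 observations per arm", call. = FALSE)
  trt <- setdiff(names(g), control)
  k <- length(trt)
  n <- lengths(g)
  means <- vapply(g, mean, 0)
  df <- sum(n) - length(g)
  s2 <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / df
  if (s2 <= .Machine$double.eps) stop("zero pooled variance", call. = FALSE)
  n0 <- n[[control]]
  est <- means[trt] - means[[control]]
  se <- sqrt(s2 * (1 / n[trt] + 1 / n0))
  tstat <- est / se
  lam <- sqrt(n[trt] / (n[trt] + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  two_sided <- config$sidedness == "two"
  balanced <- length(unique(n[trt])) == 1L
  grid <- if (two_sided && balanced && k > 1) dunnett_balanced_grid(df) else NULL
  p_adj <- vapply(seq_len(k), function(i) {
    ti <- tstat[i]
    if (k == 1L) {
      return(if (two_sided) 2 * stats::pt(abs(ti), df, lower.tail = FALSE)
             else stats::pt(ti, df, lower.tail = FALSE))
    }
    if (!is.null(grid)) {
      dunnett_p_balanced(ti, k, n[[trt[1]]], n0, grid)
    } else if (two_sided) {
      acc <- pmvt_det(lower = rep(-abs(ti), k), upper = rep(abs(ti), k),
                      df = df, corr = corr)
      max(0, 1 - acc)
    } else {
      acc <- pmvt_det(lower = rep(-Inf, k), upper = rep(ti, k), df = df,
                      corr = corr)
      max(0, 1 - acc)
    }
  }, 0)
  tibble::tibble(treatment = trt, estimate = unname(est), t = unname(tstat),
                 df = df, p_adj = unname(p_adj))
}

#' Assign responder/non-responder phenotypes from SCFA tables
#'
#' Per subject: replicate fermentations are averaged (default), the
#' acetate+butyrate sum per arm x timepoint forms the observations, a
#' one-way ANOVA across arms is computed as a diagnostic, and Dunnett
#' contrasts of each prebiotic arm against the NP control give family-wise
#' adjusted p-values. A subject is a responder ("R") to a substrate iff
#' p_adj < alpha and the mean treatment-minus-control difference is
#' positive; otherwise "NR". A pairwise Welch t-test table between arms is
#' returned as a diagnostic and does not affect labels.
#'
#' @param scfa ScfaRecord table from [simulate_scfa()] or read from disk.
#' @param config An [analysis_config()].
#' @param control Control arm label (default "NP").
#' @return List: `phenotypes` (tibble subject x substrate with label,
#'   mean_delta_ab_mM, p_adj), `anova` (per-subject one-way ANOVA),
#'   `pairwise` (diagnostic pairwise t table).
#' @export
assign_phenotypes <- function(scfa, config = analysis_config(), control = "NP") {
  d <- as.data.frame(scfa)
  need <- c("subject_id", "treatment", "replicate", "timepoint_h",
            "acetate_mM", "butyrate_mM")
  if (!all(need %in% names(d))) {
    stop("scfa table must carry columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  no_ctrl <- setdiff(unique(d$subject_id),
                     unique(d$subject_id[d$treatment == control]))
  if (length(no_ctrl)) {
    stop("subjects missing the ", control, " control arm: ",
         paste(no_ctrl, collapse = ", "), call. = FALSE)
  }
  d$ab_sum <- d$acetate_mM + d$butyrate_mM
  if (config$average_replicates) {
    d <- stats::aggregate(ab_sum ~ subject_id + treatment + timepoint_h, d, mean)
  }
  calls <- list(); aov_rows <- list(); pw_rows <- list()
  for (sid in unique(d$subject_id)) {
    ds <- d[d$subject_id == sid, ]
    fit <- stats::oneway.test(ab_sum ~ treatment, ds, var.equal = TRUE)
    aov_rows[[sid]] <- tibble::tibble(subject_id = sid,
                                      F = unname(fit$statistic), p = fit$p.value)
    arms <- unique(ds$treatment)
    pw <- t(utils::combn(arms, 2))
    pw_rows[[sid]] <- tibble::tibble(
      subject_id = sid, arm1 = pw[, 1], arm2 = pw[, 2],
      p = apply(pw, 1, function(a) {
        tryCatch(stats::t.test(ds$ab_sum[ds$treatment == a[1]],
                               ds$ab_sum[ds$treatment == a[2]])$p.value,
                 error = function(e) NA_real_)  # degenerate (constant) arms
      }))
    pw_rows[[sid]]$p_adj <- adjust_p(pw_rows[[sid]]$p, config$adjust_method)
    dn <- dunnett_vs_control(ds$ab_sum, ds$treatment, control = control, config = config)
    calls[[sid]] <- tibble::tibble(
      subject_id = sid, substrate = dn$treatment,
      label = ifelse(dn$p_adj < config$alpha & dn$estimate > 0, "R", "NR"),
      mean_delta_ab_mM = dn$estimate, p_adj = dn$p_adj
    )
  }
  list(phenotypes = do.call(rbind, calls),
       anova = do.call(rbind, aov_rows),
       pairwise = do.call(rbind, pw_rows))
}

#' Boxplot-rule univariate outlier scan
#'
#' Flags values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] (`outlier`) and outside
#' 3 IQR (`extreme`), per group. Quartiles use the standard type-7 quantile.
#'
#' @param values Numeric vector.
#' @param group Optional grouping vector (one scan per group).
#' @return Tibble with `value`, `group`, `outlier`, `extreme` in input order.
#' @export
outlier_scan <- function(values, group = NULL) {
  if (is.null(group)) group <- rep("all", length(values))
  out <- rep(FALSE, length(values)); ext <- rep(FALSE, length(values))
  for (gr in unique(group)) {
    i <- which(group == gr)
    if (length(i) < 4) next
    q <- stats::quantile(values[i], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out[i] <- values[i] < q[1] - 1.5 * iqr | values[i] > q[2] + 1.5 * iqr
    ext[i] <- values[i] < q[1] - 3 * iqr | values[i] > q[2] + 3 * iqr
  }
  tibble::tibble(value = values, group = group, outlier = out, extreme = ext)
}

#' Spearman correlation matrix with BH adjustment
#'
#' Rank correlation (average ranks for ties) of every column of `x` against
#' every column of `y`, with Benjamini-Hochberg adjustment across the whole
#' pair family. Constant columns give an undefined rho, reported as NA.
#'
#' @param x,y Numeric data frames / matrices with matched rows (n >= 3).
#' @return Tibble: `var_x`, `var_y`, `rho`, `p`, `p_adj`.
#' @export
spearman_matrix <- function(x, y) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (nrow(x) != nrow(y) || nrow(x) < 3) {
    stop("x and y need matched rows, n >= 3", call. = FALSE)
  }
  grid <- expand.grid(var_x = names(x), var_y = names(y),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- apply(grid, 1, function(g) {
    xv <- x[[g[["var_x"]]]]; yv <- y[[g[["var_y"]]]]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- tibble::tibble(var_x = grid$var_x, var_y = grid$var_y,
                        rho = res[1, ], p = res[2, ])
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
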