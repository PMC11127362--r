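#' Gene copies from DNA concentration of a purified PCR product
#'
#' copies = conc[ng/ul] x 1e-9 [g/ng] x (1 mol bp / 660 g) x
#' 6.023e23 [bp/mol bp] x (1 copy / product size [bp]) x volume [ul].
#' The Avogadro constant is fixed at 6.023e23 for fidelity to the standard
#' qPCR copy-number formula as printed in the protocols this pipeline
#' mirrors.
#'
#' @param conc_ng_per_ul DNA concentration (ng/ul), >= 0.
#' @param product_size_bp Amplicon size (bp), > 0.
#' @param volume_ul Template volume (ul), >= 0.
#' @return Number of copies.
#' @export
copies_from_concentration <- function(conc_ng_per_ul, product_size_bp, volume_ul = 1) {
  if (any(product_size_bp <= 0)) stop("product_size_bp must be > 0", call. = FALSE)
  if (any(conc_ng_per_ul < 0) || any(volume_ul < 0)) {
    stop("concentration and volume must be >= 0", call. = FALSE)
  }
  conc_ng_per_ul * 1e-9 * (1 / 660) * 6.023e23 * (1 / product_size_bp) * volume_ul
}

#' Standard-curve container
#'
#' @param slope CT change per log10 copies (must be negative).
#' @param intercept CT at log10(copies) = 0.
#' @param r2 Coefficient of determination of the fit.
#' @param dynamic_range Range of log10 copies covered by the standards.
#' @return List of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r2 = NA_real_,
                           dynamic_range = c(-Inf, Inf)) {
  if (slope >= 0) stop("standard-curve slope must be negative", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 dynamic_range = dynamic_range),
            class = "standard_curve")
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Ordinary least squares of CT on log10(copies). A slope outside the
#' amplification-efficiency sanity band [-3.6, -3.1] (roughly 90-110%
#' efficiency) triggers a warning, not an error.
#'
#' @param copies Template copies per standard (all > 0); typically a 10-fold
#'   series with >= 3 distinct levels.
#' @param ct Measured CT values.
#' @return A [standard_curve()] with slope, intercept, r2 and the dynamic
#'   range of the standards.
#' @export
fit_standard_curve <- function(copies, ct) {
  keep <- !is.na(ct)
  copies <- copies[keep]; ct <- ct[keep]
  if (any(copies <= 0)) stop("standard copies must be positive", call. = FALSE)
  l10 <- log10(copies)
  if (length(unique(round(l10, 9))) < 3) {
    stop("need >= 3 distinct dilution levels", call. = FALSE)
  }
  if (stats::var(l10) == 0) stop("zero variance in log10 copies", call. = FALSE)
  fit <- stats::lm(ct ~ l10)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("fitted slope is non-negative; not a valid standard curve", call. = FALSE)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  if (slope < -3.6 || slope > -3.1) {
    warning(sprintf("slope %.3f outside efficiency sanity band [-3.6, -3.1]", slope))
  }
  standard_curve(slope, intercept, r2, range(l10))
}

#' Quantify unknowns from CT values via a standard curve
#'
#' copies = 10^((ct - intercept)/slope). Non-detect CT (NA) propagates to a
#' non-detect (NA) copy number; results outside the curve's dynamic range
#' are flagged as extrapolated.
#'
#' @param curve A [standard_curve()].
#' @param ct CT values (NA = non-detect).
#' @return Tibble with `ct`, `copies`, `extrapolated`.
#' @export
quantify_unknown <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  l10 <- (ct - curve$intercept) / curve$slope
  copies <- 10^l10
  extrap <- !is.na(l10) &
    (l10 < curve$dynamic_range[1] | l10 > curve$dynamic_range[2])
  tibble::tibble(ct = ct, copies = copies, extrapolated = extrap)
}

#' Quantify Bifidobacterium counts (CFU/ml) from CT values
#'
#' Same inversion as [quantify_unknown()] with a curve fitted against
#' log10 CFU/ml instead of log10 copies.
#'
#' @param curve_cfu A [standard_curve()] of CT vs log10 CFU/ml.
#' @param ct CT values (NA = non-detect).
#' @return Tibble with `ct`, `cfu_per_ml`, `extrapolated`.
#' @export
bifido_cfu <- function(curve_cfu, ct) {
  out <- quantify_unknown(curve_cfu, ct)
  tibble::tibble(ct = out$ct, cfu_per_ml = out$copies, extrapolated = out$extrapolated)
}
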