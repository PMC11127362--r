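#' Simulation parameters for synthetic fermentation cohorts
#'
#' Builds the parameter set that drives every synthetic-data generator in the
#' package. Defaults emulate the in vitro study design the pipeline targets:
#' 40 fecal donors fermented in duplicate against three prebiotic substrates
#' (FOS, inulin, XOS) plus a no-prebiotic (NP) control arm, sampled every 12 h
#' over four 12-h dilution cycles, with responders producing on average
#' `delta_ab_responder` mM more acetate+butyrate than their NP arm.
#'
#' @param n_subjects Number of donors (cohort size).
#' @param substrates Prebiotic treatment arms; the NP control arm is implicit.
#' @param responder_prevalence Probability a subject responds to a given
#'   substrate (marginal, per substrate).
#' @param phenotype_correlation Latent Gaussian correlation of responder
#'   status across substrates for the same subject (shared-responder
#'   structure; 0 = independent).
#' @param delta_ab_responder Mean increase of acetate+butyrate (mM) in a
#'   responder's treatment arm over the NP arm.
#' @param delta_ab_nonresponder Mean increase (mM) for non-responders
#'   (non-specific fermentation, approximately 0).
#' @param subject_sd Between-subject SD (mM) of the shared random intercept.
#' @param residual_sd Residual SD (mM) per measurement.
#' @param timepoints_h Sampling grid in hours (one per 12-h dilution cycle).
#' @param replicates Duplicate fermentations per subject x arm.
#' @param n_contigs,genes_per_contig Size of the synthetic gene catalog.
#' @param planted_cgc_specs List of planted carbohydrate-gene-cluster layouts;
#'   see [default_planted_cgc_specs()].
#' @param background_signature_rates Named probabilities for background gene
#'   signatures (`cazyme`, `tc`, `tf`); the remainder are non-signature genes.
#' @param n_decoy_targets Number of phenotype-independent decoy qPCR target
#'   genes added per substrate to the assay panel.
#' @param count_depth_range Range of per-sample relative depth factors for the
#'   count simulator.
#' @param count_base_meanlog,count_base_sdlog Log-normal parameters of
#'   per-gene baseline mean counts.
#' @param nb_dispersion Negative-binomial dispersion (alpha; variance =
#'   mu + alpha mu^2).
#' @param planted_log2fc Planted log2 fold change of substrate-specific genes
#'   in responder samples.
#' @param qpcr_mu_log10_responder,qpcr_sd Responder target-gene copy numbers:
#'   log10 copies ~ Normal(mu, sd).
#' @param qpcr_mu_log10_nonresponder Mean log10 copies for the detected
#'   minority of non-responder wells.
#' @param nonresponder_detect_prob Probability a non-responder carries a
#'   detectable (low) copy number of a planted gene; otherwise non-detect.
#' @param qpcr_ct_sd Technical CT noise (cycles) when inverting the standard
#'   curve into well-level CT values.
#' @param qpcr_curve_slope,qpcr_curve_intercept Standard curve used to encode
#'   copies as CT values (CT = intercept + slope * log10 copies); slope must
#'   be negative.
#' @param time_slope_mM Additive acetate drift per 12-h cycle (mM), shared by
#'   all arms (no treatment x time interaction).
#' @param seed Integer master seed; identical parameters (including seed)
#'   yield bit-identical outputs.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 40,
                       substrates = c("FOS", "INU", "XOS"),
                       responder_prevalence = 0.6,
                       phenotype_correlation = 0.5,
                       delta_ab_responder = 20,
                       delta_ab_nonresponder = 0.5,
                       subject_sd = 4,
                       residual_sd = 3,
                       timepoints_h = c(12, 24, 36, 48),
                       replicates = 2,
                       n_contigs = 50,
                       genes_per_contig = 30,
                       planted_cgc_specs = default_planted_cgc_specs(substrates),
                       background_signature_rates = c(cazyme = 0.06, tc = 0.05, tf = 0.02),
                       n_decoy_targets = 4,
                       count_depth_range = c(0.5, 2),
                       count_base_meanlog = log(50),
                       count_base_sdlog = 1,
                       nb_dispersion = 0.2,
                       planted_log2fc = 2,
                       qpcr_mu_log10_responder = 3,
                       qpcr_sd = 0.5,
                       qpcr_mu_log10_nonresponder = 1,
                       nonresponder_detect_prob = 0.1,
                       qpcr_ct_sd = 0.15,
                       qpcr_curve_slope = -3.32,
                       qpcr_curve_intercept = 40,
                       time_slope_mM = 1,
                       seed = 1L) {
  p <- as.list(environment())
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$n_subjects) || p$n_subjects < 1) {
    stop("n_subjects must be a positive count", call. = FALSE)
  }
  if (length(p$timepoints_h) == 0) {
    stop("timepoints_h must be non-empty", call. = FALSE)
  }
  probs <- c(p$responder_prevalence, p$nonresponder_detect_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(p$phenotype_correlation) > 1) {
    stop("phenotype_correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (p$delta_ab_responder <= p$delta_ab_nonresponder) {
    stop("delta_ab_responder must exceed delta_ab_nonresponder", call. = FALSE)
  }
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (p$qpcr_curve_slope >= 0) {
    stop("qpcr_curve_slope must be negative (CT decreases with template)", call. = FALSE)
  }
  if (p$replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  max_span <- max(c(0L, vapply(p$planted_cgc_specs, function(s) length(s$layout), 1L)))
  if (max_span > p$genes_per_contig) {
    stop("a planted cluster layout is wider than genes_per_contig", call. = FALSE)
  }
  if (!is.numeric(p$seed) || p$seed != as.integer(p$seed) || abs(p$seed) > 2^30) {
    stop("seed must be an integer with |seed| <= 2^30", call. = FALSE)
  }
  invisible(p)
}

#' Default planted carbohydrate gene cluster layouts
#'
#' Two clusters per substrate, each with four CAZymes and two transporters
#' separated by one non-signature gene (satisfying the cluster rule of at
#' least one CAZyme, at least one transporter, gaps of at most five
#' non-signature genes). Families follow the substrate biology: fructan
#' clusters carry GH32/GH68 (beta-fructofuranosidase/levansucrase) and, for
#' inulin, GH91 (inulin lyase); xylan clusters carry GH8/GH10 xylanases and
#' GH43/GH120 beta-xylosidases, including a GH43 subfamily.
#'
#' Layout entries are CAZy family names (CAZyme members), `"TC"`
#' (transporter), `"TF"` (transcription factor) or `"NONE"` (intervening
#' non-signature gene).
#'
#' @param substrates Substrates to plant clusters for.
#' @return List of specs: `list(substrate =, layout =)`.
#' @export
default_planted_cgc_specs <- function(substrates = c("FOS", "INU", "XOS")) {
  layouts <- list(
    FOS = list(
      c("GH32", "TC", "GH68", "NONE", "GH32", "TC", "GH32"),
      c("GH32", "GH68", "TC", "NONE", "GH32", "TC", "GH32")
    ),
    INU = list(
      c("GH32", "TC", "GH91", "NONE", "GH32", "TC", "GH68"),
      c("GH91", "GH32", "TC", "NONE", "GH68", "TC", "GH32")
    ),
    XOS = list(
      c("GH43", "TC", "GH120", "NONE", "GH43_12", "TC", "GH10"),
      c("GH8", "GH43", "TC", "NONE", "GH120", "TC", "GH10")
    )
  )
  specs <- list()
  for (s in substrates) {
    if (!s %in% names(layouts)) {
      stop("no default planted layout for substrate ", s, call. = FALSE)
    }
    for (lay in layouts[[s]]) {
      specs[[length(specs) + 1L]] <- list(substrate = s, layout = lay)
    }
  }
  specs
}
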