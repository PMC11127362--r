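#' Stratify trial subjects into treatment arms from predicted phenotypes
#'
#' Single-substrate predicted responders go to that substrate's arm;
#' multi-substrate responders are assigned among their predicted substrates
#' so that responder arm sizes stay balanced (differ by at most 1 when
#' feasible; seeded random tie-break); subjects predicted non-responders to
#' every substrate are given XOS as the control-of-record arm.
#'
#' @param predictions Tibble with `subject_id`, `substrate`, `label`
#'   ("R"/"NR"), complete over subjects x substrates.
#' @param all_nr_arm Arm for all-NR subjects (default "XOS").
#' @param seed Seed for the balanced random assignment.
#' @return Tibble `subject_id`, `arm`, `n_predicted_substrates`.
#' @export
stratify_arms <- function(predictions, all_nr_arm = "XOS", seed = 1L) {
  d <- as.data.frame(predictions)
  subs <- unique(d$substrate)
  subjects <- unique(d$subject_id)
  complete <- all(table(d$subject_id, d$substrate) == 1)
  if (!complete) stop("every subject needs a prediction for every substrate", call. = FALSE)
  set.seed(seed)
  pred_list <- lapply(subjects, function(s) d$substrate[d$subject_id == s & d$label == "R"])
  names(pred_list) <- subjects
  arm <- stats::setNames(rep(NA_character_, length(subjects)), subjects)
  counts <- stats::setNames(rep(0L, length(subs)), subs)
  n_pred <- lengths(pred_list)
  arm[n_pred == 0] <- all_nr_arm
  one <- names(pred_list)[n_pred == 1]
  arm[one] <- unlist(pred_list[one])
  counts_tab <- table(factor(arm[n_pred == 1], levels = subs))
  counts[names(counts_tab)] <- as.integer(counts_tab)
  multi <- sample(names(pred_list)[n_pred > 1])
  for (s in multi) {
    cand <- pred_list[[s]]
    pick <- cand[counts[cand] == min(counts[cand])]
    if (length(pick) > 1) pick <- sample(pick, 1)
    arm[s] <- pick
    counts[pick] <- counts[pick] + 1L
  }
  resp_sizes <- counts[unique(unlist(pred_list))]
  if (length(resp_sizes) > 1 && diff(range(resp_sizes)) > 1) {
    warning("responder arm sizes differ by more than 1 (best-effort balance)")
  }
  tibble::tibble(subject_id = names(arm), arm = unname(arm),
                 n_predicted_substrates = unname(n_pred))
}

#' Paired t-test on pre/post measurements
#'
#' @param pre,post Paired numeric vectors (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2) {
    stop("need paired vectors of length >= 2", call. = FALSE)
  }
  d <- post - pre
  if (stats::var(d) <= .Machine$double.eps) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(d))
}

#' Shannon diversity index (natural log)
#'
#' @param abundances Non-negative vector with positive sum.
#' @return H = -sum p_i ln p_i over nonzero proportions.
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(abundances) <= 0) stop("abundances sum to zero", call. = FALSE)
  unname(vegan::diversity(abundances, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i). Two all-zero profiles are
#' defined as dissimilarity 0 with a warning.
#'
#' @param x,y Equal-length non-negative vectors.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("profiles must be non-negative", call. = FALSE)
  if (sum(x) + sum(y) == 0) {
    warning("both profiles are all-zero; returning 0")
    return(0)
  }
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix of sample profiles
#'
#' @param profiles Matrix samples x features, non-negative.
#' @return A `dist` object.
#' @export
bray_curtis_matrix <- function(profiles) {
  vegan::vegdist(as.matrix(profiles), method = "bray")
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of the squared dissimilarities followed by
#' eigendecomposition; coordinates are returned for positive eigenvalues
#' and negative eigenvalues are reported without correction.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param tol Asymmetry tolerance.
#' @return List: `coordinates` (samples x axes), `eigenvalues`,
#'   `relative_eig` (relative to the sum of positive eigenvalues).
#' @export
pcoa_ord <- function(d, tol = 1e-8) {
  m <- as.matrix(d)
  if (max(abs(m - t(m))) > tol) stop("dissimilarity matrix is asymmetric", call. = FALSE)
  if (max(abs(diag(m))) > tol) stop("dissimilarity matrix needs a zero diagonal", call. = FALSE)
  n <- nrow(m)
  k <- n - 1
  # negative eigenvalues are expected for non-Euclidean dissimilarities and
  # are reported to the caller rather than warned about
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > tol * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = eig,
       relative_eig = eig / sum(eig[eig > 0]))
}

#' Friedman rank test for within-subject visit comparisons
#'
#' Thin wrapper for blocked (subject) comparisons of repeated ordinal
#' scores such as gastrointestinal symptom ratings across visits.
#'
#' @param values Numeric responses.
#' @param groups Visit/treatment factor.
#' @param blocks Subject factor.
#' @return List with `chisq`, `df`, `p`.
#' @export
friedman_blocks <- function(values, groups, blocks) {
  ht <- stats::friedman.test(values, groups = factor(groups), blocks = factor(blocks))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
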