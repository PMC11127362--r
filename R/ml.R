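#' RBF-SVM configuration
#'
#' Defaults follow the study design this pipeline mirrors: grid-searched
#' cost and kernel width, 100x repeated 5-fold cross-validation, a 50:50
#' stratified train/test split, 100 models for permutation importance.
#' The cost grid spans powers of two and the kernel width grid multiplies a
#' median-distance heuristic; both are configurable because the original
#' grid values are not published.
#'
#' @param cost_grid Candidate SVM cost values C.
#' @param sigma_factors Multipliers applied to the median-heuristic RBF
#'   width (kernlab parameterization, k = exp(-sigma |x - y|^2)).
#' @param cv_folds,cv_repeats Stratified k-fold CV design for the grid search.
#' @param split_fraction Training fraction of the stratified split.
#' @param n_models Number of split/CV replicates for permutation importance.
#' @param n_permutations Column shuffles per feature per model.
#' @param seed Master seed.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(cost_grid = 2^(-2:6), sigma_factors = c(0.25, 0.5, 1, 2, 4),
                       cv_folds = 5, cv_repeats = 100, split_fraction = 0.5,
                       n_models = 100, n_permutations = 25, seed = 1L) {
  stopifnot(length(cost_grid) > 0, length(sigma_factors) > 0, cv_folds >= 2)
  structure(list(cost_grid = cost_grid, sigma_factors = sigma_factors,
                 cv_folds = cv_folds, cv_repeats = cv_repeats,
                 split_fraction = split_fraction, n_models = n_models,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "svm_config")
}

#' Feature matrix for responder classification
#'
#' Builds the subjects x features matrix for one substrate from qPCR copy
#' numbers: log10(copies + 1) per target gene (non-detect = 0 copies before
#' the transform), with responder labels attached.
#'
#' @param copy_numbers Long tibble from [simulate_qpcr()] (or a samples x
#'   genes matrix).
#' @param phenotypes Tibble with `subject_id`, `substrate` and a label
#'   column (`phenotype` or `label`).
#' @param substrate Substrate whose panel and labels to use.
#' @param bifido_log10_cfu Optional named vector (by subject) appended as a
#'   `bifidobacterium_log10_cfu` column.
#' @return List: `x` (matrix, log10 copies + 1), `y` (factor NR/R),
#'   `subjects`.
#' @export
build_feature_matrix <- function(copy_numbers, phenotypes, substrate,
                                 bifido_log10_cfu = NULL) {
  if (!is.matrix(copy_numbers)) {
    d <- as.data.frame(copy_numbers)
    d <- d[d$substrate == substrate, ]
    copy_numbers <- copy_number_matrix(d)
  }
  ph <- as.data.frame(phenotypes)
  lab_col <- intersect(c("phenotype", "label"), names(ph))[1]
  ph <- ph[ph$substrate == substrate, ]
  subj <- intersect(rownames(copy_numbers), ph$subject_id)
  x <- log10(copy_numbers[subj, , drop = FALSE] + 1)
  if (!is.null(bifido_log10_cfu)) {
    x <- cbind(x, bifidobacterium_log10_cfu = bifido_log10_cfu[subj])
  }
  y <- factor(ph[[lab_col]][match(subj, ph$subject_id)], levels = c("NR", "R"))
  list(x = x, y = y, subjects = subj)
}

#' Stratified train/test split
#'
#' @param y Class labels (factor or character).
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer index vectors `train` and `test` (a partition).
#' @export
split_train_test <- function(y, fraction = 0.5, seed = 1L) {
  y <- as.factor(y)
  if (any(table(y) < 2)) stop("every class needs >= 2 members to split", call. = FALSE)
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    k <- max(1L, round(length(idx) * fraction))
    k <- min(k, length(idx) - 1L)
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Area under the ROC curve (rank-sum formulation)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counting one half: AUC = (R1 - n1(n1+1)/2) / (n1 n0) where R1 is
#' the rank sum of the positives (the normalized Mann-Whitney U).
#'
#' @param labels Binary labels; the positive class is the second factor
#'   level (or `positive`).
#' @param scores Numeric decision scores.
#' @param positive Positive-class label (default: second level / max label).
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, scores, positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_train <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       x = sweep(sweep(x, 2, ctr), 2, scl, "/"))
}

median_heuristic_sigma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1)
  1 / stats::median(d2)
}

fit_ksvm <- function(x, y, C, sigma) {
  kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                kpar = list(sigma = sigma), C = C, scaled = FALSE)
}

decision_scores <- function(fit, x, orientation = 1) {
  as.numeric(kernlab::predict(fit, x, type = "decision")) * orientation
}

#' Train a grid-searched RBF SVM responder classifier
#'
#' Features are z-scored using training statistics only. The (C, sigma)
#' grid is scored by mean AUC over `cv_repeats` replicates of stratified
#' `cv_folds`-fold cross-validation; the winning pair (ties resolved in
#' grid order) is refit on the full training set. Decision scores are
#' oriented so that larger values indicate the responder class.
#'
#' @param x Feature matrix (subjects x features).
#' @param y Labels, factor with levels `c("NR", "R")`.
#' @param config An [svm_config()].
#' @return List of class `svm_model`: the fitted kernlab model, chosen
#'   C/sigma, `cv_auc`, scaler statistics, feature names, orientation.
#' @export
train_svm <- function(x, y, config = svm_config()) {
  y <- factor(y, levels = c("NR", "R"))
  if (any(table(y) < 2)) stop("each class needs >= 2 training subjects", call. = FALSE)
  sc <- scale_train(x)
  xs <- sc$x
  set.seed(config$seed)
  sigma0 <- median_heuristic_sigma(xs)
  grid <- expand.grid(C = config$cost_grid,
                      sigma = sigma0 * config$sigma_factors,
                      KEEP.OUT.ATTRS = FALSE)
  folds <- lapply(seq_len(config$cv_repeats), function(r) stratified_folds(y, config$cv_folds))
  cv_auc <- vapply(seq_len(nrow(grid)), function(gi) {
    aucs <- c()
    for (fold in folds) {
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f; te <- fold == f
        if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) next
        fit <- fit_ksvm(xs[tr, , drop = FALSE], y[tr], grid$C[gi], grid$sigma[gi])
        tr_sco <- decision_scores(fit, xs[tr, , drop = FALSE])
        ori <- if (mean(tr_sco[y[tr] == "R"]) >= mean(tr_sco[y[tr] == "NR"])) 1 else -1
        sco <- decision_scores(fit, xs[te, , drop = FALSE], ori)
        aucs <- c(aucs, auc(y[te], sco))
      }
    }
    mean(aucs)
  }, 0)
  best <- which.max(cv_auc)
  fit <- fit_ksvm(xs, y, grid$C[best], grid$sigma[best])
  raw <- decision_scores(fit, xs)
  orientation <- if (mean(raw[y == "R"]) >= mean(raw[y == "NR"])) 1 else -1
  structure(list(fit = fit, C = grid$C[best], sigma = grid$sigma[best],
                 cv_auc = cv_auc[best], center = sc$center, scale = sc$scale,
                 features = colnames(x), orientation = orientation),
            class = "svm_model")
}

#' Predict responder phenotypes for new subjects
#'
#' Applies the training scaler, computes oriented decision scores and
#' labels by the sign of the score (threshold 0): positive = responder.
#'
#' @param model An `svm_model` from [train_svm()].
#' @param newx Feature matrix with the training feature schema.
#' @return Tibble with `score` and `label`.
#' @export
predict_phenotype <- function(model, newx) {
  missing <- setdiff(model$features, colnames(newx))
  if (length(missing)) {
    stop("feature schema mismatch; missing features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  newx <- newx[, model$features, drop = FALSE]
  xs <- sweep(sweep(newx, 2, model$center), 2, model$scale, "/")
  sco <- decision_scores(model$fit, xs, model$orientation)
  tibble::tibble(score = sco, label = ifelse(sco > 0, "R", "NR"))
}

#' Permutation feature importance across repeated models
#'
#' For each of `n_models` models (each with its own stratified 50:50 split
#' and grid-searched training run), the importance of feature f is the
#' held-out test AUC minus the mean AUC over `n_permutations` copies of the
#' test set with feature f's column shuffled. Features are ranked by the
#' mean difference across models; a feature whose column is constant
#' contributes exactly zero.
#'
#' @param x Feature matrix (subjects x features).
#' @param y Labels (factor NR/R).
#' @param config An [svm_config()].
#' @return List: `importance` (tibble feature / mean_delta_auc / rank,
#'   sorted descending, with per-model deltas in a list column) and
#'   `test_auc` (per-model held-out AUC).
#' @export
permutation_importance <- function(x, y, config = svm_config()) {
  y <- factor(y, levels = c("NR", "R"))
  nf <- ncol(x)
  deltas <- matrix(NA_real_, config$n_models, nf,
                   dimnames = list(NULL, colnames(x)))
  test_auc <- numeric(config$n_models)
  for (m in seq_len(config$n_models)) {
    seed_m <- config$seed + 101L * m
    sp <- split_train_test(y, config$split_fraction, seed = seed_m)
    cfg_m <- config; cfg_m$seed <- seed_m
    model <- train_svm(x[sp$train, , drop = FALSE], y[sp$train], cfg_m)
    xte <- x[sp$test, , drop = FALSE]
    sco <- predict_phenotype(model, xte)$score
    a0 <- auc(y[sp$test], sco)
    test_auc[m] <- a0
    set.seed(seed_m + 7L)
    for (f in seq_len(nf)) {
      if (length(unique(xte[, f])) == 1L) { deltas[m, f] <- 0; next }
      perm_auc <- vapply(seq_len(config$n_permutations), function(p) {
        xp <- xte
        xp[, f] <- xp[sample(nrow(xp)), f]
        auc(y[sp$test], predict_phenotype(model, xp)$score)
      }, 0)
      deltas[m, f] <- a0 - mean(perm_auc)
    }
  }
  imp <- tibble::tibble(
    feature = colnames(x),
    mean_delta_auc = unname(colMeans(deltas)),
    per_model_delta = lapply(seq_len(nf), function(f) deltas[, f])
  )
  imp <- imp[order(-imp$mean_delta_auc), ]
  imp$rank <- seq_len(nrow(imp))
  list(importance = imp, test_auc = test_auc)
}
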