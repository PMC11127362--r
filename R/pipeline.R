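#' Pipeline configuration
#'
#' Bundles the stage configurations and a master seed. The master seed
#' overrides `params$seed` and seeds every stochastic stage (generator,
#' splits, CV, permutations), so a fixed configuration yields a
#' byte-identical artifact bundle.
#'
#' @param params Generator parameters ([sim_params()]).
#' @param analysis Phenotyping configuration ([analysis_config()]).
#' @param cgc Cluster-detection parameters ([cgc_params()]).
#' @param svm Classifier configuration ([svm_config()]); the default is a
#'   reduced design (10 models, 2 CV repeats, coarse grids) sized for a
#'   full pipeline run in tens of seconds.
#' @param q_threshold FDR threshold for responder-associated genes.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(params = sim_params(),
                            analysis = analysis_config(),
                            cgc = cgc_params(),
                            svm = svm_config(cost_grid = 2^seq(-2, 6, 2),
                                             sigma_factors = c(0.5, 1, 2),
                                             cv_repeats = 2, n_models = 10,
                                             n_permutations = 10),
                            q_threshold = 0.05,
                            seed = 1L) {
  params$seed <- as.integer(seed)
  svm$seed <- as.integer(seed) + 50000L
  structure(list(params = params, analysis = analysis, cgc = cgc, svm = svm,
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `params`, `analysis`, `cgc`, `svm`, `q_threshold`, `seed`
#' override the corresponding constructor defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    params = do.call(sim_params, c(y$params, list())),
    analysis = do.call(analysis_config, c(y$analysis, list())),
    cgc = do.call(cgc_params, c(y$cgc, list())),
    svm = do.call(svm_config, c(y$svm, list())),
    q_threshold = if (is.null(y$q_threshold)) 0.05 else y$q_threshold,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

#' Run the full discovery-and-prediction pipeline on a synthetic cohort
#'
#' Stage order: simulate cohort -> SCFA phenotyping -> per-substrate
#' differential abundance (NB Wald) -> substrate family/EC filtering ->
#' responder-association filter -> cluster detection -> whole-cluster
#' selection -> feature matrix from qPCR copy numbers -> permutation
#' feature ranking -> train/test split + RBF-SVM -> hold-out prediction.
#' Deterministic under the configuration's master seed. When `outdir` is
#' given, every artifact is also written to disk (TSV/GFF3/JSON).
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @param quiet Suppress per-stage log lines.
#' @return List: `cohort`, `phenotypes`, `da` (per substrate), `cgcs`,
#'   `selected_cgcs`, `retained_genes`, `importance`, `models`,
#'   `predictions`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  params <- config$params

  log_stage("[simulate] seed=%d n_subjects=%d", config$seed, params$n_subjects)
  cohort <- simulate_cohort(params)

  log_stage("[phenotype] %d SCFA records", nrow(cohort$scfa))
  phen <- assign_phenotypes(cohort$scfa, config$analysis)
  calls <- phen$phenotypes

  cgcs <- find_cgcs(cohort$catalog, config$cgc)
  log_stage("[find-cgc] %d clusters", nrow(cgcs))

  da <- list(); retained <- list(); selected <- list()
  models <- list(); predictions <- list(); importance <- list()
  for (s in params$substrates) {
    sm <- cohort$samples[cohort$samples$substrate == s, ]
    lab <- calls$label[match(paste(sm$subject_id, s), paste(calls$subject_id, calls$substrate))]
    cts <- cohort$counts[, sm$sample_id, drop = FALSE]
    if (length(unique(lab)) == 2 && min(table(lab)) >= 3) {
      da_s <- nb_wald_test(cts, lab, ref = "NR")
      da[[s]] <- da_s
      ann <- merge(da_s, cohort$catalog, by = "gene_id", sort = FALSE)
      cand <- substrate_gene_filter(ann, substrate_spec(s))
      ret <- responder_association_filter(cand, config$q_threshold)
    } else {
      log_stage("[%s] phenotype groups too small for differential abundance", s)
      cand <- tibble::tibble()
      ret <- character(0)
    }
    retained[[s]] <- ret
    sel <- suppressWarnings(clusters_for_genes(ret, cgcs, s))
    selected[[s]] <- sel$clusters
    log_stage("[%s] %d DA genes -> %d candidates -> %d retained -> %d clusters",
              s, sum(da_s$q < config$q_threshold, na.rm = TRUE), nrow(cand),
              length(ret), nrow(sel$clusters))

    fm <- build_feature_matrix(cohort$qpcr$copy_numbers, calls, s)
    if (min(table(fm$y)) < 2) {
      log_stage("[%s] too few subjects in one class; skipping classifier", s)
      next
    }
    sp <- split_train_test(fm$y, config$svm$split_fraction, seed = config$svm$seed)
    model <- train_svm(fm$x[sp$train, , drop = FALSE], fm$y[sp$train], config$svm)
    pred <- predict_phenotype(model, fm$x[sp$test, , drop = FALSE])
    pred$subject_id <- fm$subjects[sp$test]
    pred$truth_label <- as.character(fm$y[sp$test])
    pred$substrate <- s
    models[[s]] <- model
    predictions[[s]] <- pred
    imp <- permutation_importance(fm$x, fm$y, config$svm)
    importance[[s]] <- cbind(substrate = s, imp$importance)
    log_stage("[%s] test AUC %.3f (C=%g, sigma=%.3g)", s,
              auc(fm$y[sp$test], pred$score), model$C, model$sigma)
  }

  report <- list(
    seed = config$seed,
    n_subjects = params$n_subjects,
    n_scfa_records = nrow(cohort$scfa),
    n_genes = nrow(cohort$catalog),
    n_cgcs = nrow(cgcs),
    n_retained = lengths(retained),
    n_selected_cgcs = vapply(selected, nrow, 0L),
    test_auc = vapply(names(predictions), function(s) {
      pr <- predictions[[s]]
      if (length(unique(pr$truth_label)) < 2) return(NA_real_)
      auc(pr$truth_label, pr$score)
    }, 0)
  )

  bundle <- list(cohort = cohort, phenotypes = calls, diagnostics = phen,
                 da = da, cgcs = cgcs, retained_genes = retained,
                 selected_cgcs = selected, importance = importance,
                 models = models, predictions = predictions, report = report)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv_dot(bundle$cohort$scfa, p("scfa.tsv"))
  write_catalog(bundle$cohort$catalog, p("catalog.gff3"))
  write_tsv_dot(bundle$cohort$catalog, p("catalog.tsv"))
  cts <- as.data.frame(bundle$cohort$counts)
  cts <- cbind(gene_id = rownames(bundle$cohort$counts), cts)
  write_tsv_dot(cts, p("counts.tsv"))
  write_tsv_dot(bundle$cohort$samples, p("samples.tsv"))
  write_tsv_dot(bundle$cohort$qpcr$copy_numbers, p("qpcr.tsv"))
  write_tsv_dot(bundle$cohort$qpcr$wells, p("qpcr_wells.tsv"))
  write_tsv_dot(bundle$phenotypes, p("phenotypes.tsv"))
  for (s in names(bundle$da)) write_tsv_dot(bundle$da[[s]], p(sprintf("da_%s.tsv", s)))
  write_tsv_dot(bundle$cgcs, p("cgc_summary.tsv"))
  member_rows <- do.call(rbind, lapply(names(bundle$selected_cgcs), function(s) {
    cl <- bundle$selected_cgcs[[s]]
    if (!nrow(cl)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
      tibble::tibble(substrate = s, substrate_cgc_id = cl$substrate_cgc_id[i],
                     cgc_id = cl$cgc_id[i], gene_id = cl$member_gene_ids[[i]])
    }))
  }))
  if (!is.null(member_rows)) write_tsv_dot(member_rows, p("cgcs.tsv"))
  if (length(bundle$importance)) {
    imp <- do.call(rbind, bundle$importance)
    imp$per_model_delta <- NULL
    write_tsv_dot(imp, p("importance.tsv"))
  }
  if (length(bundle$predictions)) {
    write_tsv_dot(do.call(rbind, bundle$predictions), p("predictions.tsv"))
  }
  truth <- bundle$cohort$truth
  jsonlite::write_json(
    list(phenotype = truth$phenotype, planted_genes = truth$planted_genes,
         decoy_targets = truth$decoy_targets,
         planted_cgcs = truth$planted_cgcs),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
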