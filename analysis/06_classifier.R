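#!/usr/bin/env Rscript
# Train per-substrate RBF-SVM responder classifiers on baseline copy-number
# features (stratified 50:50 split, grid-searched C and sigma under
# repeated 5-fold CV) and evaluate on the held-out half.

suppressPackageStartupMessages(library(prebioresponse))

qpcr <- read_tsv_dot("results/data/qpcr.tsv")
phen <- read_tsv_dot("results/phenotypes.tsv")

rows <- list(); preds <- list()
for (s in c("FOS", "INU", "XOS")) {
  fm <- build_feature_matrix(qpcr, phen, s)
  sp <- split_train_test(fm$y, 0.5, seed = 1)
  cfg <- svm_config(cv_repeats = 10, seed = 1)
  mdl <- train_svm(fm$x[sp$train, ], fm$y[sp$train], cfg)
  pr <- predict_phenotype(mdl, fm$x[sp$test, ])
  test_auc <- auc(fm$y[sp$test], pr$score)
  rows[[s]] <- tibble::tibble(substrate = s, C = mdl$C, sigma = mdl$sigma,
                              cv_auc = mdl$cv_auc, test_auc = test_auc)
  preds[[s]] <- tibble::tibble(substrate = s, subject_id = fm$subjects[sp$test],
                               score = pr$score, label = pr$label,
                               called_phenotype = as.character(fm$y[sp$test]))
  message(sprintf("%s: C = %g, sigma = %.3g, CV AUC = %.3f, test AUC = %.3f",
                  s, mdl$C, mdl$sigma, mdl$cv_auc, test_auc))
}
write_tsv_dot(do.call(rbind, rows), "results/model_metrics.tsv")
write_tsv_dot(do.call(rbind, preds), "results/predictions.tsv")
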