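#!/usr/bin/env Rscript
# Feeding-trial stage on the synthetic cohort: stratify subjects into
# treatment arms from predicted phenotypes (all-NR subjects default to the
# XOS arm), then characterize the cohort's baseline gene profiles with
# Shannon diversity and a Bray-Curtis PCoA of log10 copy-number profiles,
# and compare SCFA output of called responders pre/post (first vs last
# 12-h cycle) with a paired t-test.

suppressPackageStartupMessages(library(prebioresponse))

phen <- read_tsv_dot("results/phenotypes.tsv")
qpcr <- read_tsv_dot("results/data/qpcr.tsv")
scfa <- read_tsv_dot("results/data/scfa.tsv")

pred <- phen[, c("subject_id", "substrate", "label")]
arms <- stratify_arms(pred, seed = 1)
write_tsv_dot(arms, "results/trial_arms.tsv")
message("arm sizes: ", paste(sprintf("%s=%d", names(table(arms$arm)),
                                     table(arms$arm)), collapse = ", "))

profiles <- log10(copy_number_matrix(qpcr) + 1)
H <- apply(profiles, 1, function(r) if (sum(r) > 0) shannon(r) else NA)
message(sprintf("gene-profile Shannon diversity: median %.2f (IQR %.2f-%.2f)",
                median(H, na.rm = TRUE), quantile(H, 0.25, na.rm = TRUE),
                quantile(H, 0.75, na.rm = TRUE)))

keep <- rowSums(profiles) > 0
ord <- pcoa_ord(as.matrix(bray_curtis_matrix(profiles[keep, ])))
coords <- tibble::tibble(subject_id = rownames(profiles)[keep],
                         PCo1 = ord$coordinates[, 1],
                         PCo2 = ord$coordinates[, 2])
write_tsv_dot(coords, "results/trial_pcoa.tsv")
message(sprintf("PCoA: first two axes explain %.0f%% + %.0f%% of positive inertia",
                100 * ord$relative_eig[1], 100 * ord$relative_eig[2]))

scfa$ab <- scfa$acetate_mM + scfa$butyrate_mM
resp <- phen[phen$label == "R", ]
first <- min(scfa$timepoint_h); last <- max(scfa$timepoint_h)
pre <- post <- c()
for (i in seq_len(nrow(resp))) {
  sel <- scfa$subject_id == resp$subject_id[i] & scfa$treatment == resp$substrate[i]
  pre <- c(pre, mean(scfa$ab[sel & scfa$timepoint_h == first]))
  post <- c(post, mean(scfa$ab[sel & scfa$timepoint_h == last]))
}
pt <- paired_t(pre, post)
message(sprintf("responders' acetate+butyrate, cycle 1 vs 4: mean diff %.1f mM, t(%d) = %.2f, p = %.3g",
                pt$mean_diff, pt$df, pt$t, pt$p))
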