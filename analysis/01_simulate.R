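#!/usr/bin/env Rscript
# Generate the default synthetic fermentation cohort (40 donors, duplicate
# fermentations of FOS/inulin/XOS plus a no-prebiotic control over four 12-h
# cycles) with planted ground truth, and write every raw data product.

suppressPackageStartupMessages(library(prebioresponse))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

params <- sim_params(seed = 1)
cohort <- simulate_cohort(params)

write_tsv_dot(cohort$scfa, file.path(outdir, "scfa.tsv"))
write_catalog(cohort$catalog, file.path(outdir, "catalog.gff3"))
write_tsv_dot(cohort$catalog, file.path(outdir, "catalog.tsv"))
counts <- cbind(gene_id = rownames(cohort$counts), as.data.frame(cohort$counts))
write_tsv_dot(counts, file.path(outdir, "counts.tsv"))
write_tsv_dot(cohort$samples, file.path(outdir, "samples.tsv"))
write_tsv_dot(cohort$qpcr$copy_numbers, file.path(outdir, "qpcr.tsv"))
write_tsv_dot(cohort$qpcr$wells, file.path(outdir, "qpcr_wells.tsv"))
jsonlite::write_json(
  list(phenotype = cohort$truth$phenotype,
       planted_genes = cohort$truth$planted_genes,
       decoy_targets = cohort$truth$decoy_targets),
  file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)

tr <- cohort$truth$phenotype
message(sprintf("cohort: %d subjects, %d SCFA records, %d genes, %d samples",
                params$n_subjects, nrow(cohort$scfa), nrow(cohort$catalog),
                nrow(cohort$samples)))
for (s in params$substrates) {
  message(sprintf("  %s responders (truth): %d/%d", s,
                  sum(tr$phenotype[tr$substrate == s] == "R"), params$n_subjects))
}
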