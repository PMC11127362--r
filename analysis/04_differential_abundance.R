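#!/usr/bin/env Rscript
# Per-substrate differential abundance between called responders and
# non-responders (median-of-ratios + NB Wald), followed by the
# substrate-specific filtering cascade: CAZy family whitelist, enzyme-name
# exclusions, responder-association retention, and whole-cluster selection.

suppressPackageStartupMessages(library(prebioresponse))

catalog <- read_catalog("results/data/catalog.gff3")
counts_tab <- read_tsv_dot("results/data/counts.tsv")
counts <- as.matrix(counts_tab[, -1])
rownames(counts) <- counts_tab$gene_id
samples <- read_tsv_dot("results/data/samples.tsv")
phen <- read_tsv_dot("results/phenotypes.tsv")
cgcs <- find_cgcs(catalog)

selected_rows <- list()
for (s in c("FOS", "INU", "XOS")) {
  sm <- samples[samples$substrate == s, ]
  lab <- phen$label[match(paste(sm$subject_id, s),
                          paste(phen$subject_id, phen$substrate))]
  da <- nb_wald_test(counts[, sm$sample_id], lab, ref = "NR")
  write_tsv_dot(da, sprintf("results/da_%s.tsv", s))
  n_r <- sum(da$q < 0.05 & da$log2fc > 0, na.rm = TRUE)
  n_nr <- sum(da$q < 0.05 & da$log2fc < 0, na.rm = TRUE)
  gof <- chisq_gof(c(n_r, n_nr))
  message(sprintf("%s: %d responder- vs %d non-responder-associated DA genes (chi2 = %.1f, p = %.2g)",
                  s, n_r, n_nr, gof$chisq, gof$p))

  ann <- merge(da, catalog, by = "gene_id", sort = FALSE)
  cand <- substrate_gene_filter(ann, substrate_spec(s))
  retained <- responder_association_filter(cand, 0.05)
  sel <- clusters_for_genes(retained, cgcs, s)
  message(sprintf("  %d whitelist candidates -> %d retained -> %d clusters (%s)",
                  nrow(cand), length(retained), nrow(sel$clusters),
                  paste(sel$clusters$substrate_cgc_id, collapse = ", ")))
  if (nrow(sel$clusters)) {
    cl <- sel$clusters
    selected_rows[[s]] <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
      tibble::tibble(substrate = s, substrate_cgc_id = cl$substrate_cgc_id[i],
                     cgc_id = cl$cgc_id[i], gene_id = cl$member_gene_ids[[i]])
    }))
  }
}
write_tsv_dot(do.call(rbind, selected_rows), "results/selected_cgcs.tsv")
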