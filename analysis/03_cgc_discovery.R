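#!/usr/bin/env Rscript
# Detect carbohydrate gene clusters in the annotated catalog: maximal runs
# of signature genes (CAZyme/transporter/TF) with at most five intervening
# non-signature genes, kept when they contain at least one CAZyme and one
# transporter.

suppressPackageStartupMessages(library(prebioresponse))

catalog <- read_catalog("results/data/catalog.gff3")
cgcs <- find_cgcs(catalog, cgc_params(max_gap = 5))
write_tsv_dot(cgcs, "results/cgc_summary.tsv")

message(sprintf("%d clusters on %d contigs (catalog: %d genes)",
                nrow(cgcs), length(unique(cgcs$contig_id)), nrow(catalog)))
message(sprintf("composition: median %d members, %d-%d CAZymes, %d-%d transporters",
                median(lengths(cgcs$member_gene_ids)),
                min(cgcs$n_cazyme), max(cgcs$n_cazyme),
                min(cgcs$n_tc), max(cgcs$n_tc)))
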