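# Shared fixtures and independent oracles, built in code at test time.

# Random annotation catalog independent of the package generator: plain
# uniform signatures, fixed-length genes, used for oracle-equivalence tests.
random_catalog <- function(n_contigs, genes_per_contig, seed,
                           p_sig = c(CAZYME = 0.15, TC = 0.12, TF = 0.05)) {
  set.seed(seed)
  rows <- lapply(seq_len(n_contigs), function(ci) {
    sig <- sample(c(names(p_sig), "NONE"), genes_per_contig, replace = TRUE,
                  prob = c(p_sig, 1 - sum(p_sig)))
    start <- seq(1, by = 1500, length.out = genes_per_contig)
    tibble::tibble(
      gene_id = sprintf("c%03d_g%03d", ci, seq_len(genes_per_contig)),
      contig_id = sprintf("c%03d", ci),
      order_index = seq_len(genes_per_contig) - 1L,
      start_bp = start, end_bp = start + 999L,
      strand = "+",
      signature = sig,
      cazy_families = ifelse(sig == "CAZYME", "GH13", ""),
      ec_numbers = "", ec_names = "",
      taxon = "unclassified"
    )
  })
  do.call(rbind, rows)
}

# Exhaustive brute-force CGC enumeration: every window starting and ending
# at a signature gene is examined for the gap and composition rules, and
# only maximal windows are kept. O(n^2) per contig; the oracle for find_cgcs.
brute_force_cgcs <- function(catalog, max_gap = 5) {
  out <- list()
  for (ct in unique(catalog$contig_id)) {
    dc <- catalog[catalog$contig_id == ct, ]
    sig <- which(dc$signature %in% c("CAZYME", "TC", "TF"))
    ok_window <- function(a, b) {
      # a, b: indices into sig; window spans genes sig[a]..sig[b]
      members <- sig[a:b]
      gaps <- diff(members) - 1L
      if (length(gaps) && any(gaps > max_gap)) return(FALSE)
      s <- dc$signature[members]
      any(s == "CAZYME") && any(s == "TC")
    }
    gap_ok <- function(a, b) {
      members <- sig[a:b]
      gaps <- diff(members) - 1L
      !(length(gaps) && any(gaps > max_gap))
    }
    m <- length(sig)
    for (a in seq_len(m)) {
      for (b in a:m) {
        if (!gap_ok(a, b)) next
        # maximal: cannot extend with the adjacent signature gene
        if (a > 1 && sig[a] - sig[a - 1] - 1L <= max_gap) next
        if (b < m && sig[b + 1] - sig[b] - 1L <= max_gap) next
        if (!ok_window(a, b)) next
        out[[length(out) + 1L]] <- dc$gene_id[seq(sig[a], sig[b])]
      }
    }
  }
  out
}

# Canonical form for comparing cluster member lists.
member_key <- function(members) vapply(members, paste, "", collapse = "|")

default_substrates <- c("FOS", "INU", "XOS")

planted_signature_genes <- function(truth, substrate) {
  pg <- truth$planted_genes
  pg$gene_id[pg$substrate == substrate & pg$member_role != "NONE"]
}

# Reduced SVM configuration for test-speed model fits; the statistical
# design (stratified 50:50 split, repeated stratified 5-fold CV, grid
# search) is unchanged, only the grid and repeat counts are smaller.
test_svm_config <- function(seed = 1L, n_models = 10, cv_repeats = 2,
                            n_permutations = 10) {
  svm_config(cost_grid = 2^seq(-2, 6, 2), sigma_factors = c(0.5, 1, 2),
             cv_repeats = cv_repeats, n_models = n_models,
             n_permutations = n_permutations, seed = seed)
}
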