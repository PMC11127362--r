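make_catalog <- function(signatures, contig = "c1") {
  n <- length(signatures)
  start <- seq(1, by = 1500, length.out = n)
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", contig, seq_len(n)), contig_id = contig,
    order_index = seq_len(n) - 1L, start_bp = start, end_bp = start + 999L,
    strand = "+", signature = signatures,
    cazy_families = ifelse(signatures == "CAZYME", "GH43", ""),
    ec_numbers = "", ec_names = "", taxon = "t"
  )
}

test_that("gap threshold of five non-signature genes is the cluster boundary", {
  within <- make_catalog(c("CAZYME", rep("NONE", 5), "TC"))
  res <- find_cgcs(within)
  expect_equal(nrow(res), 1)
  expect_identical(res$member_gene_ids[[1]], within$gene_id)

  beyond <- make_catalog(c("CAZYME", rep("NONE", 6), "TC"))
  expect_equal(nrow(find_cgcs(beyond)), 0)

  # composition: a run without a transporter is not a cluster
  no_tc <- make_catalog(c("CAZYME", "NONE", "CAZYME", "TF"))
  expect_equal(nrow(find_cgcs(no_tc)), 0)
  # TF keeps the run alive but cannot satisfy the TC requirement
  tf_bridge <- make_catalog(c("CAZYME", rep("NONE", 4), "TF", rep("NONE", 4), "TC"))
  expect_equal(nrow(find_cgcs(tf_bridge)), 1)

  expect_equal(nrow(find_cgcs(within[0, ])), 0)
  shuffled <- within[c(2, 1, 3:7), ]
  expect_error(find_cgcs(shuffled), "sorted")
})

test_that("find_cgcs equals exhaustive brute-force enumeration", {
  for (seed in 1:6) {
    cat <- random_catalog(20, 20, seed)
    res <- find_cgcs(cat)
    oracle <- brute_force_cgcs(cat)
    expect_setequal(member_key(res$member_gene_ids), member_key(oracle))
  }
})

test_that("find_cgcs is idempotent and invariant to contig order", {
  cat <- random_catalog(10, 15, 99)
  a <- find_cgcs(cat)
  perm <- unique(cat$contig_id)[c(5, 1, 9, 2, 10, 3, 8, 4, 7, 6)]
  cat2 <- do.call(rbind, lapply(perm, function(ct) cat[cat$contig_id == ct, ]))
  b <- find_cgcs(cat2)
  expect_setequal(member_key(a$member_gene_ids), member_key(b$member_gene_ids))
  # composition and gap constraints hold on the output alone
  for (i in seq_len(nrow(a))) {
    m <- cat[match(a$member_gene_ids[[i]], cat$gene_id), ]
    sig_pos <- which(m$signature != "NONE")
    expect_equal(sig_pos[1], 1)
    expect_equal(sig_pos[length(sig_pos)], nrow(m))
    expect_true(all(diff(sig_pos) - 1 <= 5))
    expect_gte(a$n_cazyme[i], 1)
    expect_gte(a$n_tc[i], 1)
  }
})

test_that("substrate filter applies whitelist then enzyme-name exclusions", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    cazy_families = c("GH43", "GH3", "GH43_12", "GH13"),
    ec_numbers = c("3.2.1.37", "3.2.1.21", "3.2.1.37", "3.2.1.1"),
    ec_names = c("beta-xylosidase", "beta-glucosidase", "beta-xylosidase",
                 "alpha-amylase")
  )
  kept <- substrate_gene_filter(genes, substrate_spec("XOS"))
  expect_identical(kept$gene_id, c("g1", "g3"))   # subfamily matches parent
  # blacklist matches by EC number even with a novel name
  genes$ec_names[2] <- "putative hydrolase"
  expect_identical(substrate_gene_filter(genes, substrate_spec("XOS"))$gene_id,
                   c("g1", "g3"))
  expect_equal(nrow(substrate_gene_filter(genes[0, ], substrate_spec("XOS"))), 0)
  expect_error(substrate_spec("PECTIN"), "unknown substrate")

  # monotone cascade: a larger whitelist never removes a kept gene
  small <- substrate_gene_filter(genes, substrate_spec("XOS", family_whitelist = "GH43"))
  big <- substrate_gene_filter(genes, substrate_spec("XOS"))
  expect_true(all(small$gene_id %in% big$gene_id))
})

test_that("responder-association filter keeps positive significant genes", {
  da <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       log2fc = c(2, -2, 1, 0.5),
                       q = c(0.01, 0.01, 0.2, NA))
  expect_identical(responder_association_filter(da), "a")
})

test_that("whole clusters are selected and named per substrate", {
  cat <- make_catalog(c("CAZYME", "NONE", "TC", "NONE", "NONE", "NONE",
                        "NONE", "NONE", "NONE", "CAZYME", "TC"))
  cgcs <- find_cgcs(cat)
  expect_equal(nrow(cgcs), 2)
  sel <- clusters_for_genes(cat$gene_id[1], cgcs, "XOS")
  expect_equal(nrow(sel$clusters), 1)
  # one retained gene pulls in the entire cluster
  expect_identical(sel$clusters$member_gene_ids[[1]], cat$gene_id[1:3])
  both <- clusters_for_genes(cat$gene_id[c(1, 10)], cgcs, "XOS")
  expect_identical(both$clusters$substrate_cgc_id, c("XCGC1", "XCGC2"))
  none <- clusters_for_genes(character(0), cgcs, "XOS")
  expect_equal(nrow(none$clusters), 0)
  expect_warning(clusters_for_genes(cat$gene_id[5], cgcs, "XOS"), "outside")
})

test_that("cluster copy number sums member genes with non-detects as zero", {
  m <- matrix(c(1e3, 1e3, 0, 500, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("gA", "gB", "gC")))
  expect_equal(cluster_copy_number(m, c("gA", "gB", "gC")),
               c(s1 = 2e3, s2 = 500))
  expect_equal(cluster_copy_number(m["s2", , drop = FALSE], c("gB", "gC")),
               c(s2 = 0))
  expect_error(cluster_copy_number(m, "gZ"), "no assayed")
  set.seed(1)
  r <- matrix(rpois(60, 100), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  members <- paste0("g", c(2, 5, 9))
  expect_equal(cluster_copy_number(r, members),
               apply(r[, members], 1, sum))
})
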