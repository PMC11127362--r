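test_that("generators are deterministic and validate parameters", {
  p <- sim_params(seed = 7)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$scfa, b$scfa)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr$copy_numbers, b$qpcr$copy_numbers)

  expect_error(sim_params(n_subjects = 0), "n_subjects")
  expect_error(sim_params(timepoints_h = numeric(0)), "timepoints_h")
  expect_error(sim_params(delta_ab_responder = 0, delta_ab_nonresponder = 0),
               "exceed")
  expect_error(sim_params(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_params(qpcr_curve_slope = 1), "slope")
  expect_error(sim_params(genes_per_contig = 3), "wider")
})

test_that("scfa tables have full design coverage and planted effect size", {
  p <- sim_params(seed = 1, delta_ab_responder = 20, residual_sd = 3)
  out <- simulate_scfa(p)
  scfa <- out$scfa
  # conservation: every subject in every arm x replicate x timepoint
  expect_equal(nrow(scfa), 40 * 4 * 2 * 4)
  expect_true(all(table(scfa$subject_id, scfa$treatment) == 8))
  expect_true(all(scfa$acetate_mM >= 0 & scfa$butyrate_mM >= 0 &
                    scfa$propionate_mM >= 0))
  # pH decreases and % fermented increases with acetate+butyrate
  ab <- scfa$acetate_mM + scfa$butyrate_mM
  expect_lt(cor(ab, scfa$pH), -0.5)
  expect_gt(cor(ab, scfa$pct_fermented), 0.5)

  # empirical responder effect close to the generating mean (Monte Carlo
  # over several seeds to average out cohort noise)
  deltas <- unlist(lapply(1:5, function(s) {
    o <- simulate_scfa(sim_params(seed = s, delta_ab_responder = 20, residual_sd = 3))
    d <- o$scfa; d$ab <- d$acetate_mM + d$butyrate_mM
    m <- aggregate(ab ~ subject_id + treatment, d, mean)
    np <- m$ab[match(paste(m$subject_id, "NP"), paste(m$subject_id, m$treatment))]
    tr <- o$truth$phenotype
    r <- tr[tr$phenotype == "R", ]
    m$delta <- m$ab - np
    m$delta[match(paste(r$subject_id, r$substrate), paste(m$subject_id, m$treatment))]
  }))
  expect_equal(mean(deltas), 20, tolerance = 1 / 20)
})

test_that("no-effect generator yields indistinguishable phenotype groups", {
  p <- sim_params(seed = 11, delta_ab_responder = 1e-9,
                  delta_ab_nonresponder = 0)
  pv <- vapply(1:20, function(s) {
    p$seed <- s
    o <- simulate_scfa(p)
    d <- o$scfa; d$ab <- d$acetate_mM + d$butyrate_mM
    m <- aggregate(ab ~ subject_id + treatment, d, mean)
    np <- m$ab[match(paste(m$subject_id, "NP"), paste(m$subject_id, m$treatment))]
    delta <- m$ab - np
    keep <- m$treatment != "NP"
    tr <- o$truth$phenotype
    lab <- tr$phenotype[match(paste(m$subject_id, m$treatment)[keep],
                              paste(tr$subject_id, tr$substrate))]
    t.test(delta[keep][lab == "R"], delta[keep][lab == "NR"])$p.value
  }, 0)
  # under no effect the two-sample p-values are approximately uniform
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("gene catalog plants isolated clusters exactly once", {
  p <- sim_params(seed = 2)
  out <- simulate_gene_catalog(p)
  cat <- out$catalog
  # coordinates strictly increasing and non-overlapping within contigs
  for (ct in unique(cat$contig_id)) {
    d <- cat[cat$contig_id == ct, ]
    expect_true(all(diff(d$start_bp) > 0))
    expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
    expect_true(all(d$start_bp <= d$end_bp))
  }
  # every planted gene exists exactly once in the catalog
  pg <- out$truth$planted_genes
  expect_true(all(pg$gene_id %in% cat$gene_id))
  expect_false(any(duplicated(pg$gene_id)))
  # planted layout is written verbatim at its position
  pc <- out$truth$planted_cgcs[[1]]
  idx <- match(pc$member_gene_ids, cat$gene_id)
  lay <- pg$member_role[pg$planted_cgc == pc$id]
  expect_identical(cat$signature[idx],
                   ifelse(lay %in% c("TC", "TF", "NONE"), lay, "CAZYME"))
  # signature invariant
  expect_identical(cat$signature == "CAZYME", cat$cazy_families != "")

  # zero planted specs -> empty planted truth
  p0 <- sim_params(seed = 2, planted_cgc_specs = list())
  out0 <- simulate_gene_catalog(p0)
  expect_equal(nrow(out0$truth$planted_genes), 0)
})

test_that("count matrix is NB with planted fold change and Poisson limit", {
  p <- sim_params(seed = 3)
  co <- simulate_cohort(p)
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_identical(colnames(co$counts), co$samples$sample_id)

  # dispersion -> 0 limit: variance/mean ratio -> 1 across Poisson draws
  p0 <- sim_params(seed = 3, nb_dispersion = 1e-9, n_contigs = 10,
                   count_depth_range = c(1, 1), count_base_sdlog = 0)
  co0 <- simulate_cohort(p0)
  bg <- setdiff(rownames(co0$counts), co0$truth$planted_genes$gene_id)
  vm <- apply(co0$counts[bg, ], 1, var) / rowMeans(co0$counts[bg, ])
  expect_equal(mean(vm), 1, tolerance = 0.05)

  # planted log2 fold change is recovered by a normalized-mean estimator
  lfc <- unlist(lapply(1:3, function(s) {
    ps <- sim_params(seed = s)
    cs <- simulate_cohort(ps)
    sapply(ps$substrates, function(sub) {
      sm <- cs$samples[cs$samples$substrate == sub, ]
      cts <- cs$counts[, sm$sample_id]
      sf <- size_factors(cts)
      q <- sweep(cts, 2, sf, "/")
      g <- planted_signature_genes(cs$truth, sub)
      log2(rowMeans(q[g, sm$phenotype == "R"]) / rowMeans(q[g, sm$phenotype == "NR"]))
    })
  }))
  expect_lt(abs(median(lfc) - 2), 0.3)
})

test_that("qpcr simulation respects detection model and standard curve", {
  p <- sim_params(seed = 4, nonresponder_detect_prob = 0)
  co <- simulate_cohort(p)
  cn <- co$qpcr$copy_numbers
  tr <- co$truth$phenotype
  nr <- merge(cn[cn$role == "planted", ], tr, by = c("subject_id", "substrate"))
  expect_true(all(!nr$detected[nr$phenotype == "NR"]))
  expect_true(all(nr$detected[nr$phenotype == "R"]))
  # non-detect wells carry NA CT, never 0
  expect_true(all(is.na(co$qpcr$wells$ct[!co$qpcr$wells$detected])))
  expect_true(all(co$qpcr$wells$ct[co$qpcr$wells$detected] > 0))

  # noiseless CT inverts exactly back to planted copies
  p0 <- sim_params(seed = 4, qpcr_ct_sd = 0)
  co0 <- simulate_cohort(p0)
  w <- co0$qpcr$wells[co0$qpcr$wells$detected, ]
  cn0 <- co0$qpcr$copy_numbers
  planted <- cn0$copies[match(paste(w$sample_id, w$target_gene),
                              paste(cn0$subject_id, cn0$gene_id))]
  est <- quantify_unknown(co0$qpcr$curve, w$ct)$copies
  expect_equal(est, planted, tolerance = 1e-9)

  # responder subject-level mean log10 copies near the generating mean
  r <- merge(cn[cn$role == "planted", ], tr, by = c("subject_id", "substrate"))
  l10 <- log10(r$copies[r$phenotype == "R"])
  se3 <- 3 * p$qpcr_sd / sqrt(length(l10))
  expect_lt(abs(mean(l10) - p$qpcr_mu_log10_responder), se3 + 0.02)
})
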