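#' Synthetic fermentation cohorts with planted ground truth
#'
#' The generators in this file emulate the data products of an in vitro
#' fermentation screen: SCFA tables per subject x treatment x replicate x
#' timepoint, a dbCAN2-style annotated gene catalog with planted
#' carbohydrate gene clusters, negative-binomially overdispersed gene x
#' sample count matrices, and qPCR copy-number / CT tables generated from a
#' log-linear standard curve. Every generator is deterministic given
#' `params$seed`, and the planted truth it returns drives parameter-recovery
#' tests downstream.
#'
#' @name synthetic-cohort
NULL

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Draw responder/non-responder phenotype truth
#'
#' Latent Gaussian copula: each subject has a shared latent factor so
#' responder status is correlated across substrates (shared-responder
#' structure), with marginal prevalence `responder_prevalence`.
#'
#' @param params A [sim_params()] object.
#' @return Tibble with columns `subject_id`, `substrate`, `phenotype`
#'   ("R"/"NR").
#' @export
simulate_phenotype_truth <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_subjects
  subs <- params$substrates
  rho <- params$phenotype_correlation
  u <- stats::rnorm(n)
  out <- list()
  for (s in subs) {
    z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
    lab <- ifelse(z < stats::qnorm(params$responder_prevalence), "R", "NR")
    out[[s]] <- tibble::tibble(subject_id = subject_ids(n), substrate = s, phenotype = lab)
  }
  do.call(rbind, out)
}

#' Simulate SCFA fermentation tables
#'
#' Additive Gaussian model on baseline-subtracted concentrations: subject
#' random intercept + treatment effect + additive time drift + residual,
#' clipped at zero. Responders to a substrate receive a mean
#' acetate+butyrate increase of `delta_ab_responder` mM over the NP control
#' arm (split 65:35 acetate:butyrate); non-responders receive
#' `delta_ab_nonresponder`. pH decreases affinely with acetate+butyrate and
#' the percentage of carbohydrate fermented increases affinely, both plus
#' noise, so their correlation signs match fermentation chemistry.
#'
#' @param params A [sim_params()] object.
#' @param truth Optional phenotype truth from [simulate_phenotype_truth()];
#'   drawn internally (same seed) when omitted.
#' @return `list(scfa = tibble of measurements, truth = list(phenotype = ...))`.
#' @export
simulate_scfa <- function(params, truth = NULL) {
  validate_sim_params(params)
  if (is.null(truth)) truth <- simulate_phenotype_truth(params)
  set.seed(params$seed + 1000L)
  n <- params$n_subjects
  ids <- subject_ids(n)
  arms <- c(params$substrates, "NP")
  tps <- sort(params$timepoints_h)
  reps <- seq_len(params$replicates)

  pheno <- matrix("NR", n, length(params$substrates),
                  dimnames = list(ids, params$substrates))
  pheno[cbind(truth$subject_id, truth$substrate)] <- truth$phenotype

  b_subj <- stats::setNames(stats::rnorm(n, 0, params$subject_sd), ids)

  grid <- expand.grid(subject_id = ids, treatment = arms, replicate = reps,
                      timepoint_h = tps, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$treatment, grid$replicate, grid$timepoint_h), ]
  m <- nrow(grid)

  delta <- numeric(m)
  is_trt <- grid$treatment != "NP"
  resp <- is_trt & pheno[cbind(grid$subject_id, ifelse(is_trt, grid$treatment, params$substrates[1]))] == "R"
  delta[is_trt] <- params$delta_ab_nonresponder
  delta[resp] <- params$delta_ab_responder

  cycle <- match(grid$timepoint_h, tps) - 1L
  base_ac <- 15; base_bu <- 6; base_pr <- 0.8
  ac <- base_ac + b_subj[grid$subject_id] + 0.65 * delta +
    params$time_slope_mM * cycle + stats::rnorm(m, 0, params$residual_sd)
  bu <- base_bu + 0.4 * b_subj[grid$subject_id] + 0.35 * delta +
    stats::rnorm(m, 0, params$residual_sd)
  pr <- base_pr + stats::rnorm(m, 0, 0.3)
  ac <- pmax(ac, 0); bu <- pmax(bu, 0); pr <- pmax(pr, 0)

  ab <- ac + bu
  ph <- pmin(pmax(7.4 - 0.045 * ab + stats::rnorm(m, 0, 0.15), 4), 9.5)
  pf <- pmin(pmax(15 + 1.5 * ab + stats::rnorm(m, 0, 5), 0), 100)

  scfa <- tibble::tibble(
    subject_id = grid$subject_id, treatment = grid$treatment,
    replicate = grid$replicate, timepoint_h = grid$timepoint_h,
    acetate_mM = ac, butyrate_mM = bu, propionate_mM = pr,
    pH = ph, pct_fermented = pf
  )
  list(scfa = scfa, truth = list(phenotype = truth))
}

random_background_signature <- function(n, rates) {
  r <- stats::runif(n)
  sig <- rep("NONE", n)
  sig[r < rates["cazyme"] + rates["tc"] + rates["tf"]] <- "TF"
  sig[r < rates["cazyme"] + rates["tc"]] <- "TC"
  sig[r < rates["cazyme"]] <- "CAZYME"
  sig
}

# Background CAZyme pool: mixes irrelevant families with whitelist-family
# decoys whose enzyme names sit on the EC-name exclusion list, so the
# filtering cascade has true negatives to reject.
background_cazyme_pool <- function() {
  list(
    list(family = "GH13", ec = "3.2.1.1",  name = "alpha-amylase"),
    list(family = "GT2",  ec = "2.4.1.-",  name = "glycosyltransferase"),
    list(family = "CE1",  ec = "3.1.1.72", name = "acetyl xylan esterase"),
    list(family = "GH77", ec = "2.4.1.25", name = "4-alpha-glucanotransferase"),
    list(family = "GH1",  ec = "3.2.1.21", name = "beta-glucosidase"),
    list(family = "GH3",  ec = "3.2.1.21", name = "beta-glucosidase"),
    list(family = "GH2",  ec = "3.2.1.23", name = "beta-galactosidase"),
    list(family = "GH2",  ec = "3.2.1.25", name = "beta-mannosidase"),
    list(family = "GH3",  ec = "3.2.1.52", name = "beta-N-acetylhexosaminidase"),
    list(family = "GH43", ec = "3.2.1.99", name = "arabinan endo-1,5-alpha-L-arabinosidase")
  )
}

planted_enzyme_annotation <- function(family) {
  fam <- sub("_.*$", "", family)
  switch(fam,
    GH32 = c("3.2.1.26", "beta-fructofuranosidase"),
    GH68 = c("2.4.1.10", "levansucrase"),
    GH91 = c("4.2.2.18", "inulin lyase"),
    GH43 = c("3.2.1.37", "beta-xylosidase"),
    GH120 = c("3.2.1.37", "beta-xylosidase"),
    GH8 = c("3.2.1.8", "endo-1,4-beta-xylanase"),
    GH10 = c("3.2.1.8", "endo-1,4-beta-xylanase"),
    c("3.2.1.-", "glycoside hydrolase")
  )
}

taxon_pool <- function() {
  c("Bifidobacterium adolescentis", "Bifidobacterium longum",
    "Bifidobacterium pseudocatenulatum", "Bacteroides ovatus",
    "Streptococcus pasteurianus", "Escherichia coli",
    "Clostridium butyricum", "Citrobacter freundii")
}

#' Simulate an annotated gene catalog with planted gene clusters
#'
#' Emits a dbCAN2/Prokka-style annotation table: contigs carry ordered genes
#' with non-overlapping, strictly increasing 1-based inclusive coordinates;
#' background genes receive random signatures (CAZYME/TC/TF/NONE) at the
#' configured rates, with decoy CAZymes carrying enzyme names on the
#' exclusion list; each planted cluster layout is written onto its own
#' contig at a random offset, satisfying the cluster rule (>= 1 CAZyme,
#' >= 1 transporter, gaps <= 5 non-signature genes). Planted genes are
#' annotated to Bifidobacterium taxa.
#'
#' @param params A [sim_params()] object.
#' @return `list(catalog = tibble of gene features, truth = list(
#'   planted_genes, planted_cgcs, decoy_targets))`.
#' @export
simulate_gene_catalog <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed + 2000L)
  nc <- params$n_contigs
  gpc <- params$genes_per_contig
  specs <- params$planted_cgc_specs
  if (length(specs) > nc) stop("more planted clusters than contigs", call. = FALSE)
  pool <- background_cazyme_pool()
  taxa <- taxon_pool()
  bif_taxa <- taxa[startsWith(taxa, "Bifidobacterium")]

  rows <- vector("list", nc)
  planted_rows <- list()
  planted_cgcs <- list()
  gid <- 0L
  for (ci in seq_len(nc)) {
    contig <- sprintf("contig_%03d", ci)
    sig <- random_background_signature(gpc, params$background_signature_rates)
    fam <- character(gpc); ecn <- character(gpc); ecna <- character(gpc)
    tax <- sample(taxa, gpc, replace = TRUE)
    bg_caz <- which(sig == "CAZYME")
    for (j in bg_caz) {
      a <- pool[[sample.int(length(pool), 1)]]
      fam[j] <- a$family; ecn[j] <- a$ec; ecna[j] <- a$name
    }
    plant_members <- integer(0)
    if (ci <= length(specs)) {
      lay <- specs[[ci]]$layout
      off <- sample.int(gpc - length(lay) + 1L, 1)
      idx <- seq(off, length.out = length(lay))
      # isolate the planted run: clear background signatures within 6 genes
      # on each side so the cluster rule (gap <= 5) cannot merge neighbours
      buffer <- setdiff(seq(max(1L, off - 6L), min(gpc, off + length(lay) - 1L + 6L)), idx)
      sig[buffer] <- "NONE"
      fam[buffer] <- ""; ecn[buffer] <- ""; ecna[buffer] <- ""
      sig[idx] <- ifelse(lay %in% c("TC", "TF", "NONE"), lay, "CAZYME")
      fam[idx] <- ifelse(sig[idx] == "CAZYME", lay, "")
      tax[idx] <- sample(bif_taxa, 1)
      for (j in seq_along(idx)) {
        if (sig[idx[j]] == "CAZYME") {
          ann <- planted_enzyme_annotation(lay[j])
          ecn[idx[j]] <- ann[1]; ecna[idx[j]] <- ann[2]
        } else {
          ecn[idx[j]] <- ""; ecna[idx[j]] <- ""
        }
      }
      plant_members <- idx
    }
    len <- sample(600:3000, gpc, replace = TRUE)
    gap <- sample(20:400, gpc, replace = TRUE)
    start <- cumsum(c(1L, (len + gap)[-gpc]))
    end <- start + len - 1L
    ids <- sprintf("GID_%05d", gid + seq_len(gpc))
    gid <- gid + gpc
    rows[[ci]] <- tibble::tibble(
      gene_id = ids, contig_id = contig, order_index = seq_len(gpc) - 1L,
      start_bp = start, end_bp = end,
      strand = sample(c("+", "-"), gpc, replace = TRUE),
      signature = sig, cazy_families = fam, ec_numbers = ecn,
      ec_names = ecna, taxon = tax
    )
    if (length(plant_members)) {
      lay <- specs[[ci]]$layout
      sig_members <- ids[plant_members][lay != "NONE"]
      planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
        substrate = specs[[ci]]$substrate,
        gene_id = ids[plant_members],
        member_role = lay,
        planted_cgc = sprintf("planted_%02d", ci)
      )
      planted_cgcs[[length(planted_cgcs) + 1L]] <- list(
        id = sprintf("planted_%02d", ci), substrate = specs[[ci]]$substrate,
        contig_id = contig, member_gene_ids = ids[plant_members],
        signature_gene_ids = sig_members
      )
    }
  }
  catalog <- do.call(rbind, rows)
  planted_genes <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    tibble::tibble(substrate = character(), gene_id = character(),
                   member_role = character(), planted_cgc = character())

  # decoy assay targets: background genes outside any planted cluster, with
  # copy numbers independent of phenotype downstream
  non_planted <- setdiff(catalog$gene_id, planted_genes$gene_id)
  decoys <- list()
  for (s in params$substrates) {
    k <- min(params$n_decoy_targets, length(non_planted))
    pick <- sample(non_planted, k)
    non_planted <- setdiff(non_planted, pick)
    decoys[[s]] <- tibble::tibble(substrate = s, gene_id = pick)
  }
  decoy_targets <- do.call(rbind, decoys)

  list(catalog = catalog,
       truth = list(planted_genes = planted_genes,
                    planted_cgcs = planted_cgcs,
                    decoy_targets = decoy_targets))
}

#' Simulate a gene x sample count matrix
#'
#' Salmon-style quantification analog: one metagenome sample per subject x
#' substrate fermentation; counts are negative binomial with per-gene
#' log-normal baseline means, per-sample depth factors drawn uniformly from
#' `count_depth_range`, and an expected log2 fold change of
#' `planted_log2fc` for substrate-planted genes in samples whose subject
#' responds to that substrate.
#'
#' @param catalog Gene catalog from [simulate_gene_catalog()].
#' @param truth Combined truth list carrying `phenotype` and `planted_genes`.
#' @param params A [sim_params()] object.
#' @return `list(counts = integer matrix genes x samples, samples = tibble
#'   of sample metadata)`.
#' @export
simulate_counts <- function(catalog, truth, params) {
  validate_sim_params(params)
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  set.seed(params$seed + 3000L)
  pheno <- truth$phenotype
  samples <- tibble::tibble(
    sample_id = paste(pheno$subject_id, pheno$substrate, sep = "_"),
    subject_id = pheno$subject_id, substrate = pheno$substrate,
    phenotype = pheno$phenotype
  )
  G <- nrow(catalog); S <- nrow(samples)
  base <- stats::rlnorm(G, params$count_base_meanlog, params$count_base_sdlog)
  depth <- stats::runif(S, params$count_depth_range[1], params$count_depth_range[2])
  mu <- outer(base, depth)
  pg <- truth$planted_genes
  if (nrow(pg)) {
    for (s in unique(pg$substrate)) {
      gidx <- match(pg$gene_id[pg$substrate == s], catalog$gene_id)
      sidx <- which(samples$substrate == s & samples$phenotype == "R")
      if (length(gidx) && length(sidx)) {
        mu[gidx, sidx] <- mu[gidx, sidx] * 2^params$planted_log2fc
      }
    }
  }
  counts <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / params$nb_dispersion),
                   G, S, dimnames = list(catalog$gene_id, samples$sample_id))
  list(counts = counts, samples = samples)
}

#' Simulate qPCR copy numbers and well-level CT values
#'
#' For each substrate the assay panel is that substrate's planted signature
#' genes plus phenotype-independent decoy targets. Responders' planted
#' targets have log10 copies ~ Normal(`qpcr_mu_log10_responder`, `qpcr_sd`);
#' non-responders are non-detect with probability
#' `1 - nonresponder_detect_prob`, else low copy. Well CT values are
#' generated by inverting the configured log-linear standard curve plus
#' Gaussian technical noise; non-detects are encoded as `NA` CT with a
#' `detected = FALSE` flag, never as CT 0.
#'
#' @param truth Combined truth list with `phenotype`, `planted_genes` and
#'   `decoy_targets`.
#' @param params A [sim_params()] object.
#' @param n_wells Technical replicate wells per subject x target.
#' @return `list(copy_numbers = tibble (subject x target long form),
#'   wells = tibble of CT wells, curve = the generating standard curve)`.
#' @export
simulate_qpcr <- function(truth, params, n_wells = 2) {
  validate_sim_params(params)
  set.seed(params$seed + 4000L)
  pheno <- truth$phenotype
  pg <- truth$planted_genes
  targets <- rbind(
    tibble::tibble(substrate = pg$substrate[pg$member_role != "NONE"],
                   gene_id = pg$gene_id[pg$member_role != "NONE"],
                   role = "planted"),
    tibble::tibble(substrate = truth$decoy_targets$substrate,
                   gene_id = truth$decoy_targets$gene_id, role = "decoy")
  )
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    s <- targets$substrate[i]
    ph <- pheno[pheno$substrate == s, ]
    n <- nrow(ph)
    if (targets$role[i] == "planted") {
      is_r <- ph$phenotype == "R"
      det <- ifelse(is_r, TRUE, stats::runif(n) < params$nonresponder_detect_prob)
      l10 <- ifelse(is_r,
                    stats::rnorm(n, params$qpcr_mu_log10_responder, params$qpcr_sd),
                    stats::rnorm(n, params$qpcr_mu_log10_nonresponder, params$qpcr_sd))
    } else {
      det <- stats::runif(n) < 0.5
      l10 <- stats::rnorm(n, 2, params$qpcr_sd)
    }
    copies <- ifelse(det, 10^pmax(l10, 0), 0)
    rows[[i]] <- tibble::tibble(
      subject_id = ph$subject_id, substrate = s,
      gene_id = targets$gene_id[i], role = targets$role[i],
      detected = det, copies = copies
    )
  }
  cn <- do.call(rbind, rows)
  curve <- standard_curve(slope = params$qpcr_curve_slope,
                          intercept = params$qpcr_curve_intercept,
                          r2 = 1, dynamic_range = c(1, 8))
  wells <- cn[rep(seq_len(nrow(cn)), each = n_wells), ]
  wells$well_replicate <- rep(seq_len(n_wells), nrow(cn))
  ct <- ifelse(wells$detected,
               curve$intercept + curve$slope * log10(pmax(wells$copies, 1)) +
                 stats::rnorm(nrow(wells), 0, params$qpcr_ct_sd),
               NA_real_)
  wells <- tibble::tibble(
    sample_id = wells$subject_id, substrate = wells$substrate,
    target_gene = wells$gene_id, well_replicate = wells$well_replicate,
    detected = wells$detected, ct = ct
  )
  list(copy_numbers = cn, wells = wells, curve = curve)
}

#' Simulate a complete cohort
#'
#' Runs all generators under one master seed and merges their truth tables.
#'
#' @param params A [sim_params()] object.
#' @return List with `scfa`, `catalog`, `counts`, `samples`, `qpcr`
#'   (copy_numbers/wells/curve) and the combined `truth`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  validate_sim_params(params)
  pheno <- simulate_phenotype_truth(params)
  sc <- simulate_scfa(params, truth = pheno)
  cat_out <- simulate_gene_catalog(params)
  truth <- c(list(phenotype = pheno), cat_out$truth)
  cnt <- simulate_counts(cat_out$catalog, truth, params)
  qp <- simulate_qpcr(truth, params)
  list(scfa = sc$scfa, catalog = cat_out$catalog, counts = cnt$counts,
       samples = cnt$samples, qpcr = qp, truth = truth, params = params)
}
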