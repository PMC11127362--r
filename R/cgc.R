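#' Parameters for carbohydrate gene cluster detection
#'
#' @param max_gap Maximum number of intervening non-signature genes allowed
#'   between consecutive signature genes of one cluster (default 5).
#' @param require_tc,require_cazyme Composition requirements (defaults TRUE:
#'   a cluster needs >= 1 transporter and >= 1 CAZyme).
#' @return List of class `cgc_params`.
#' @export
cgc_params <- function(max_gap = 5L, require_tc = TRUE, require_cazyme = TRUE) {
  stopifnot(max_gap >= 0)
  structure(list(max_gap = as.integer(max_gap), require_tc = isTRUE(require_tc),
                 require_cazyme = isTRUE(require_cazyme)),
            class = "cgc_params")
}

#' Detect carbohydrate gene clusters (CGCs) in a gene catalog
#'
#' Per contig, signature genes (CAZYME, TC, TF) are grouped into maximal
#' runs in which consecutive signature genes are separated by at most
#' `max_gap` non-signature genes; a run is kept when it contains at least
#' one CAZyme and at least one transporter (TF genes count as signature --
#' they do not break runs -- but do not satisfy the transporter
#' requirement). Cluster members are the signature genes plus the
#' intervening non-signature genes within the span; the first and last
#' members are always signature genes. Clusters never cross contigs, and
#' clusters touching contig ends are allowed.
#'
#' @param catalog GeneFeature table (as from [simulate_gene_catalog()] or
#'   [read_catalog()]); must be sorted by `order_index` within each contig.
#' @param params A [cgc_params()].
#' @return Tibble: one row per cluster with `cgc_id`, `contig_id`, counts of
#'   CAZyme/TC/TF members, bp span, and `member_gene_ids` (list column in
#'   contig order).
#' @export
find_cgcs <- function(catalog, params = cgc_params()) {
  d <- as.data.frame(catalog)
  if (nrow(d) == 0) {
    return(tibble::tibble(cgc_id = character(), contig_id = character(),
                          n_cazyme = integer(), n_tc = integer(), n_tf = integer(),
                          start_bp = integer(), end_bp = integer(),
                          member_gene_ids = list()))
  }
  for (ct in unique(d$contig_id)) {
    oi <- d$order_index[d$contig_id == ct]
    if (is.unsorted(oi, strictly = TRUE)) {
      stop("catalog not sorted by order_index within contig ", ct, call. = FALSE)
    }
  }
  rows <- list()
  cid <- 0L
  for (ct in unique(d$contig_id)) {
    dc <- d[d$contig_id == ct, ]
    sig_idx <- which(dc$signature %in% c("CAZYME", "TC", "TF"))
    if (!length(sig_idx)) next
    gaps <- diff(sig_idx) - 1L
    block <- cumsum(c(0L, gaps > params$max_gap))
    for (b in unique(block)) {
      run <- sig_idx[block == b]
      sigs <- dc$signature[run]
      if (params$require_cazyme && !any(sigs == "CAZYME")) next
      if (params$require_tc && !any(sigs == "TC")) next
      span <- seq(min(run), max(run))
      cid <- cid + 1L
      rows[[cid]] <- tibble::tibble(
        cgc_id = sprintf("CGC_%04d", cid), contig_id = ct,
        n_cazyme = sum(sigs == "CAZYME"), n_tc = sum(sigs == "TC"),
        n_tf = sum(sigs == "TF"),
        start_bp = dc$start_bp[min(run)], end_bp = dc$end_bp[max(run)],
        member_gene_ids = list(dc$gene_id[span])
      )
    }
  }
  if (!length(rows)) {
    return(find_cgcs(d[0, ], params))
  }
  do.call(rbind, rows)
}

#' Substrate specification: family whitelist and enzyme-name exclusions
#'
#' The default whitelists carry the substrate-relevant glycoside hydrolase
#' families (fructans: GH32, GH68, and GH91 for inulin; xylan/XOS: GH8,
#' GH10, GH43 with subfamilies, GH120, plus broader families GH1/GH2/GH3/
#' GH30/GH51/GH67/GH115 whose false positives are handled by the enzyme-name
#' exclusion list). The exclusion list drops genes annotated as
#' beta-glucosidase, beta-galactosidase, beta-mannosidase,
#' beta-N-acetylhexosaminidase or arabinan endo-1,5-alpha-L-arabinosidase,
#' matched by enzyme name or by the corresponding EC number.
#'
#' @param substrate One of "FOS", "INU", "XOS" (for defaults) or any name
#'   when `family_whitelist` is given.
#' @param family_whitelist Character set of CAZy families (subfamilies of a
#'   whitelisted family match by prefix).
#' @param ec_name_blacklist Named character vector mapping enzyme name to EC
#'   number; genes matching either are removed.
#' @return List of class `substrate_spec`.
#' @export
substrate_spec <- function(substrate, family_whitelist = NULL,
                           ec_name_blacklist = default_ec_blacklist()) {
  if (is.null(family_whitelist)) {
    defaults <- list(
      FOS = c("GH32", "GH68"),
      INU = c("GH32", "GH68", "GH91"),
      XOS = c("GH8", "GH10", "GH43", "GH120", "GH1", "GH2", "GH3",
              "GH30", "GH51", "GH67", "GH115")
    )
    if (!substrate %in% names(defaults)) {
      stop("unknown substrate '", substrate,
           "'; supply family_whitelist explicitly", call. = FALSE)
    }
    family_whitelist <- defaults[[substrate]]
  }
  stopifnot(length(family_whitelist) > 0)
  structure(list(substrate = substrate, family_whitelist = family_whitelist,
                 ec_name_blacklist = ec_name_blacklist),
            class = "substrate_spec")
}

#' @rdname substrate_spec
#' @export
default_ec_blacklist <- function() {
  c("beta-glucosidase" = "3.2.1.21",
    "beta-galactosidase" = "3.2.1.23",
    "beta-mannosidase" = "3.2.1.25",
    "beta-N-acetylhexosaminidase" = "3.2.1.52",
    "arabinan endo-1,5-alpha-L-arabinosidase" = "3.2.1.99")
}

split_multi <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE)

#' Filter an annotated gene table to substrate-specific candidates
#'
#' Keeps genes with at least one CAZy family on the substrate whitelist
#' (subfamilies such as GH43_12 match their parent family), then removes
#' genes whose enzyme names or EC numbers hit the exclusion list. Row order
#' is preserved.
#'
#' @param genes Table with `cazy_families`, `ec_names`, `ec_numbers`
#'   (comma-separated strings).
#' @param spec A [substrate_spec()].
#' @return The filtered table.
#' @export
substrate_gene_filter <- function(genes, spec) {
  d <- as.data.frame(genes)
  if (nrow(d) == 0) return(tibble::tibble(d))
  fams <- split_multi(d$cazy_families)
  hit <- vapply(fams, function(f) {
    any(f %in% spec$family_whitelist | sub("_.*$", "", f) %in% spec$family_whitelist)
  }, TRUE)
  d <- d[hit, , drop = FALSE]
  if (nrow(d)) {
    names_bl <- names(spec$ec_name_blacklist)
    ec_bl <- unname(spec$ec_name_blacklist)
    bad <- mapply(function(nm, ec) any(nm %in% names_bl) || any(ec %in% ec_bl),
                  split_multi(d$ec_names), split_multi(d$ec_numbers))
    d <- d[!bad, , drop = FALSE]
  }
  tibble::as_tibble(d)
}

#' Retain responder-associated genes from differential-abundance results
#'
#' Keeps genes whose fold change is elevated in responders (log2FC > 0, with
#' responders as numerator) at q below the threshold.
#'
#' @param da DaResult table from [nb_wald_test()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return Character vector of retained gene ids (in `da` order).
#' @export
responder_association_filter <- function(da, q_threshold = 0.05) {
  d <- as.data.frame(da)
  keep <- !is.na(d$q) & d$q < q_threshold & d$log2fc > 0
  d$gene_id[keep]
}

#' Select whole clusters containing retained genes
#'
#' Every cluster containing at least one retained gene is selected whole
#' (intact genetic machinery is required for carbohydrate uptake and
#' metabolism), and substrate-scoped identifiers are assigned in discovery
#' order: `<first letter of substrate>CGC<n>`.
#'
#' @param retained_genes Character vector of retained gene ids.
#' @param cgcs Cluster table from [find_cgcs()].
#' @param substrate Substrate name (its first letter prefixes the ids).
#' @return List: `clusters` (selected subset of `cgcs` with an added
#'   `substrate_cgc_id` column), `singletons` (retained genes in no
#'   cluster; a warning is emitted when nonempty).
#' @export
clusters_for_genes <- function(retained_genes, cgcs, substrate) {
  sel <- vapply(cgcs$member_gene_ids, function(m) any(retained_genes %in% m), TRUE)
  out <- cgcs[sel, , drop = FALSE]
  if (nrow(out)) {
    out$substrate_cgc_id <- sprintf("%sCGC%d", substr(substrate, 1, 1), seq_len(nrow(out)))
  } else {
    out$substrate_cgc_id <- character(0)
  }
  in_cluster <- unique(unlist(cgcs$member_gene_ids))
  singletons <- setdiff(retained_genes, in_cluster)
  if (length(singletons)) {
    warning("retained genes outside any cluster: ",
            paste(singletons, collapse = ", "))
  }
  list(clusters = out, singletons = singletons)
}

#' Per-sample cluster copy number
#'
#' Sums the qPCR copy numbers of a cluster's assayed member genes per
#' sample; non-detects contribute 0.
#'
#' @param copy_numbers Matrix samples x target genes (copies; non-detect
#'   already encoded as 0) or the long tibble from [simulate_qpcr()].
#' @param member_genes Gene ids of the cluster's assayed members.
#' @return Named numeric vector of per-sample totals.
#' @export
cluster_copy_number <- function(copy_numbers, member_genes) {
  if (!is.matrix(copy_numbers)) {
    copy_numbers <- copy_number_matrix(copy_numbers)
  }
  present <- intersect(member_genes, colnames(copy_numbers))
  if (!length(present)) stop("cluster has no assayed member genes", call. = FALSE)
  rowSums(copy_numbers[, present, drop = FALSE])
}

#' Pivot long qPCR copy numbers to a samples x genes matrix
#'
#' @param cn Long tibble with `subject_id`, `gene_id`, `copies` (non-detect
#'   rows carry 0 copies).
#' @return Numeric matrix subjects x target genes.
#' @export
copy_number_matrix <- function(cn) {
  d <- as.data.frame(cn)
  subj <- sort(unique(d$subject_id)); genes <- unique(d$gene_id)
  m <- matrix(0, length(subj), length(genes), dimnames = list(subj, genes))
  m[cbind(d$subject_id, d$gene_id)] <- d$copies
  m
}
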