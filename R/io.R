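#' Write a gene catalog as GFF3
#'
#' One `gene` feature per row with 1-based inclusive coordinates and the
#' attributes `ID`, `signature`, `CAZy`, `EC`, `ec_name`, `taxon`.
#' Multi-valued attributes are comma-separated; commas, semicolons, equals
#' signs and percent signs inside individual values are percent-encoded per
#' the GFF3 attribute rules.
#'
#' @param catalog GeneFeature tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  d <- as.data.frame(catalog)
  enc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    gsub(",", "%2C", x, fixed = TRUE)
  }
  enc_multi <- function(x) {
    vapply(split_multi(x), function(v) paste(enc(v), collapse = ","), "")
  }
  attr_str <- paste0(
    "ID=", enc(d$gene_id),
    ";signature=", d$signature,
    ";CAZy=", enc_multi(d$cazy_families),
    ";EC=", enc_multi(d$ec_numbers),
    ";ec_name=", enc_multi(d$ec_names),
    ";taxon=", enc(d$taxon)
  )
  lines <- c("##gff-version 3",
             paste(d$contig_id, "prebioresponse", "gene", d$start_bp, d$end_bp,
                   ".", d$strand, ".", attr_str, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

decode_pct <- function(x) {
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Read a gene catalog from GFF3 (or its TSV mirror)
#'
#' Parses a dbCAN2/Prokka-style annotation export carrying the attributes
#' `signature`, `CAZy`, `EC`, `ec_name`, `taxon`. The catalog is validated
#' (coordinates 1-based inclusive, start <= end, strictly increasing and
#' non-overlapping within contigs, unique gene ids) and sorted; the
#' per-contig `order_index` is derived from coordinates, never read.
#' Round-trips losslessly through [write_catalog()].
#'
#' @param path GFF3 file (`.gff3`/`.gff`) or TSV mirror.
#' @return Validated GeneFeature tibble.
#' @export
read_catalog <- function(path) {
  if (grepl("\\.tsv$", path)) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
    for (col in c("cazy_families", "ec_numbers", "ec_names")) {
      d[[col]][is.na(d[[col]])] <- ""
    }
    return(validate_catalog(tibble::as_tibble(d)))
  }
  raw <- readLines(path)
  feat <- which(!startsWith(raw, "#") & nzchar(raw))
  fields <- strsplit(raw[feat], "\t", fixed = TRUE)
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  bad <- which(!is.finite(st) | !is.finite(en) | st < 1 | st > en)
  if (length(bad)) {
    stop("invalid coordinates at lines ", paste(feat[bad], collapse = ", "),
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  need <- c("ID", "signature", "CAZy", "EC", "ec_name", "taxon")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("GFF3 is missing required attributes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  collapse <- function(col) {
    if (is.list(col) || methods::is(col, "List")) {
      vapply(as.list(col), function(v) paste(decode_pct(v), collapse = ","), "")
    } else {
      v <- decode_pct(as.character(col))
      ifelse(is.na(v), "", v)
    }
  }
  d <- tibble::tibble(
    gene_id = collapse(md$ID),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    order_index = NA_integer_,
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    signature = collapse(md$signature),
    cazy_families = collapse(md$CAZy),
    ec_numbers = collapse(md$EC),
    ec_names = collapse(md$ec_name),
    taxon = collapse(md$taxon)
  )
  validate_catalog(d)
}

validate_catalog <- function(d) {
  line_of <- function(i) i + 1L  # one ##gff-version header line
  dup <- duplicated(d$gene_id)
  if (any(dup)) {
    stop("duplicate gene ids (lines ",
         paste(line_of(which(d$gene_id %in% d$gene_id[dup])), collapse = ", "),
         "): ", paste(unique(d$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad <- which(d$start_bp > d$end_bp | d$start_bp < 1)
  if (length(bad)) {
    stop("invalid coordinates at lines ", paste(line_of(bad), collapse = ", "),
         call. = FALSE)
  }
  d <- d[order(d$contig_id, d$start_bp), ]
  for (ct in unique(d$contig_id)) {
    i <- which(d$contig_id == ct)
    if (length(i) > 1 && any(d$start_bp[i][-1] <= d$end_bp[i][-length(i)])) {
      stop("overlapping genes on contig ", ct, call. = FALSE)
    }
    d$order_index[i] <- seq_along(i) - 1L
  }
  caz <- d$signature == "CAZYME"
  fam_empty <- d$cazy_families == ""
  if (any(caz & fam_empty) || any(!caz & !fam_empty)) {
    stop("signature CAZYME must coincide with a non-empty CAZy family list",
         call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Write a table as TSV with '.' for missing values
#'
#' @param x Data frame; list columns of character vectors are collapsed
#'   with commas.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_dot <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv_dot()]
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_tsv_dot <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = "."))
}
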