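#' Gene coordinate annotation
#'
#' Internal genomic coordinates are 0-based half-open (`[start, end)`),
#' converted at the reader boundary; BED files are taken as-is, GFF3 (1-based
#' closed) has 1 subtracted from the start.
#'
#' @param gene_symbol,chromosome,start,end,strand equal-length vectors;
#'   `strand` one of `"+"`, `"-"`, `"unknown"`.
#' @return A `data.frame` of class `gene_annotation` with those five columns.
#' @export
gene_annotation <- function(gene_symbol, chromosome, start, end,
                            strand = "unknown") {
  ann <- data.frame(gene_symbol = as.character(gene_symbol),
                    chromosome = as.character(chromosome),
                    start = as.numeric(start), end = as.numeric(end),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  ann$strand[ann$strand %in% c("*", ".", NA)] <- "unknown"
  if (!all(ann$strand %in% c("+", "-", "unknown")))
    stop("strand must be '+', '-' or 'unknown'")
  if (any(ann$start < 0)) stop("negative start coordinate")
  if (any(ann$start >= ann$end))
    stop("start >= end after normalization for: ",
         paste(ann$gene_symbol[ann$start >= ann$end], collapse = ", "))
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotation from BED or GFF3
#'
#' Uses `rtracklayer::import()` and normalizes coordinates to the internal
#' 0-based half-open convention. For GFF3, rows with `type == feature_type`
#' are selected and the gene symbol is taken from `attr_key` (falling back to
#' `ID` where that attribute is missing).
#'
#' @param path file path ending in `.bed`, `.gff`, `.gff3` or `.gtf`.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param attr_key GFF3 attribute carrying the gene symbol (default `"Name"`).
#' @return A [gene_annotation()] data frame.
#' @export
read_gene_annotation <- function(path, feature_type = "gene",
                                 attr_key = "Name") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("bed", "gff", "gff3", "gtf"))
    stop("unknown annotation format extension: .", ext)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (ext == "bed") {
    sym <- df$name
  } else {
    df <- df[df$type == feature_type, , drop = FALSE]
    if (nrow(df) == 0)
      stop("no '", feature_type, "' features in ", path)
    sym <- if (attr_key %in% names(df)) df[[attr_key]] else NULL
    if (is.null(sym)) sym <- rep(NA_character_, nrow(df))
    if (anyNA(sym) && "ID" %in% names(df))
      sym[is.na(sym)] <- df$ID[is.na(sym)]
  }
  if (is.null(sym) || anyNA(sym))
    stop("missing gene symbols in ", path)
  # rtracklayer yields 1-based closed coordinates for both formats
  gene_annotation(gene_symbol = as.character(sym),
                  chromosome = as.character(df$seqnames),
                  start = df$start - 1L, end = df$end,
                  strand = as.character(df$strand))
}

#' Write gene annotation as BED (0-based half-open)
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  strand <- ifelse(ann$strand == "unknown", ".", ann$strand)
  bed <- data.frame(ann$chromosome, format(ann$start, scientific = FALSE,
                                           trim = TRUE),
                    format(ann$end, scientific = FALSE, trim = TRUE),
                    ann$gene_symbol, 0L, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Probe-to-gene annotation
#'
#' Maps probe identifiers to gene symbols and, optionally, groups technical
#' replicate probes. `replicate_group` is `NA` for singleton probes; probes
#' sharing a non-`NA` group key are technical replicates of one another and
#' are averaged by [average_technical_replicates()].
#'
#' @param probe_id,gene_symbol,replicate_group equal-length vectors;
#'   `gene_symbol` may contain `NA` for unannotated probes.
#' @return A `data.frame` of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, gene_symbol,
                             replicate_group = NA_character_) {
  pa <- data.frame(probe_id = as.character(probe_id),
                   gene_symbol = as.character(gene_symbol),
                   replicate_group = as.character(replicate_group),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pa$probe_id))
    stop("duplicate probe ids in probe annotation")
  grp <- pa$replicate_group[!is.na(pa$replicate_group)]
  if (length(grp)) {
    gg <- split(pa$gene_symbol[!is.na(pa$replicate_group)], grp)
    bad <- names(gg)[vapply(gg, function(g) length(unique(g)) > 1L, NA)]
    if (length(bad))
      stop("replicate group maps to more than one gene: ",
           paste(bad, collapse = ", "))
  }
  class(pa) <- c("probe_annotation", "data.frame")
  pa
}

# row key after replicate averaging: group key where present, else probe id
.probe_keys <- function(probes) {
  ifelse(is.na(probes$replicate_group), probes$probe_id,
         probes$replicate_group)
}

# key -> gene map valid both before and after replicate averaging
.key_gene_map <- function(probes) {
  key <- c(probes$probe_id, .probe_keys(probes))
  gene <- c(probes$gene_symbol, probes$gene_symbol)
  keep <- !duplicated(key)
  stats::setNames(gene[keep], key[keep])
}
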