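#' Window specification around an anchor gene
#'
#' Defines the co-amplification surrogate region: the anchor gene plus a
#' fixed flank on either side (default 1 Mb, giving the ~2 Mb window used
#' around CCND1 on 11q13).
#'
#' @param anchor anchor gene symbol.
#' @param flank flank size in base pairs (> 0).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(anchor, flank = 1e6) {
  if (flank <= 0) stop("flank must be positive")
  structure(list(anchor = anchor, flank = as.numeric(flank)),
            class = "window_spec")
}

#' Select genes in the window around the anchor
#'
#' Genes on the anchor's chromosome whose interval overlaps
#' `[anchor.start - flank, anchor.end + flank)` (half-open; overlap, not
#' containment, so genes straddling the edge are included), sorted by start
#' coordinate. Side labels are positional and strand-independent:
#' `upstream` if the gene ends at or before the anchor start (lower
#' coordinates), `downstream` if it starts at or after the anchor end,
#' `anchor` otherwise (the anchor itself and anything overlapping it).
#'
#' @param annotation a [gene_annotation()].
#' @param spec a [window_spec()].
#' @return A `data.frame` with the annotation columns plus `side`, ordered
#'   by `start`.
#' @export
select_window_genes <- function(annotation, spec) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(spec, "window_spec"))
  a <- annotation[annotation$gene_symbol == spec$anchor, ]
  if (nrow(a) == 0L) stop("anchor not in annotation: ", spec$anchor)
  if (nrow(a) > 1L) stop("anchor annotated more than once: ", spec$anchor)
  ws <- a$start - spec$flank
  we <- a$end + spec$flank
  g <- annotation[annotation$chromosome == a$chromosome &
                    annotation$start < we & annotation$end > ws, ]
  g <- g[order(g$start, g$end, g$gene_symbol), ]
  g$side <- ifelse(g$end <= a$start, "upstream",
                   ifelse(g$start >= a$end, "downstream", "anchor"))
  rownames(g) <- NULL
  class(g) <- "data.frame"
  g
}

#' Per-patient fold-change profile of the window genes
#'
#' Computes the paired tumor-vs-normal log2 fold change of every expressed
#' gene in the window, for every paired patient. Expression is gauged by the
#' mean log2 intensity over all samples against `intensity_threshold`
#' (see [filter_low_expression()]); genes below the threshold, or absent
#' from the matrix, stay in the gene list but are masked (`NA` rows in the
#' fold-change matrix).
#'
#' @param m a gene-level log2 [expression_matrix()].
#' @param samples a [sample_table()].
#' @param annotation a [gene_annotation()].
#' @param spec a [window_spec()].
#' @param intensity_threshold mean log2-intensity cutoff (default 5).
#' @return An object of class `window_profile`: list with `genes` (the
#'   ordered gene table with `side` and `expressed`), `lfc` (genes x paired
#'   patients matrix, masked rows `NA`), `anchor`, `spec`,
#'   `intensity_threshold`.
#' @export
window_lfc_matrix <- function(m, samples, annotation, spec,
                              intensity_threshold = 5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$level != "gene") stop("expected a gene-level matrix")
  genes <- select_window_genes(annotation, spec)
  present <- genes$gene_symbol %in% feature_ids(m)
  expressed <- present
  expressed[present] <-
    rowMeans(m$values[genes$gene_symbol[present], , drop = FALSE]) >=
    intensity_threshold
  genes$expressed <- expressed
  if (!any(expressed)) stop("no expressed gene in the window")
  pr <- validate_pairing(samples)
  if (length(pr$paired_ids) == 0L) stop("no paired patients")
  lfc <- matrix(NA_real_, nrow = nrow(genes), ncol = length(pr$paired_ids),
                dimnames = list(genes$gene_symbol, pr$paired_ids))
  sub <- m$values[genes$gene_symbol[expressed], , drop = FALSE]
  lfc[expressed, ] <- sub[, pr$tumor_sample, drop = FALSE] -
    sub[, pr$normal_sample, drop = FALSE]
  structure(list(genes = genes, lfc = lfc, anchor = spec$anchor,
                 spec = spec, intensity_threshold = intensity_threshold),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf(paste0("window_profile: anchor %s +/- %g bp; %d gene(s), %d ",
                     "expressed; %d paired patient(s)\n"),
              x$anchor, x$spec$flank, nrow(x$genes), sum(x$genes$expressed),
              ncol(x$lfc)))
  print(table(side = x$genes$side, expressed = x$genes$expressed))
  invisible(x)
}

#' Per-patient co-amplification surrogate call
#'
#' Locus amplification is expected to raise the expression of the genes
#' downstream of the anchor together with the anchor itself. The score for a
#' patient is the number (and fraction) of expressed downstream genes with
#' log2 fold change at or above `lfc_cut`; the flag is set when the count
#' reaches `min_genes`. The rule is configurable because the qualitative
#' observation it formalizes has no canonical numeric definition.
#'
#' @param profile a [window_lfc_matrix()] result.
#' @param patients optional subset of patient ids (typically the
#'   anchor-upregulated group); default all paired patients.
#' @param min_genes minimum qualifying downstream genes (default 2).
#' @param lfc_cut log2 fold-change cutoff (default 1.0).
#' @return A `data.frame` with `patient_id`, `n_down_expressed`,
#'   `score_count`, `score_frac`, `flag`. With zero expressed downstream
#'   genes the flag is `NA` (undefined).
#' @export
coamplification_call <- function(profile, patients = NULL, min_genes = 2,
                                 lfc_cut = 1.0) {
  stopifnot(inherits(profile, "window_profile"))
  if (is.null(patients)) patients <- colnames(profile$lfc)
  missing <- setdiff(patients, colnames(profile$lfc))
  if (length(missing))
    stop("patient(s) not in profile: ", paste(missing, collapse = ", "))
  down <- profile$genes$side == "downstream" & profile$genes$expressed
  nd <- sum(down)
  if (nd == 0L) {
    cnt <- rep(NA_integer_, length(patients))
  } else {
    sub <- profile$lfc[down, patients, drop = FALSE]
    cnt <- colSums(sub >= lfc_cut)
  }
  data.frame(patient_id = patients, n_down_expressed = nd,
             score_count = cnt,
             score_frac = if (nd) cnt / nd else NA_real_,
             flag = if (nd) cnt >= min_genes else NA,
             stringsAsFactors = FALSE, row.names = NULL)
}
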