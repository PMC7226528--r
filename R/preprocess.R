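#' Quantile normalization
#'
#' Forces every sample onto the common reference distribution (the
#' across-sample mean of sorted value vectors), preserving within-sample rank
#' order. Tied input values receive the mean of the quantile targets they
#' span. Delegates to `limma::normalizeQuantiles(ties = TRUE)`; the operation
#' is idempotent.
#'
#' @param m an [expression_matrix()] on the log2 scale.
#' @return A quantile-normalized `expression_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2") stop("quantile normalization expects log2 data")
  if (ncol(m$values) < 1L) stop("need at least one sample")
  if (nrow(m$values) == 1L) {
    warning("single-feature matrix returned unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(out) <- dimnames(m$values)
  expression_matrix(out, level = m$level, scale = "log2")
}

#' Average technical replicate probes
#'
#' Illumina bead arrays spot some probes multiple times; their intensities
#' are averaged at the probe level (arithmetic mean on the log2 scale, i.e. a
#' geometric mean of intensities). Rows sharing a non-`NA` `replicate_group`
#' in the probe annotation collapse to one row named by the group key;
#' singleton probes pass through unchanged.
#'
#' @param m a probe-level [expression_matrix()].
#' @param probes a [probe_annotation()] covering the matrix features.
#' @return An `expression_matrix` with one row per replicate group.
#' @export
average_technical_replicates <- function(m, probes) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(probes, "probe_annotation"))
  if (m$level != "probe") stop("expected a probe-level matrix")
  idx <- match(feature_ids(m), probes$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(utils::head(feature_ids(m)[is.na(idx)], 5L), collapse = ", "))
  key <- .probe_keys(probes)[idx]
  out <- rowsum(m$values, group = key, reorder = FALSE) /
    as.vector(table(key)[unique(key)])
  expression_matrix(out[unique(key), , drop = FALSE],
                    level = "probe", scale = m$scale)
}

#' Collapse probes to genes
#'
#' One row per gene, the per-sample mean over the probes targeting it (log2
#' scale). Probes without a gene symbol are dropped and counted in a message.
#'
#' @param m a probe-level [expression_matrix()] (before or after
#'   [average_technical_replicates()]).
#' @param probes a [probe_annotation()].
#' @return A gene-level `expression_matrix`.
#' @export
collapse_probes_to_genes <- function(m, probes) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(probes, "probe_annotation"))
  if (m$level != "probe") stop("expected a probe-level matrix")
  map <- .key_gene_map(probes)
  gene <- unname(map[feature_ids(m)])
  drop <- is.na(gene)
  if (all(drop)) stop("no probe maps to a gene symbol")
  if (any(drop))
    message(sum(drop), " unmapped probe(s) dropped")
  vals <- m$values[!drop, , drop = FALSE]
  gene <- gene[!drop]
  out <- rowsum(vals, group = gene, reorder = TRUE)
  out <- out / as.vector(table(gene)[rownames(out)])
  expression_matrix(out, level = "gene", scale = m$scale)
}

#' Filter low-expression genes
#'
#' Removes genes whose mean log2 intensity over all samples is strictly
#' below `threshold` (a gene sitting exactly at the threshold is kept). The
#' removed gene set is attached as attribute `"removed"`.
#'
#' @param m a gene-level [expression_matrix()] on the log2 scale.
#' @param threshold mean log2-intensity cutoff (default 5).
#' @return The filtered `expression_matrix`.
#' @export
filter_low_expression <- function(m, threshold = 5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2") stop("intensity filter expects log2 data")
  keep <- rowMeans(m$values) >= threshold
  if (!any(keep)) stop("all genes fall below the intensity threshold")
  out <- expression_matrix(m$values[keep, , drop = FALSE],
                           level = m$level, scale = "log2")
  attr(out, "removed") <- feature_ids(m)[!keep]
  out
}

#' Median-of-ratios normalization of a count matrix
#'
#' Computes per-sample size factors as the median, over genes with a nonzero
#' geometric mean, of the ratio of the gene's count to its across-sample
#' geometric mean, then returns `log2(count / size_factor + 1)`. This is the
#' standard sequencing-depth correction for the RNA-seq validation path; the
#' log transform is a monotone stand-in for a full variance-stabilizing
#' transform, which leaves paired fold-change calls essentially unchanged at
#' moderate counts.
#'
#' @param m a count-scale [expression_matrix()] with at least 2 samples.
#' @return A log2-scale `expression_matrix`; size factors are attached as
#'   attribute `"size_factors"`.
#' @export
size_factor_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "count") stop("expected raw counts")
  if (ncol(m$values) < 2L) stop("need at least 2 samples")
  loggeo <- rowMeans(log(m$values))
  use <- is.finite(loggeo)
  if (!any(use)) stop("every gene has a zero count in some sample; ",
                      "no reference genes for size factors")
  sf <- apply(log(m$values[use, , drop = FALSE]) - loggeo[use], 2L,
              function(z) exp(stats::median(z)))
  out <- log2(sweep(m$values, 2L, sf, "/") + 1)
  out <- expression_matrix(out, level = m$level, scale = "log2")
  attr(out, "size_factors") <- sf
  out
}

#' Optional per-batch mean centering
#'
#' Subtracts, per gene, the batch mean and restores the gene's overall mean,
#' removing additive batch offsets. Off by default in the pipeline; full
#' empirical-Bayes batch correction is out of scope (deposited data arrives
#' already batch-corrected).
#'
#' @param m an [expression_matrix()] on the log2 scale.
#' @param samples a [sample_table()] with a `batch` column.
#' @return The centered `expression_matrix`.
#' @export
center_batches <- function(m, samples) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(samples, "sample_table"))
  batch <- samples$batch[match(sample_ids(m), samples$sample_id)]
  if (anyNA(batch)) stop("batch labels missing for some samples")
  vals <- m$values
  grand <- rowMeans(vals)
  for (b in unique(batch)) {
    j <- batch == b
    vals[, j] <- vals[, j] - rowMeans(vals[, j, drop = FALSE]) + grand
  }
  expression_matrix(vals, level = m$level, scale = m$scale)
}
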