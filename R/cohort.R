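#' Cohort bundle
#'
#' Ties together an expression matrix, its sample metadata and, where
#' available, probe annotation, clinical follow-up, gene coordinates and
#' (for simulated cohorts) the ground truth. Cross-references are validated:
#' the sample table must describe exactly the expression columns.
#'
#' @param expression an [expression_matrix()].
#' @param samples a [sample_table()].
#' @param probes optional [probe_annotation()].
#' @param clinical optional [clinical_table()].
#' @param annotation optional [gene_annotation()].
#' @param truth optional simulation truth (see [simulate_cohort()]).
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(expression, samples, probes = NULL,
                           clinical = NULL, annotation = NULL, truth = NULL) {
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(samples, "sample_table"))
  if (!setequal(sample_ids(expression), samples$sample_id))
    stop("sample table and expression matrix describe different samples")
  if (!is.null(probes)) {
    stopifnot(inherits(probes, "probe_annotation"))
    if (expression$level == "probe" &&
        !all(feature_ids(expression) %in% probes$probe_id))
      stop("probe annotation does not cover all expression features")
  }
  if (!is.null(clinical)) {
    stopifnot(inherits(clinical, "clinical_table"))
    extra <- setdiff(clinical$patient_id, samples$patient_id)
    if (length(extra))
      warning(length(extra),
              " clinical patient(s) without any profiled sample")
  }
  if (!is.null(annotation)) stopifnot(inherits(annotation, "gene_annotation"))
  structure(list(expression = expression, samples = samples, probes = probes,
                 clinical = clinical, annotation = annotation, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  pr <- validate_pairing(x$samples)
  cat(sprintf("cohort_dataset: %d patient(s), %d paired; ",
              length(unique(x$samples$patient_id)), length(pr$paired_ids)))
  cat(sprintf("%d %s(s) x %d sample(s)\n", nrow(x$expression$values),
              x$expression$level, ncol(x$expression$values)))
  cat(sprintf("  components: %s\n",
              paste(names(Filter(Negate(is.null), unclass(x))),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `expression.tsv`, `samples.tsv` and, where
#' present, `probes.tsv`, `clinical.tsv`, `annotation.bed`, `truth.tsv` into
#' `dir`; `read_cohort()` reads them back. The round trip is the identity on
#' values and identifiers.
#'
#' @param cohort a [cohort_dataset()].
#' @param dir directory (created if needed).
#' @return `write_cohort()` returns `dir`; `read_cohort()` a
#'   `cohort_dataset`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"),
                   feature_col = cohort$expression$level)
  .write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$probes))
    .write_tsv(cohort$probes, file.path(dir, "probes.tsv"))
  if (!is.null(cohort$clinical))
    .write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(cohort$annotation))
    write_gene_annotation(cohort$annotation, file.path(dir, "annotation.bed"))
  if (!is.null(cohort$truth))
    .write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cat(sprintf("scale: %s\nlevel: %s\n", cohort$expression$scale,
              cohort$expression$level),
      file = file.path(dir, "expression-meta.txt"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- readLines(file.path(dir, "expression-meta.txt"))
  scale <- sub("^scale: ", "", meta[1L])
  level <- sub("^level: ", "", meta[2L])
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          scale = scale, level = level)
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  probes <- clinical <- annotation <- truth <- NULL
  if (file.exists(file.path(dir, "probes.tsv"))) {
    p <- .read_delim(file.path(dir, "probes.tsv"))
    probes <- probe_annotation(p$probe_id, p$gene_symbol, p$replicate_group)
  }
  if (file.exists(file.path(dir, "clinical.tsv")))
    clinical <- read_clinical_table(file.path(dir, "clinical.tsv"))
  if (file.exists(file.path(dir, "annotation.bed")))
    annotation <- read_gene_annotation(file.path(dir, "annotation.bed"))
  if (file.exists(file.path(dir, "truth.tsv")))
    truth <- .read_delim(file.path(dir, "truth.tsv"))
  cohort_dataset(expr, samples, probes = probes, clinical = clinical,
                 annotation = annotation, truth = truth)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
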