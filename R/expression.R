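#' Expression matrix container
#'
#' A light S3 container for a features-by-samples expression table. The
#' microarray path carries log2 intensities (`scale = "log2"`); the RNA-seq
#' validation path carries raw non-negative integer counts
#' (`scale = "count"`). Rows are probes or genes (`level`), columns are
#' samples.
#'
#' @param values numeric matrix with rownames = feature identifiers and
#'   colnames = sample identifiers.
#' @param level `"probe"` or `"gene"`.
#' @param scale `"log2"` or `"count"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `level`, `scale`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(5, 6, 7, 8), 2, 2,
#'          dimnames = list(c("CCND1", "CCND2"), c("s1", "s2"))),
#'   level = "gene", scale = "log2")
#' feature_ids(m)
#' @export
expression_matrix <- function(values, level = c("gene", "probe"),
                              scale = c("log2", "count")) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyNA(values))
    stop("missing expression values are not permitted")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (level == "gene" && anyDuplicated(rownames(values)))
    stop("duplicate feature ids in a gene-level matrix")
  if (scale == "count") {
    if (any(values < 0))
      stop("count-scale values must be non-negative")
    if (any(values != round(values)))
      stop("count-scale values must be integers")
  }
  structure(list(values = values, level = level, scale = scale),
            class = "expression_matrix")
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %s(s) x %d sample(s), %s scale\n",
              nrow(x$values), x$level, ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression table from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Tab-separated by default; comma-separated files are detected
#' from the `.csv` extension. Parsing is locale-independent (decimal point).
#'
#' @param path file path.
#' @param scale,level forwarded to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, scale = c("log2", "count"),
                            level = c("gene", "probe")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr))
    stop("duplicate sample ids in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("expression table needs >= 1 sample column")
  feat <- as.character(df[[1L]])
  dat <- df[-1L]
  for (j in seq_along(dat)) {
    if (!is.numeric(dat[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dat[[j]]))))[1L]
      stop(sprintf("non-numeric value in column '%s', row '%s'",
                   names(dat)[j], feat[bad]))
    }
  }
  vals <- as.matrix(dat)
  rownames(vals) <- feat
  expression_matrix(vals, level = level, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @param feature_col name for the leading feature-id column.
#' @export
write_expression <- function(x, path, feature_col = "feature_id") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
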