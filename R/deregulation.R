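#' Per-patient paired fold change for one gene
#'
#' For every patient with exactly one tumor and one normal sample, the log2
#' fold change is the difference of log2 values (tumor minus normal), and the
#' linear fold change is `2^lfc`. Computing on the log2 scale by subtraction
#' avoids background-offset sensitivity; unpaired patients are excluded, not
#' an error.
#'
#' @param m a gene-level log2 [expression_matrix()].
#' @param samples a [sample_table()].
#' @param gene gene symbol, must be present in `m`.
#' @return A `data.frame` of class `fold_change_table` with columns
#'   `patient_id`, `gene_symbol`, `lfc`, `fc`.
#' @export
paired_lfc <- function(m, samples, gene) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$level != "gene") stop("expected a gene-level matrix")
  if (m$scale != "log2") stop("expected log2 data")
  if (!gene %in% feature_ids(m)) stop("gene not in matrix: ", gene)
  pr <- validate_pairing(samples)
  if (length(pr$paired_ids) == 0L) stop("no paired patients")
  v <- m$values[gene, ]
  lfc <- unname(v[pr$tumor_sample] - v[pr$normal_sample])
  out <- data.frame(patient_id = pr$paired_ids, gene_symbol = gene,
                    lfc = lfc, fc = 2^lfc, stringsAsFactors = FALSE)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Three-way deregulation classification of a fold change
#'
#' `up` if the linear fold change exceeds `upper`, `down` if below `lower`,
#' `not` otherwise. The inequalities are strict on both sides, so a fold
#' change sitting exactly on a boundary is absorbed by the middle class.
#'
#' @param fc vector of linear fold changes (> 0).
#' @param upper,lower thresholds, default 2 and 0.5.
#' @return A factor with levels `up`, `not`, `down`.
#' @examples
#' classify_fc(c(2.5, 2, 1, 0.5, 0.4))
#' @export
classify_fc <- function(fc, upper = 2, lower = 0.5) {
  if (any(fc <= 0)) stop("fold changes must be positive")
  if (lower >= upper) stop("lower threshold must be below upper")
  factor(ifelse(fc > upper, "up", ifelse(fc < lower, "down", "not")),
         levels = c("up", "not", "down"))
}

#' Deregulation calls for a set of genes
#'
#' Combines [paired_lfc()] and [classify_fc()] for each requested gene and
#' annotates each paired patient with their HPV status. The thresholds used
#' are recorded as attributes and echoed by every downstream report.
#'
#' @param m a gene-level log2 [expression_matrix()].
#' @param samples a [sample_table()].
#' @param genes gene symbols (default the three D-type cyclins).
#' @param upper,lower fold-change thresholds (default 2 and 0.5).
#' @return A `data.frame` of class `dereg_calls` with columns `patient_id`,
#'   `gene_symbol`, `lfc`, `fc`, `call`, `hpv_status`.
#' @export
call_deregulation <- function(m, samples,
                              genes = c("CCND1", "CCND2", "CCND3"),
                              upper = 2, lower = 0.5) {
  missing <- setdiff(genes, feature_ids(m))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  hpv <- stats::setNames(samples$hpv_status, samples$patient_id)
  out <- do.call(rbind, lapply(genes, function(g) {
    fcts <- paired_lfc(m, samples, g)
    fcts$call <- classify_fc(fcts$fc, upper = upper, lower = lower)
    fcts$hpv_status <- unname(hpv[fcts$patient_id])
    fcts
  }))
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(upper = upper, lower = lower)
  class(out) <- c("dereg_calls", "data.frame")
  out
}

#' @export
print.dereg_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("dereg_calls: %d patient(s) x %d gene(s), thresholds FC > %g",
              length(unique(x$patient_id)), length(unique(x$gene_symbol)),
              th["upper"]),
      sprintf("(up) / FC < %g (down)\n", th["lower"]))
  print(table(gene = x$gene_symbol, call = x$call))
  invisible(x)
}

#' Summarize deregulation calls by gene and HPV stratum
#'
#' Counts and fractions of up / not / down calls per gene, for the whole
#' paired cohort and for the HPV-positive and HPV-negative strata. Patients
#' with unknown HPV status contribute to the whole-cohort rows only.
#'
#' @param calls a [call_deregulation()] result.
#' @return A `data.frame` of class `dereg_summary` with one row per gene and
#'   stratum: counts `n_up`, `n_not`, `n_down`, total `n`, and fractions.
#' @export
summarize_deregulation <- function(calls) {
  stopifnot(inherits(calls, "dereg_calls"))
  strata <- list(all = rep(TRUE, nrow(calls)),
                 hpv_pos = calls$hpv_status == "positive",
                 hpv_neg = calls$hpv_status == "negative")
  rows <- list()
  for (g in unique(calls$gene_symbol)) {
    for (s in names(strata)) {
      sub <- calls[calls$gene_symbol == g & strata[[s]], ]
      cnt <- table(sub$call)
      n <- sum(cnt)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = g, stratum = s,
        n_up = unname(cnt["up"]), n_not = unname(cnt["not"]),
        n_down = unname(cnt["down"]), n = n,
        frac_up = if (n) unname(cnt["up"]) / n else NA_real_,
        frac_not = if (n) unname(cnt["not"]) / n else NA_real_,
        frac_down = if (n) unname(cnt["down"]) / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- attr(calls, "thresholds")
  class(out) <- c("dereg_summary", "data.frame")
  out
}
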