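#' Sample metadata table
#'
#' One row per profiled sample. `tissue` distinguishes the tumor and the
#' matched normal mucosa sample of a patient; `hpv_status` is the cohort's
#' principal prognostic stratifier and may be `"unknown"` (such patients are
#' kept in whole-cohort outputs but excluded from HPV-stratified ones).
#'
#' @param sample_id,patient_id,tissue,hpv_status,batch equal-length vectors;
#'   `tissue` in `{"tumor","normal"}`, `hpv_status` in
#'   `{"positive","negative","unknown"}`.
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, patient_id, tissue,
                         hpv_status = "unknown", batch = NA_character_) {
  st <- data.frame(sample_id = as.character(sample_id),
                   patient_id = as.character(patient_id),
                   tissue = as.character(tissue),
                   hpv_status = as.character(hpv_status),
                   batch = as.character(batch),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(st$sample_id)) stop("duplicate sample ids")
  if (!all(st$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (!all(st$hpv_status %in% c("positive", "negative", "unknown")))
    stop("hpv_status must be 'positive', 'negative' or 'unknown'")
  class(st) <- c("sample_table", "data.frame")
  st
}

#' @rdname sample_table
#' @param path TSV (or CSV) file with columns `sample_id`, `patient_id`,
#'   `tissue` and optionally `hpv_status`, `batch`.
#' @export
read_sample_table <- function(path) {
  df <- .read_delim(path)
  sample_table(df$sample_id, df$patient_id, df$tissue,
               hpv_status = if ("hpv_status" %in% names(df))
                 df$hpv_status else "unknown",
               batch = if ("batch" %in% names(df)) df$batch
                 else NA_character_)
}

#' Clinical follow-up table
#'
#' Overall survival (OS) uses death from any cause as the event.
#' Disease-free survival (DFS) may arrive either as a precomputed 0/1 event
#' indicator or as the four-state vital status
#' `{disease_free, exitus_other, recidive, exitus_disease}`, of which
#' `recidive` and `exitus_disease` count as events; the mapping is fixed.
#'
#' @param patient_id patient identifiers.
#' @param os_months,os_event OS follow-up time (months, non-negative) and
#'   0/1 event indicator.
#' @param dfs_months,dfs_status optional DFS time and status (four-state
#'   character or 0/1).
#' @return A `data.frame` of class `clinical_table` with columns
#'   `patient_id`, `os_months`, `os_event` and, when DFS is supplied,
#'   `dfs_months`, `dfs_status`, `dfs_event`.
#' @export
clinical_table <- function(patient_id, os_months, os_event,
                           dfs_months = NULL, dfs_status = NULL) {
  ct <- data.frame(patient_id = as.character(patient_id),
                   os_months = as.numeric(os_months),
                   os_event = as.integer(os_event),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ct$patient_id)) stop("duplicate patient ids")
  if (any(ct$os_months < 0)) stop("negative follow-up time")
  if (!all(ct$os_event %in% c(0L, 1L))) stop("os_event must be 0/1")
  if (!is.null(dfs_months)) {
    ct$dfs_months <- as.numeric(dfs_months)
    if (any(ct$dfs_months < 0, na.rm = TRUE))
      stop("negative follow-up time")
    if (is.null(dfs_status)) stop("dfs_months given without dfs_status")
    ct$dfs_status <- as.character(dfs_status)
    states <- c("disease_free", "exitus_other", "recidive", "exitus_disease")
    if (all(ct$dfs_status %in% c("0", "1"))) {
      ct$dfs_event <- as.integer(ct$dfs_status)
    } else if (all(ct$dfs_status %in% states)) {
      ct$dfs_event <-
        as.integer(ct$dfs_status %in% c("recidive", "exitus_disease"))
    } else {
      stop("dfs_status must be 0/1 or one of: ",
           paste(states, collapse = ", "))
    }
  }
  class(ct) <- c("clinical_table", "data.frame")
  ct
}

#' @rdname clinical_table
#' @param path TSV (or CSV) file with the clinical columns.
#' @export
read_clinical_table <- function(path) {
  df <- .read_delim(path)
  clinical_table(df$patient_id, df$os_months, df$os_event,
                 dfs_months = df[["dfs_months"]],
                 dfs_status = df[["dfs_status"]])
}

#' Validate tumor/normal pairing
#'
#' Returns the patients with exactly one tumor and one normal sample — the
#' paired subcohort on which all fold-change analyses operate. Patients with
#' a single tissue are counted and excluded; two samples of the same tissue
#' for one patient make the pairing ambiguous and are a hard error.
#'
#' @param samples a [sample_table()].
#' @return An object of class `pairing`: list with `paired_ids` (character),
#'   `n_tumor_only`, `n_normal_only`, and the per-patient `tumor_sample` /
#'   `normal_sample` lookup for the paired patients.
#' @export
validate_pairing <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  tab <- table(samples$patient_id,
               factor(samples$tissue, levels = c("normal", "tumor")))
  if (any(tab > 1L)) {
    bad <- rownames(tab)[apply(tab > 1L, 1L, any)]
    stop("ambiguous pairing: more than one sample of the same tissue for ",
         "patient(s): ", paste(bad, collapse = ", "))
  }
  has_t <- rownames(tab)[tab[, "tumor", drop = TRUE] == 1L]
  has_n <- rownames(tab)[tab[, "normal", drop = TRUE] == 1L]
  paired <- sort(intersect(has_t, has_n))
  idx_t <- samples$tissue == "tumor"
  idx_n <- samples$tissue == "normal"
  tumor_sample <- stats::setNames(samples$sample_id[idx_t],
                                  samples$patient_id[idx_t])[paired]
  normal_sample <- stats::setNames(samples$sample_id[idx_n],
                                   samples$patient_id[idx_n])[paired]
  structure(list(paired_ids = paired,
                 n_tumor_only = length(setdiff(has_t, has_n)),
                 n_normal_only = length(setdiff(has_n, has_t)),
                 tumor_sample = tumor_sample,
                 normal_sample = normal_sample),
            class = "pairing")
}

#' @export
print.pairing <- function(x, ...) {
  cat(sprintf(paste0("pairing: %d paired patient(s); excluded %d tumor-only",
                     " and %d normal-only\n"),
              length(x$paired_ids), x$n_tumor_only, x$n_normal_only))
  invisible(x)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
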