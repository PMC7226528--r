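#' Survival records
#'
#' The survival operations take a plain `data.frame` with columns `time`
#' (months, non-negative), `event` (0/1) and, for group comparisons,
#' `group`. Times recorded as 0 (the cohort's follow-up range starts at 0
#' months) are kept: internally an event at time 0 is shifted to a tiny
#' positive epsilon and a censoring at 0 to twice that, so that zero-time
#' events precede zero-time censorings, in keeping with the right-censoring
#' convention that censored subjects at t do not count as events at t.
#'
#' @name survival_records
#' @keywords internal
NULL

.prep_surv <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in%
                                          names(records)))
  if (any(records$time < 0)) stop("negative survival time")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  eps <- 1e-6
  z <- records$time == 0
  records$time[z & records$event == 1] <- eps
  records$time[z & records$event == 0] <- 2 * eps
  records
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate with Greenwood variance and pointwise 95%
#' confidence intervals on the complementary log-log scale (bounded within
#' [0, 1]). One curve, or one per group when `records$group` is present.
#'
#' @param records see [survival_records].
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `km_curve` wrapping the `survfit` fit;
#'   elements `fit` (the `survfit` object) and `n`.
#' @export
km_fit <- function(records, conf_level = 0.95) {
  records <- .prep_surv(records)
  if (nrow(records) < 1L) stop("need at least one record")
  f <- if ("group" %in% names(records))
    survival::survfit(survival::Surv(time, event) ~ group, data = records,
                      conf.type = "log-log", conf.int = conf_level)
  else
    survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                      conf.type = "log-log", conf.int = conf_level)
  structure(list(fit = f, n = nrow(records)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("km_curve (product-limit estimate, log-log CI)\n")
  print(x$fit)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, mark.time = TRUE, xlab = "months",
       ylab = "survival probability", ...)
  invisible(x)
}

#' Survival estimate at a time point
#'
#' Step-function value of the Kaplan-Meier curve at `t` (the step at the
#' last event time at or before `t`) with its confidence interval. When `t`
#' exceeds the last observed time the last step is returned and flagged.
#'
#' @param curve a [km_fit()] result.
#' @param t time in months (default 60, i.e. five years).
#' @return A `data.frame` with columns `group` (absent for ungrouped fits),
#'   `time`, `estimate`, `lower`, `upper`, `extrapolated`.
#' @export
survival_at <- function(curve, t = 60) {
  stopifnot(inherits(curve, "km_curve"))
  f <- curve$fit
  s <- summary(f, times = t, extend = TRUE)
  grouped <- !is.null(f$strata)
  maxt <- if (grouped)
    tapply(f$time, rep(names(f$strata), f$strata), max)
  else max(f$time)
  out <- data.frame(time = t, estimate = s$surv, lower = s$lower,
                    upper = s$upper)
  if (grouped) {
    grp <- sub("^group=", "", as.character(s$strata))
    out <- cbind(group = grp, out)
    out$extrapolated <- t > unname(maxt[as.character(s$strata)])
  } else {
    out$extrapolated <- t > maxt
  }
  rownames(out) <- NULL
  out
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing two or more groups,
#' with `df = #groups - 1` and the p-value from the chi-square upper tail.
#'
#' @param records see [survival_records]; `group` required, every level
#'   non-empty.
#' @return A list of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   `n_per_group`.
#' @export
logrank <- function(records) {
  records <- .prep_surv(records)
  if (!"group" %in% names(records)) stop("'group' column required")
  records$group <- as.factor(records$group)
  if (nlevels(records$group) < 2L) stop("need >= 2 groups")
  empty <- setdiff(levels(records$group), unique(as.character(records$group)))
  if (length(empty))
    stop("group(s) with zero records: ", paste(empty, collapse = ", "))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- nlevels(records$group) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_per_group = table(records$group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Univariate Cox proportional-hazards model with a reference group
#'
#' Partial-likelihood fit with the Efron approximation for tied event times
#' (ties are guaranteed at month resolution), Newton iterations driven to a
#' tight convergence tolerance. Hazard ratios with Wald 95% confidence
#' intervals `exp(coef +/- 1.96 SE)` and Wald p-values are reported per
#' non-reference level. A level with no events (monotone likelihood /
#' separation, the coefficient diverging) is flagged non-estimable and
#' reported as `NA`.
#'
#' @param records see [survival_records]; `group` required.
#' @param reference reference group label (e.g. the no-deregulation class).
#' @return A `data.frame` of class `cox_result` with one row per
#'   non-reference level: `group`, `n`, `events`, `coef`, `hr`, `lower`,
#'   `upper`, `p_value`, `estimable`; attributes `reference` and
#'   `converged`.
#' @export
cox_univariate <- function(records, reference) {
  records <- .prep_surv(records)
  if (!"group" %in% names(records)) stop("'group' column required")
  records$group <- stats::relevel(as.factor(records$group), ref = reference)
  if (nlevels(records$group) < 2L) stop("need >= 2 groups")
  if (sum(records$event) < 1L) stop("no events in the data")
  # separation (monotone likelihood) is detected below and reported via
  # the 'estimable' flag; the fitter's warning about it is redundant here
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, event) ~ group, data = records, ties = "efron",
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  lv <- levels(records$group)[-1L]
  co <- sm$coefficients
  events <- tapply(records$event, records$group, sum)
  ns <- table(records$group)
  # divergence bound: |coef| beyond this indicates monotone likelihood;
  # a level with zero events is non-estimable (HR would be 0 exactly)
  estimable <- abs(co[, "coef"]) < 15 & is.finite(co[, "se(coef)"]) &
    as.vector(events[lv]) > 0
  out <- data.frame(
    group = lv,
    n = as.vector(ns[lv]),
    events = as.vector(events[lv]),
    coef = ifelse(estimable, co[, "coef"], NA_real_),
    hr = ifelse(estimable, exp(co[, "coef"]), NA_real_),
    lower = ifelse(estimable,
                   exp(co[, "coef"] - 1.96 * co[, "se(coef)"]), NA_real_),
    upper = ifelse(estimable,
                   exp(co[, "coef"] + 1.96 * co[, "se(coef)"]), NA_real_),
    p_value = ifelse(estimable, co[, "Pr(>|z|)"], NA_real_),
    estimable = unname(estimable),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference") <- reference
  attr(out, "converged") <- fit$info["convergence"]
  attr(out, "score") <- unname(fit$score)
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Deregulation-group survival report
#'
#' Joins the deregulation calls of one gene with the clinical table and
#' produces, per HPV stratum: Kaplan-Meier curves per call group, five-year
#' survival with confidence intervals, the log-rank test across groups, and
#' univariate Cox hazard ratios against the no-deregulation reference.
#' Groups smaller than `min_group` are reported descriptively and excluded
#' from the Cox fit (their HR would rest on a handful of patients).
#'
#' @param calls a [call_deregulation()] result.
#' @param clinical a [clinical_table()].
#' @param gene gene symbol to report on.
#' @param stratum `"all"`, `"hpv_neg"` or `"hpv_pos"`.
#' @param endpoint `"OS"` or `"DFS"` (requires DFS columns).
#' @param reference reference call group (default `"not"`).
#' @param min_group minimum group size for the Cox fit (default 3).
#' @param five_year_months time point for the survival extraction
#'   (default 60).
#' @return An object of class `dereg_survival`: list with `table` (per-group
#'   n, events, five-year estimate and CI), `km`, `logrank`, `cox`, and the
#'   settings used.
#' @export
survival_by_deregulation <- function(calls, clinical, gene,
                                     stratum = c("all", "hpv_neg",
                                                 "hpv_pos"),
                                     endpoint = c("OS", "DFS"),
                                     reference = "not", min_group = 3,
                                     five_year_months = 60) {
  stopifnot(inherits(calls, "dereg_calls"),
            inherits(clinical, "clinical_table"))
  stratum <- match.arg(stratum)
  endpoint <- match.arg(endpoint)
  sub <- calls[calls$gene_symbol == gene, ]
  if (nrow(sub) == 0L) stop("no calls for gene: ", gene)
  if (stratum == "hpv_pos") sub <- sub[sub$hpv_status == "positive", ]
  if (stratum == "hpv_neg") sub <- sub[sub$hpv_status == "negative", ]
  idx <- match(sub$patient_id, clinical$patient_id)
  keep <- !is.na(idx)
  sub <- sub[keep, ]
  idx <- idx[keep]
  if (nrow(sub) == 0L) stop("no patients with both calls and follow-up")
  if (endpoint == "OS") {
    time <- clinical$os_months[idx]
    event <- clinical$os_event[idx]
  } else {
    if (!all(c("dfs_months", "dfs_event") %in% names(clinical)))
      stop("DFS endpoint columns missing from clinical table")
    time <- clinical$dfs_months[idx]
    event <- clinical$dfs_event[idx]
  }
  records <- data.frame(patient_id = sub$patient_id, time = time,
                        event = event,
                        group = factor(as.character(sub$call),
                                       levels = c("up", "not", "down")),
                        stringsAsFactors = FALSE)
  records <- droplevels(records[!is.na(records$time), ])
  km <- km_fit(records)
  sa <- survival_at(km, t = five_year_months)
  if (!"group" %in% names(sa)) sa <- cbind(group = levels(records$group), sa)
  tab <- data.frame(group = sa$group,
                    n = as.vector(table(records$group)[sa$group]),
                    events = as.vector(tapply(records$event, records$group,
                                              sum)[sa$group]),
                    five_year = sa$estimate, lower = sa$lower,
                    upper = sa$upper, stringsAsFactors = FALSE)
  lr <- if (nlevels(records$group) >= 2L) logrank(records) else NULL
  big <- names(which(table(records$group) >= min_group))
  cox <- NULL
  if (reference %in% big && length(big) >= 2L &&
      sum(records$event[records$group %in% big]) >= 1L) {
    cr <- droplevels(records[records$group %in% big, ])
    cox <- cox_univariate(cr, reference = reference)
  }
  structure(list(gene = gene, stratum = stratum, endpoint = endpoint,
                 table = tab, km = km, logrank = lr, cox = cox,
                 reference = reference, min_group = min_group,
                 five_year_months = five_year_months,
                 thresholds = attr(calls, "thresholds"),
                 n = nrow(records)),
            class = "dereg_survival")
}

#' @export
print.dereg_survival <- function(x, ...) {
  cat(sprintf("%s, %s, %s endpoint: %d patient(s) with follow-up\n",
              x$gene, x$stratum, x$endpoint, x$n))
  th <- x$thresholds
  if (!is.null(th))
    cat(sprintf("  deregulation thresholds: FC > %g (up), FC < %g (down)\n",
                th["upper"], th["lower"]))
  tab <- x$table
  tab$five_year <- sprintf("%.0f%% (%.0f-%.0f%%)", 100 * tab$five_year,
                           100 * tab$lower, 100 * tab$upper)
  print(tab[, c("group", "n", "events", "five_year")], row.names = FALSE)
  if (!is.null(x$logrank)) print(x$logrank)
  if (!is.null(x$cox)) {
    cat(sprintf("  Cox vs '%s' (Efron ties):\n", x$reference))
    cx <- x$cox
    cx$hr_ci <- ifelse(cx$estimable,
                       sprintf("%.2f (%.2f-%.2f), p %.2g", cx$hr, cx$lower,
                               cx$upper, cx$p_value), "NA")
    print(cx[, c("group", "n", "events", "hr_ci")], row.names = FALSE)
  } else {
    cat("  Cox fit omitted (group sizes below minimum or no events)\n")
  }
  invisible(x)
}
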