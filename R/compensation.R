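#' Cross-tabulate deregulation calls of two genes
#'
#' 3x3 contingency table of per-patient calls, gene A in rows and gene B in
#' columns, both over `{up, not, down}`. If the paired patient sets differ,
#' they are intersected with a warning.
#'
#' @param calls_a,calls_b [call_deregulation()] results each restricted to a
#'   single gene (or a shared `dereg_calls` table together with `gene_a` /
#'   `gene_b` to pick the two genes out of it).
#' @param gene_a,gene_b optional gene symbols selecting rows of `calls_a`
#'   (and `calls_b`, which then defaults to `calls_a`).
#' @return A `table` of class `dereg_crosstab` with attributes `gene_a`,
#'   `gene_b`, `n`.
#' @export
cross_tabulate <- function(calls_a, calls_b = calls_a, gene_a = NULL,
                           gene_b = NULL) {
  stopifnot(inherits(calls_a, "dereg_calls") || is.data.frame(calls_a))
  force(calls_b)
  if (!is.null(gene_a)) calls_a <- calls_a[calls_a$gene_symbol == gene_a, ]
  if (!is.null(gene_b)) calls_b <- calls_b[calls_b$gene_symbol == gene_b, ]
  if (length(unique(calls_a$gene_symbol)) != 1L ||
      length(unique(calls_b$gene_symbol)) != 1L)
    stop("each call set must cover exactly one gene")
  common <- intersect(calls_a$patient_id, calls_b$patient_id)
  if (length(common) == 0L) stop("no patients shared between the two genes")
  if (length(common) < max(nrow(calls_a), nrow(calls_b)))
    warning("patient sets differ; intersecting to ", length(common),
            " patient(s)")
  a <- calls_a$call[match(common, calls_a$patient_id)]
  b <- calls_b$call[match(common, calls_b$patient_id)]
  lv <- c("up", "not", "down")
  ct <- table(factor(a, levels = lv), factor(b, levels = lv))
  names(dimnames(ct)) <- c(unique(calls_a$gene_symbol),
                           unique(calls_b$gene_symbol))
  structure(ct, gene_a = unique(calls_a$gene_symbol),
            gene_b = unique(calls_b$gene_symbol), n = length(common),
            class = c("dereg_crosstab", class(ct)))
}

#' Compensation fractions from a cross-tab
#'
#' The two reciprocal quantities of interest: among patients with gene A
#' downregulated, the fraction with gene B upregulated, and vice versa. A
#' zero denominator yields `NA` (undefined), never 0.
#'
#' @param ct a [cross_tabulate()] result.
#' @return An object of class `compensation_result`: list with
#'   `frac_down_a_up_b`, `frac_up_a_down_b` and the counts backing each.
#' @export
compensation_fractions <- function(ct) {
  stopifnot(inherits(ct, "dereg_crosstab"))
  n_down_a <- sum(ct["down", ])
  n_up_a <- sum(ct["up", ])
  structure(list(
    gene_a = attr(ct, "gene_a"), gene_b = attr(ct, "gene_b"),
    frac_down_a_up_b = if (n_down_a) ct["down", "up"] / n_down_a else
      NA_real_,
    frac_up_a_down_b = if (n_up_a) ct["up", "down"] / n_up_a else NA_real_,
    n_down_a_up_b = unname(ct["down", "up"]), n_down_a = n_down_a,
    n_up_a_down_b = unname(ct["up", "down"]), n_up_a = n_up_a,
    n = attr(ct, "n")), class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  f1 <- if (is.na(x$frac_down_a_up_b)) "undefined" else
    sprintf("%d/%d (%.1f%%)", x$n_down_a_up_b, x$n_down_a,
            100 * x$frac_down_a_up_b)
  f2 <- if (is.na(x$frac_up_a_down_b)) "undefined" else
    sprintf("%d/%d (%.1f%%)", x$n_up_a_down_b, x$n_up_a,
            100 * x$frac_up_a_down_b)
  cat(sprintf("compensation %s vs %s (n = %d paired)\n", x$gene_a, x$gene_b,
              x$n))
  cat(sprintf("  %s down & %s up: %s\n", x$gene_a, x$gene_b, f1))
  cat(sprintf("  %s up & %s down: %s\n", x$gene_a, x$gene_b, f2))
  invisible(x)
}

#' Permutation test for opposite-direction coupling
#'
#' The statistic is the number of patients with opposite-direction calls in
#' the two genes (A up & B down, plus A down & B up). The null distribution
#' permutes gene B's calls across patients; the one-sided p-value uses the
#' add-one estimator `(1 + #(null >= observed)) / (1 + n_perm)`, which never
#' returns exactly zero. One-sided because compensation is a directional
#' hypothesis. The RNG state of the session is left untouched.
#'
#' @param calls_a,calls_b single-gene call tables as in [cross_tabulate()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; required, recorded in the result.
#' @return A list of class `coupling_test`: `statistic`, `p_value`,
#'   `null_mean`, `null_sd`, `n_perm`, `seed`.
#' @export
coupling_permutation_test <- function(calls_a, calls_b, n_perm = 1000,
                                      seed) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (missing(seed)) stop("a seed is required")
  # canonical patient order makes the null draws order-invariant
  common <- sort(intersect(calls_a$patient_id, calls_b$patient_id))
  a <- as.character(calls_a$call[match(common, calls_a$patient_id)])
  b <- as.character(calls_b$call[match(common, calls_b$patient_id)])
  stat <- function(a, b) sum((a == "up" & b == "down") |
                               (a == "down" & b == "up"))
  obs <- stat(a, b)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    warning("fewer than 2 distinct call values in a gene; the statistic is ",
            "permutation-invariant and the test degenerate (p = 1)")
  null <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vapply(seq_len(n_perm), function(i) stat(a, sample(b)), numeric(1))
  })
  structure(list(statistic = obs,
                 p_value = (1 + sum(null >= obs)) / (1 + n_perm),
                 null_mean = mean(null), null_sd = stats::sd(null),
                 n_perm = n_perm, seed = seed),
            class = "coupling_test")
}

#' @export
print.coupling_test <- function(x, ...) {
  cat(sprintf(paste0("coupling permutation test: observed %d ",
                     "opposite-direction pair(s)\n"), x$statistic))
  if (is.na(x$p_value)) cat("  p undefined (degenerate calls)\n") else
    cat(sprintf("  one-sided p = %.4g (null %.2f +/- %.2f, %d perms, seed %d)\n",
                x$p_value, x$null_mean, x$null_sd, x$n_perm, x$seed))
  invisible(x)
}
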