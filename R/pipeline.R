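#' Run the paired deregulation pipeline end to end
#'
#' Orchestrates all stages from a configuration (a YAML file path or an
#' equivalent nested list): load or simulate the cohort, preprocess
#' (quantile normalization, technical-replicate averaging, probe-to-gene
#' collapsing; median-of-ratios for the count path), per-patient
#' deregulation calls and summaries, pairwise compensation cross-tabs with
#' the permutation test, the window co-amplification profile, and the
#' deregulation-group survival tables. Writes TSV/JSON reports plus a
#' machine-readable `manifest.json` recording inputs, thresholds, seed and
#' package version; identical config and seed reproduce the report byte for
#' byte. Raw p-values are reported throughout without multiple-testing
#' correction, and every table carries the thresholds that produced it.
#'
#' Config keys (all optional unless noted): `simulate` (a list of
#' [simulation_config()] overrides; mutually exclusive with `inputs`),
#' `inputs` (`dir` of a [write_cohort()] cohort, or individual file paths
#' `expression`, `samples`, `clinical`, `annotation`, `probes`, with
#' `scale`/`level`), `genes` (default CCND1, CCND2, CCND3), `anchor`
#' (default CCND1), `flank` (default 1e6), `thresholds` (`upper`/`lower`,
#' default 2/0.5), `intensity_threshold` (default 5), `endpoints` (default
#' `"OS"`), `strata` (default all three), `permutations` (default 1000),
#' `min_group` (default 3), `batch_center` (default `FALSE`),
#' `skip_survival` (default `FALSE`), `seed`.
#'
#' @param config path to a YAML file, or a nested list.
#' @param out_dir report directory (created; must be empty or absent).
#' @param seed overrides `config$seed`.
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list. On a stage error, partial outputs
#'   are marked by an `_INCOMPLETE` file and the error names the stage.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, "_INCOMPLETE"))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed
    else 1L
  genes <- if (!is.null(cfg$genes)) cfg$genes else
    c("CCND1", "CCND2", "CCND3")
  anchor <- if (!is.null(cfg$anchor)) cfg$anchor else "CCND1"
  flank <- if (!is.null(cfg$flank)) cfg$flank else 1e6
  upper <- if (!is.null(cfg$thresholds$upper)) cfg$thresholds$upper else 2
  lower <- if (!is.null(cfg$thresholds$lower)) cfg$thresholds$lower else 0.5
  ithr <- if (!is.null(cfg$intensity_threshold)) cfg$intensity_threshold
    else 5
  endpoints <- if (!is.null(cfg$endpoints)) cfg$endpoints else "OS"
  strata <- if (!is.null(cfg$strata)) cfg$strata else
    c("all", "hpv_neg", "hpv_pos")
  n_perm <- if (!is.null(cfg$permutations)) cfg$permutations else 1000
  min_group <- if (!is.null(cfg$min_group)) cfg$min_group else 3

  ## -- cohort ------------------------------------------------------------
  cohort <- stage("load", {
    if (!is.null(cfg$simulate)) {
      note("simulating cohort (seed ", seed, ")")
      sc <- do.call(simulation_config,
                    cfg$simulate[names(cfg$simulate) != "seed"])
      simulate_cohort(sc, seed = seed)
    } else if (!is.null(cfg$inputs$dir)) {
      read_cohort(cfg$inputs$dir)
    } else if (!is.null(cfg$inputs)) {
      inp <- cfg$inputs
      expr <- read_expression(inp$expression,
                              scale = if (!is.null(inp$scale)) inp$scale
                                else "log2",
                              level = if (!is.null(inp$level)) inp$level
                                else "probe")
      cohort_dataset(
        expr, read_sample_table(inp$samples),
        probes = if (!is.null(inp$probes)) {
          p <- .read_delim(inp$probes)
          probe_annotation(p$probe_id, p$gene_symbol, p$replicate_group)
        },
        clinical = if (!is.null(inp$clinical))
          read_clinical_table(inp$clinical),
        annotation = if (!is.null(inp$annotation))
          read_gene_annotation(inp$annotation))
    } else stop("config needs a 'simulate' or 'inputs' section")
  })

  ## -- preprocess --------------------------------------------------------
  gm <- stage("preprocess", {
    m <- cohort$expression
    if (m$scale == "count") {
      m <- size_factor_normalize(m)
      if (m$level != "gene") m <- collapse_probes_to_genes(m, cohort$probes)
      m
    } else {
      m <- quantile_normalize(m)
      if (isTRUE(cfg$batch_center)) m <- center_batches(m, cohort$samples)
      if (m$level == "probe") {
        if (is.null(cohort$probes))
          stop("probe-level matrix without probe annotation")
        m <- average_technical_replicates(m, cohort$probes)
        m <- collapse_probes_to_genes(m, cohort$probes)
      }
      m
    }
  })

  ## -- deregulation ------------------------------------------------------
  calls <- stage("deregulation", {
    present <- intersect(genes, feature_ids(gm))
    if (length(present) == 0L)
      stop("none of the target genes present: ",
           paste(genes, collapse = ", "))
    if (length(present) < length(genes))
      warning("target gene(s) absent: ",
              paste(setdiff(genes, present), collapse = ", "))
    cl <- call_deregulation(gm, cohort$samples, genes = present,
                            upper = upper, lower = lower)
    .write_tsv(cl, file.path(out_dir, "deregulation_calls.tsv"))
    .write_tsv(summarize_deregulation(cl),
               file.path(out_dir, "deregulation_summary.tsv"))
    cl
  })
  genes <- unique(calls$gene_symbol)

  ## -- compensation ------------------------------------------------------
  stage("compensation", {
    if (length(genes) >= 2L) {
      pairs <- utils::combn(genes[seq_len(min(3L, length(genes)))], 2L)
      for (k in seq_len(ncol(pairs))) {
        ga <- pairs[1L, k]; gb <- pairs[2L, k]
        ct <- cross_tabulate(calls, gene_a = ga, gene_b = gb)
        mt <- stats::addmargins(unclass(ct))
        .write_tsv(as.data.frame.matrix(cbind(call = rownames(mt), mt)),
                   file.path(out_dir, sprintf("crosstab_%s_%s.tsv", ga,
                                              gb)))
        cf <- compensation_fractions(ct)
        pt <- suppressWarnings(
          coupling_permutation_test(calls[calls$gene_symbol == ga, ],
                                    calls[calls$gene_symbol == gb, ],
                                    n_perm = n_perm, seed = seed))
        jsonlite::write_json(
          list(gene_a = ga, gene_b = gb,
               frac_down_a_up_b = cf$frac_down_a_up_b,
               frac_up_a_down_b = cf$frac_up_a_down_b,
               n_down_a = cf$n_down_a, n_up_a = cf$n_up_a, n = cf$n,
               permutation = list(statistic = pt$statistic,
                                  p_value = pt$p_value,
                                  n_perm = pt$n_perm, seed = pt$seed)),
          file.path(out_dir, sprintf("compensation_%s_%s.json", ga, gb)),
          auto_unbox = TRUE, digits = NA, na = "null")
      }
    }
  })

  ## -- locus window ------------------------------------------------------
  stage("locus_window", {
    if (!is.null(cohort$annotation) &&
        anchor %in% cohort$annotation$gene_symbol) {
      wp <- window_lfc_matrix(gm, cohort$samples, cohort$annotation,
                              window_spec(anchor, flank),
                              intensity_threshold = ithr)
      .write_tsv(wp$genes, file.path(out_dir, "window_genes.tsv"))
      lfc <- data.frame(gene_symbol = rownames(wp$lfc), wp$lfc,
                        check.names = FALSE)
      .write_tsv(lfc, file.path(out_dir, "window_lfc.tsv"))
      up_pat <- calls$patient_id[calls$gene_symbol == anchor &
                                   calls$call == "up"]
      cc <- coamplification_call(wp)
      cc$anchor_up <- cc$patient_id %in% up_pat
      .write_tsv(cc, file.path(out_dir, "coamplification_calls.tsv"))
    } else note("window stage skipped (no annotation for anchor)")
  })

  ## -- survival ----------------------------------------------------------
  stage("survival", {
    if (isTRUE(cfg$skip_survival)) {
      note("survival stage skipped by config")
    } else if (is.null(cohort$clinical)) {
      warning("no clinical table; survival stage skipped")
    } else {
      surv_rows <- list(); cox_rows <- list(); lr_rows <- list()
      for (g in genes) for (st in strata) for (ep in endpoints) {
        rep <- tryCatch(
          survival_by_deregulation(calls, cohort$clinical, g, stratum = st,
                                   endpoint = ep, min_group = min_group),
          error = function(e) NULL)
        if (is.null(rep)) next
        tb <- rep$table
        tb <- cbind(gene = g, stratum = st, endpoint = ep, tb)
        surv_rows[[length(surv_rows) + 1L]] <- tb
        if (!is.null(rep$cox))
          cox_rows[[length(cox_rows) + 1L]] <-
            cbind(gene = g, stratum = st, endpoint = ep,
                  as.data.frame(rep$cox))
        if (!is.null(rep$logrank))
          lr_rows[[length(lr_rows) + 1L]] <-
            data.frame(gene = g, stratum = st, endpoint = ep,
                       chisq = rep$logrank$statistic, df = rep$logrank$df,
                       p_value = rep$logrank$p_value)
      }
      if (length(surv_rows))
        .write_tsv(do.call(rbind, surv_rows),
                   file.path(out_dir, "survival_five_year.tsv"))
      if (length(cox_rows))
        .write_tsv(do.call(rbind, cox_rows),
                   file.path(out_dir, "survival_cox.tsv"))
      if (length(lr_rows))
        .write_tsv(do.call(rbind, lr_rows),
                   file.path(out_dir, "survival_logrank.tsv"))
    }
  })

  ## -- manifest (written last: its presence marks a complete run) --------
  manifest <- list(
    package = "cyclinpair",
    version = as.character(utils::packageVersion("cyclinpair")),
    seed = seed, genes = genes, anchor = anchor, flank = flank,
    thresholds = list(upper = upper, lower = lower),
    intensity_threshold = ithr, permutations = n_perm,
    min_group = min_group, endpoints = endpoints, strata = strata,
    simulated = !is.null(cfg$simulate),
    inputs = if (is.null(cfg$simulate)) cfg$inputs else cfg$simulate,
    multiple_testing = "none; raw p-values as reported")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("report written to ", out_dir)
  invisible(manifest)
}

#' Clinical association tests between HPV strata
#'
#' For each declared variable, tests its association with HPV status:
#' continuous variables with a Kruskal-Wallis test across HPV groups,
#' categorical ones with Fisher's exact test. Variables with a single
#' observed level are skipped with a note. Significance stars: `*` for
#' p < 0.05, `***` for p < 0.001.
#'
#' @param samples a [sample_table()] (one row per patient is derived from
#'   the tumor samples; patients with unknown HPV status are excluded).
#' @param data `data.frame` keyed by `patient_id` holding the variables.
#' @param variables named character vector: names are columns of `data`,
#'   values are `"continuous"` or `"categorical"`.
#' @return A `data.frame` with `variable`, `test`, `statistic`, `p_value`,
#'   `signif`, `note`.
#' @export
clinical_association_tests <- function(samples, data, variables) {
  stopifnot(inherits(samples, "sample_table"))
  tum <- samples[samples$tissue == "tumor" &
                   samples$hpv_status != "unknown", ]
  hpv <- tum$hpv_status[match(data$patient_id, tum$patient_id)]
  keep <- !is.na(hpv)
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    x <- data[[v]][keep]
    g <- hpv[keep]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L)
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        signif = "", note = "skipped: single level",
                        stringsAsFactors = FALSE))
    if (type == "continuous") {
      kt <- stats::kruskal.test(x[ok], factor(g[ok]))
      res <- c(unname(kt$statistic), kt$p.value)
      test <- "kruskal_wallis"
    } else {
      ft <- stats::fisher.test(table(x[ok], g[ok]))
      res <- c(NA_real_, ft$p.value)
      test <- "fisher_exact"
    }
    data.frame(variable = v, test = test, statistic = res[1L],
               p_value = res[2L],
               signif = if (res[2L] < 0.001) "***"
                 else if (res[2L] < 0.05) "*" else "n.s.",
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
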