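#' Simulation configuration for a paired tumor/normal cohort
#'
#' Defines the generative model behind [simulate_cohort()]. The defaults
#' describe a cohort of the size and composition of the study the pipeline
#' was built for: 82 paired HNSCC patients, ~30% HPV-positive, anchor-gene
#' (CCND1-like) deregulation class probabilities echoing the observed
#' stratum fractions, a partner gene (CCND2-like) whose class is coupled to
#' the anchor's in the opposite direction with probability `coupling_kappa`,
#' a block of window genes on a synthetic chromosome around the anchor that
#' are co-upregulated in amplified anchor-up patients, and exponential
#' group-dependent survival with uniform right censoring.
#'
#' Generative model, per patient: HPV status ~ Bernoulli(`hpv_pos_fraction`);
#' anchor class from the stratum's `class_probs_a`; with probability
#' `coupling_kappa` a class-deregulated patient's partner gene takes the
#' opposite class, otherwise the partner class is drawn from
#' `class_probs_b`. Probe-level normal-tissue intensity =
#' `baseline_mean` + gene effect + patient effect + probe effect + noise;
#' the paired tumor intensity is that same value plus the patient's tumor
#' shift for the gene, drawn `N(lfc_mean_class, lfc_sd)` for the anchor and
#' partner, `N(amp_mu, lfc_sd)` for downstream window genes of amplified
#' patients, and `N(0, lfc_sd)` otherwise. Because the tumor value is the
#' normal value plus the shift, measurement noise cancels in the paired
#' fold change and the drawn shift is exactly the patient's log2 fold
#' change.
#'
#' @param n_patients number of paired patients (default 82).
#' @param hpv_pos_fraction probability of HPV-positive status (default
#'   25/82).
#' @param class_probs_a named list with elements `hpv_pos` and `hpv_neg`,
#'   each a probability vector over `(up, not, down)` for the anchor gene.
#' @param coupling_kappa probability that a class-deregulated patient's
#'   partner gene takes the opposite class (default 0.35).
#' @param class_probs_b marginal class probabilities for the partner gene
#'   among uncoupled patients (default the observed CCND2 fractions).
#' @param lfc_mean_up,lfc_mean_down,lfc_sd tumor-shift distribution (log2
#'   units) per class; the `not` class is centred at 0.
#' @param baseline_mean,gene_sd,patient_sd,probe_sd,residual_sd log2
#'   intensity model for the normal tissue.
#' @param n_window_genes window genes per side of the anchor (default 8).
#' @param window_unexpressed_fraction fraction of window genes given a low
#'   baseline (below the intensity filter), emulating probes below the
#'   detection threshold (default 0.3).
#' @param amp_mu mean extra log2 shift on downstream window genes of
#'   amplified patients (default 1.5).
#' @param p_amp probability that an anchor-up patient is amplified
#'   (default 0.93).
#' @param probes_per_gene probes per gene (default 2).
#' @param replicate_fraction fraction of probes duplicated as technical
#'   replicates (default 0.2).
#' @param n_background_genes unrelated genes filling out the matrix so the
#'   matrix-wide stages (quantile normalization, intensity filter) operate
#'   on a realistic value distribution (default 300).
#' @param base_hazard named monthly baseline hazards per HPV stratum;
#'   defaults give five-year OS near the observed 77% / 32%.
#' @param group_loghr named log hazard ratios per anchor class relative to
#'   baseline (default all 0: deregulation does not shift survival).
#' @param censor_max upper bound of the uniform censoring window in months
#'   (default 139, the observed follow-up maximum).
#' @param anchor_symbol,partner_symbol gene names used for the anchor and
#'   partner (defaults `"CCND1"`, `"CCND2"`).
#' @param seed default seed used when [simulate_cohort()] is called without
#'   one.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 82,
    hpv_pos_fraction = 25 / 82,
    class_probs_a = list(hpv_pos = c(up = 0.04, not = 0.44, down = 0.52),
                         hpv_neg = c(up = 0.246, not = 0.631, down = 0.123)),
    coupling_kappa = 0.35,
    class_probs_b = c(up = 0.317, not = 0.598, down = 0.085),
    lfc_mean_up = 1.8, lfc_mean_down = -1.8, lfc_sd = 0.3,
    baseline_mean = 8, gene_sd = 1, patient_sd = 0.5, probe_sd = 0.3,
    residual_sd = 0.25,
    n_window_genes = 8, window_unexpressed_fraction = 0.3,
    amp_mu = 1.5, p_amp = 0.93,
    probes_per_gene = 2, replicate_fraction = 0.2,
    n_background_genes = 300,
    base_hazard = c(hpv_pos = 0.005, hpv_neg = 0.02),
    group_loghr = c(up = 0, not = 0, down = 0),
    censor_max = 139,
    anchor_symbol = "CCND1", partner_symbol = "CCND2",
    seed = 1L) {
  cfg <- as.list(environment())
  .validate_sim_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  probs_ok <- function(p) all(p >= 0) && abs(sum(p) - 1) < 1e-9
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (cfg$hpv_pos_fraction < 0 || cfg$hpv_pos_fraction > 1)
    stop("hpv_pos_fraction must lie in [0, 1]")
  if (!all(c("hpv_pos", "hpv_neg") %in% names(cfg$class_probs_a)))
    stop("class_probs_a needs 'hpv_pos' and 'hpv_neg' entries")
  for (p in cfg$class_probs_a)
    if (!probs_ok(p)) stop("class_probs_a entries must sum to 1")
  if (!probs_ok(cfg$class_probs_b))
    stop("class_probs_b must sum to 1")
  if (cfg$coupling_kappa < 0 || cfg$coupling_kappa > 1)
    stop("coupling_kappa must lie in [0, 1]")
  for (s in c("lfc_sd", "gene_sd", "patient_sd", "probe_sd", "residual_sd"))
    if (cfg[[s]] <= 0) stop(s, " must be > 0")
  if (any(cfg$base_hazard <= 0)) stop("baseline hazards must be > 0")
  if (cfg$censor_max <= 0) stop("censor_max must be > 0")
  if (cfg$probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  invisible(TRUE)
}

# deterministic per-component sub-seeds: truth, layout, expression and
# survival use separate streams, so changing one component's draw count
# (e.g. more probes) never reshuffles the others
.sub_seed <- function(seed, k) (as.integer(seed) + 104729L * k) %% 2147483647L

.draw_class <- function(n, probs) {
  lv <- c("up", "not", "down")
  lv[1L + findInterval(stats::runif(n), cumsum(probs[lv]))]
}

.opposite <- c(up = "down", not = "not", down = "up")

#' Simulate a paired tumor/normal cohort with ground truth
#'
#' Emits a complete probe-level cohort: log2 expression for one tumor and
#' one normal sample per patient, probe annotation with technical
#' replicates, gene coordinates laying the window genes on a synthetic
#' chromosome around the anchor, sample metadata with HPV status, clinical
#' follow-up with exponential survival and uniform right censoring (times
#' rounded to whole months, so tied event times occur as in real follow-up
#' data), and the per-patient simulation truth. Fully reproducible given
#' the seed; the session RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A [cohort_dataset()] whose `truth` is a `data.frame` with one
#'   row per patient: `patient_id`, `hpv_status`, `class_a`, `class_b`,
#'   `coupled`, `amplified`, `surv_group`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_sim_config(config)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))

  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  ## -- truth stream ------------------------------------------------------
  set.seed(.sub_seed(seed, 1L))
  hpv <- ifelse(stats::runif(n) < config$hpv_pos_fraction,
                "positive", "negative")
  class_a <- character(n)
  class_a[hpv == "positive"] <-
    .draw_class(sum(hpv == "positive"), config$class_probs_a$hpv_pos)
  class_a[hpv == "negative"] <-
    .draw_class(sum(hpv == "negative"), config$class_probs_a$hpv_neg)
  coupled <- stats::runif(n) < config$coupling_kappa & class_a != "not"
  class_b <- .draw_class(n, config$class_probs_b)
  class_b[coupled] <- unname(.opposite[class_a[coupled]])
  amplified <- class_a == "up" & stats::runif(n) < config$p_amp

  truth <- data.frame(patient_id = pid, hpv_status = hpv,
                      class_a = class_a, class_b = class_b,
                      coupled = coupled, amplified = amplified,
                      surv_group = class_a, stringsAsFactors = FALSE)

  ## -- gene / probe layout stream ---------------------------------------
  set.seed(.sub_seed(seed, 2L))
  nw <- config$n_window_genes
  anchor_start <- 69e6
  anchor_end <- anchor_start + 1e4
  layout <- list(data.frame(gene_symbol = config$anchor_symbol,
                            chromosome = "chrS", start = anchor_start,
                            end = anchor_end, role = "anchor",
                            stringsAsFactors = FALSE))
  if (nw > 0) {
    sp <- 1e6 / (nw + 1)                     # even spacing inside the flank
    up <- data.frame(gene_symbol = sprintf("WGU%02d", seq_len(nw)),
                     chromosome = "chrS",
                     start = anchor_start - sp * seq_len(nw) - 2e4,
                     end = anchor_start - sp * seq_len(nw),
                     role = "window_up", stringsAsFactors = FALSE)
    dn <- data.frame(gene_symbol = sprintf("WGD%02d", seq_len(nw)),
                     chromosome = "chrS",
                     start = anchor_end + sp * seq_len(nw),
                     end = anchor_end + sp * seq_len(nw) + 2e4,
                     role = "window_down", stringsAsFactors = FALSE)
    layout <- c(layout, list(up, dn))
  }
  genes <- do.call(rbind, layout)
  genes <- rbind(genes,
                 data.frame(gene_symbol = config$partner_symbol,
                            chromosome = "chrP", start = 4e6, end = 4.03e6,
                            role = "partner", stringsAsFactors = FALSE))
  if (config$n_background_genes > 0) {
    nb <- config$n_background_genes
    genes <- rbind(genes,
                   data.frame(gene_symbol = sprintf("BG%03d", seq_len(nb)),
                              chromosome = "chrB",
                              start = 1e5 * seq_len(nb),
                              end = 1e5 * seq_len(nb) + 3e4,
                              role = "background", stringsAsFactors = FALSE))
  }
  ng <- nrow(genes)
  is_window <- genes$role %in% c("window_up", "window_down")
  unexpressed <- rep(FALSE, ng)
  unexpressed[is_window] <-
    stats::runif(sum(is_window)) < config$window_unexpressed_fraction
  gene_base <- config$baseline_mean +
    stats::rnorm(ng, sd = config$gene_sd)
  gene_base[unexpressed] <- stats::rnorm(sum(unexpressed), mean = 3,
                                         sd = 0.5)
  # anchor and partner stay detectable so their fold changes are defined
  gene_base[genes$role %in% c("anchor", "partner")] <-
    pmax(gene_base[genes$role %in% c("anchor", "partner")],
         config$baseline_mean)

  ppg <- config$probes_per_gene
  probe <- data.frame(
    probe_id = sprintf("%s_p%d", rep(genes$gene_symbol, each = ppg),
                       rep(seq_len(ppg), ng)),
    gene_symbol = rep(genes$gene_symbol, each = ppg),
    replicate_group = NA_character_, stringsAsFactors = FALSE)
  probe_eff <- stats::rnorm(nrow(probe), sd = config$probe_sd)
  # duplicate a fraction of probes as technical replicates
  is_rep <- stats::runif(nrow(probe)) < config$replicate_fraction
  if (any(is_rep)) {
    rep_rows <- probe[is_rep, , drop = FALSE]
    grp <- paste0(rep_rows$probe_id, "_grp")
    probe$replicate_group[is_rep] <- grp
    rep_rows$replicate_group <- grp
    rep_rows$probe_id <- paste0(rep_rows$probe_id, "r")
    probe <- rbind(probe, rep_rows)
    probe_eff <- c(probe_eff, probe_eff[is_rep])   # same probe sequence
  }
  np <- nrow(probe)
  gene_of_probe <- match(probe$gene_symbol, genes$gene_symbol)

  ## -- expression stream (patient-major sample order) --------------------
  set.seed(.sub_seed(seed, 3L))
  patient_eff <- stats::rnorm(n, sd = config$patient_sd)
  mu <- c(up = config$lfc_mean_up, not = 0, down = config$lfc_mean_down)
  shift <- matrix(stats::rnorm(ng * n, sd = config$lfc_sd), ng, n)
  shift[genes$role == "anchor", ] <-
    shift[genes$role == "anchor", ] + mu[class_a]
  shift[genes$role == "partner", ] <-
    shift[genes$role == "partner", ] + mu[class_b]
  if (any(genes$role == "window_down"))
    shift[genes$role == "window_down", amplified] <-
      shift[genes$role == "window_down", amplified, drop = FALSE] +
      config$amp_mu
  noise <- matrix(stats::rnorm(np * n, sd = config$residual_sd), np, n)
  normal <- gene_base[gene_of_probe] + probe_eff +
    rep(patient_eff, each = np) + noise
  tumor <- normal + shift[gene_of_probe, , drop = FALSE]
  vals <- matrix(0, np, 2L * n)
  vals[, seq(1L, 2L * n, by = 2L)] <- normal
  vals[, seq(2L, 2L * n, by = 2L)] <- tumor
  sidN <- paste0(pid, "_N")
  sidT <- paste0(pid, "_T")
  colnames(vals) <- as.vector(rbind(sidN, sidT))
  rownames(vals) <- probe$probe_id
  expr <- expression_matrix(vals, level = "probe", scale = "log2")

  samples <- sample_table(
    sample_id = colnames(vals),
    patient_id = rep(pid, each = 2L),
    tissue = rep(c("normal", "tumor"), n),
    hpv_status = rep(hpv, each = 2L),
    batch = "b1")

  ## -- survival stream ---------------------------------------------------
  set.seed(.sub_seed(seed, 4L))
  base <- ifelse(hpv == "positive", config$base_hazard["hpv_pos"],
                 config$base_hazard["hpv_neg"])
  loghr <- config$group_loghr[class_a]
  rate <- base * exp(unname(loghr))
  ev_time <- stats::rexp(n, rate = rate)
  cens <- stats::runif(n, 0, config$censor_max)
  os_event <- as.integer(ev_time <= cens)
  os_months <- round(pmin(ev_time, cens))
  dfs_time <- stats::rexp(n, rate = 1.3 * rate)
  dfs_event <- as.integer(dfs_time <= pmin(ev_time, cens))
  dfs_months <- round(pmin(dfs_time, ev_time, cens))
  dfs_status <- ifelse(dfs_event == 1L,
                       ifelse(dfs_time < ev_time, "recidive",
                              "exitus_disease"),
                       ifelse(os_event == 1L, "exitus_other",
                              "disease_free"))
  clinical <- clinical_table(pid, os_months, os_event,
                             dfs_months = dfs_months,
                             dfs_status = dfs_status)

  annotation <- gene_annotation(genes$gene_symbol, genes$chromosome,
                                genes$start, genes$end)
  attr(truth, "gene_roles") <-
    data.frame(gene_symbol = genes$gene_symbol, role = genes$role,
               design_unexpressed = unexpressed, stringsAsFactors = FALSE)
  probes <- probe_annotation(probe$probe_id, probe$gene_symbol,
                             probe$replicate_group)
  cohort_dataset(expr, samples, probes = probes, clinical = clinical,
                 annotation = annotation, truth = truth)
}

#' Simulate group-dependent survival records
#'
#' The survival sub-model of [simulate_cohort()] in isolation: exponential
#' event times with hazard `base_hazard * exp(group_loghr[group])`, uniform
#' right censoring on `[0, censor_max]`, times rounded to whole months.
#' Useful for parameter-recovery and operating-characteristic studies of
#' the survival operations.
#'
#' @param groups character vector of group labels (one per subject).
#' @param base_hazard baseline monthly hazard.
#' @param group_loghr named log hazard ratios, one per group level.
#' @param censor_max uniform censoring upper bound (months).
#' @param seed integer seed.
#' @return A `data.frame` with `time`, `event`, `group`.
#' @export
simulate_survival_records <- function(groups, base_hazard = 0.02,
                                      group_loghr, censor_max = 139,
                                      seed) {
  if (missing(seed)) stop("a seed is required")
  groups <- as.character(groups)
  if (!all(groups %in% names(group_loghr)))
    stop("group_loghr must name every group level")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(groups)
  rate <- base_hazard * exp(unname(group_loghr[groups]))
  ev <- stats::rexp(n, rate = rate)
  cens <- stats::runif(n, 0, censor_max)
  data.frame(time = round(pmin(ev, cens)),
             event = as.integer(ev <= cens),
             group = groups, stringsAsFactors = FALSE)
}

#' Confusion matrix of calls against simulation truth
#'
#' Rows are the true classes, columns the called classes, for the anchor
#' (or, with `gene = "partner"`, the partner) gene.
#'
#' @param calls a [call_deregulation()] result containing the gene.
#' @param truth the `truth` component of a simulated [cohort_dataset()].
#' @param gene `"anchor"` or `"partner"` — which truth column to compare.
#' @param gene_symbol the gene symbol in `calls` (defaults to the only
#'   gene present).
#' @return A 3x3 `table`, truth in rows, calls in columns.
#' @export
truth_confusion <- function(calls, truth, gene = c("anchor", "partner"),
                            gene_symbol = NULL) {
  gene <- match.arg(gene)
  col <- if (gene == "anchor") "class_a" else "class_b"
  if (is.null(gene_symbol)) {
    gs <- unique(calls$gene_symbol)
    if (length(gs) != 1L)
      stop("multiple genes in calls; give gene_symbol")
    gene_symbol <- gs
  }
  sub <- calls[calls$gene_symbol == gene_symbol, ]
  if (!setequal(sub$patient_id, truth$patient_id))
    stop("calls and truth cover different patients")
  idx <- match(sub$patient_id, truth$patient_id)
  lv <- c("up", "not", "down")
  table(truth = factor(truth[[col]][idx], levels = lv),
        called = factor(sub$call, levels = lv))
}
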