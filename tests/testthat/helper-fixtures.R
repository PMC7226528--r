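# Small builders used across the module tests.

# minimal gene-level matrix: genes x (P*_N, P*_T) columns from a named list
# of per-gene (normal, tumor) value pairs per patient
toy_gene_matrix <- function(normal, tumor) {
  stopifnot(identical(dim(normal), dim(tumor)))
  n <- ncol(normal)
  pid <- sprintf("P%02d", seq_len(n))
  vals <- matrix(NA_real_, nrow(normal), 2 * n)
  vals[, seq(1, 2 * n, 2)] <- normal
  vals[, seq(2, 2 * n, 2)] <- tumor
  colnames(vals) <- as.vector(rbind(paste0(pid, "_N"), paste0(pid, "_T")))
  rownames(vals) <- rownames(normal)
  expression_matrix(vals, level = "gene", scale = "log2")
}

toy_samples <- function(n, hpv = "negative") {
  pid <- sprintf("P%02d", seq_len(n))
  sample_table(sample_id = as.vector(rbind(paste0(pid, "_N"),
                                           paste0(pid, "_T"))),
               patient_id = rep(pid, each = 2),
               tissue = rep(c("normal", "tumor"), n),
               hpv_status = rep(hpv, length.out = 2 * n))
}

# fast simulator configuration: anchor + partner only, one probe per gene
fast_config <- function(...) {
  simulation_config(probes_per_gene = 1, replicate_fraction = 0,
                    n_window_genes = 0, n_background_genes = 0,
                    window_unexpressed_fraction = 0, ...)
}

# collapse a simulated cohort to gene level without renormalization (the
# simulator emits intensities that are already comparable across samples)
collapse_cohort <- function(co) {
  m <- co$expression
  if (any(!is.na(co$probes$replicate_group)))
    m <- average_technical_replicates(m, co$probes)
  collapse_probes_to_genes(m, co$probes)
}
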