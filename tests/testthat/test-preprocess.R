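mk <- function(vals, level = "gene", scale = "log2") {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("g%d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%d", seq_len(ncol(vals)))
  expression_matrix(vals, level = level, scale = scale)
}

test_that("quantile normalization maps samples onto the mean distribution", {
  m <- mk(cbind(c(1, 3), c(2, 4)))
  q <- quantile_normalize(m)
  expect_equal(unname(q$values), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  # single sample: the reference is the sample itself
  m1 <- mk(matrix(c(5, 1, 9), 3, 1))
  expect_equal(quantile_normalize(m1)$values, m1$values)

  # definitional postcondition: sorted columns identical afterwards
  set.seed(1)
  r <- mk(matrix(rnorm(60, 8, 2), 12, 5))
  q2 <- quantile_normalize(r)
  srt <- apply(q2$values, 2, sort)
  expect_true(max(abs(srt - srt[, 1])) < 1e-12)
  # rank order within each sample is preserved
  expect_equal(apply(q2$values, 2, rank), apply(r$values, 2, rank))

  # idempotence
  q3 <- quantile_normalize(q2)
  expect_lt(max(abs(q3$values - q2$values)), 1e-9)

  expect_warning(quantile_normalize(mk(matrix(c(1, 2), 1, 2))),
                 "single-feature")
})

test_that("technical replicates average on the log2 scale", {
  vals <- matrix(c(5, 7, 3, 1, 4, 5, 6, 2), 4, 2,
                 dimnames = list(c("p1", "p1r", "p2", "p3"), c("s1", "s2")))
  pa <- probe_annotation(c("p1", "p1r", "p2", "p3"),
                         c("gA", "gA", "gA", "gB"),
                         c("grp1", "grp1", NA, NA))
  av <- average_technical_replicates(mk(vals, level = "probe"), pa)
  expect_equal(nrow(av$values), 3L)
  expect_equal(unname(av$values["grp1", ]), c((5 + 7) / 2, (4 + 5) / 2))
  expect_equal(unname(av$values["p2", ]), c(3, 6))   # singleton passthrough

  # three replicates (4,5,6) -> 5
  v3 <- matrix(c(4, 5, 6), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  pa3 <- probe_annotation(c("a", "b", "c"), "g", c("G", "G", "G"))
  expect_equal(unname(average_technical_replicates(
    mk(v3, level = "probe"), pa3)$values[1, ]), 5)
})

test_that("probes collapse to per-gene means and unmapped probes drop", {
  vals <- matrix(c(6, 8, 3, 1), 4, 1,
                 dimnames = list(c("p1", "p2", "p3", "p4"), "s1"))
  pa <- probe_annotation(c("p1", "p2", "p3", "p4"),
                         c("gA", "gA", "gB", NA))
  expect_message(g <- collapse_probes_to_genes(mk(vals, level = "probe"),
                                               pa), "1 unmapped")
  expect_equal(sort(feature_ids(g)), c("gA", "gB"))
  expect_equal(unname(g$values["gA", ]), 7)
  expect_equal(unname(g$values["gB", ]), 3)   # single probe is identity
  expect_equal(g$level, "gene")

  pa_none <- probe_annotation(c("p1", "p2", "p3", "p4"), NA_character_)
  expect_error(collapse_probes_to_genes(mk(vals, level = "probe"), pa_none),
               "no probe maps")
})

test_that("intensity filter removes strictly-below-threshold genes only", {
  vals <- matrix(c(4.9, 5.0, 5.1), 3, 1,
                 dimnames = list(c("lo", "edge", "hi"), "s1"))
  f <- filter_low_expression(mk(vals))
  expect_setequal(feature_ids(f), c("edge", "hi"))
  expect_equal(attr(f, "removed"), "lo")
  expect_error(filter_low_expression(mk(vals), threshold = 10),
               "all genes")
})

test_that("collapse-then-filter commutes with filter for 1:1 mappings", {
  set.seed(3)
  vals <- matrix(rnorm(20, 5, 1), 10, 2,
                 dimnames = list(sprintf("p%d", 1:10),
                                 sprintf("s%d", 1:2)))
  pa <- probe_annotation(sprintf("p%d", 1:10), sprintf("g%d", 1:10))
  a <- filter_low_expression(collapse_probes_to_genes(mk(vals,
                                                         level = "probe"),
                                                      pa))
  pre <- mk(vals, level = "probe")
  rownames(pre$values) <- sprintf("g%d", 1:10)
  pre$level <- "gene"
  b <- filter_low_expression(pre)
  expect_setequal(feature_ids(a), feature_ids(b))
  expect_equal(a$values[sort(feature_ids(a)), ],
               b$values[sort(feature_ids(a)), ])
})

test_that("median-of-ratios size factors behave as defined", {
  cnt <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
                dimnames = list(sprintf("g%d", 1:3), c("A", "B")))
  n1 <- size_factor_normalize(mk(cnt, scale = "count"))
  expect_equal(unname(attr(n1, "size_factors")), c(1, 1))

  cnt2 <- cnt; cnt2[, 2] <- 2L * cnt2[, 1]
  n2 <- size_factor_normalize(mk(cnt2, scale = "count"))
  sf <- attr(n2, "size_factors")
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf[2] / sf[1]), 2)
  # normalized values equalize the two samples
  expect_equal(n2$values[, 1], n2$values[, 2])

  zero <- matrix(c(0L, 5L, 0L, 7L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  zero[2, 1] <- 0L   # now every gene has a zero somewhere
  expect_error(size_factor_normalize(mk(zero, scale = "count")),
               "no reference genes")
})

test_that("scaling one sample's counts scales its size factor, leaving
           normalized values invariant", {
  set.seed(7)
  cnt <- matrix(rpois(40, 50) + 1L, 10, 4,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  base <- size_factor_normalize(mk(cnt, scale = "count"))
  sf0 <- attr(base, "size_factors")
  for (c_mult in c(2, 5)) {
    cnt2 <- cnt; cnt2[, 3] <- as.integer(cnt2[, 3] * c_mult)
    scl <- size_factor_normalize(mk(cnt2, scale = "count"))
    r <- attr(scl, "size_factors") / sf0
    # sample 3's factor moves by c relative to the others; the geometric-
    # mean reference spreads a common c^(-1/n) over everyone
    expect_equal(unname(r[3] / r[1]), c_mult, tolerance = 1e-12)
    expect_equal(unname(r[-3]), rep(c_mult^(-1 / 4), 3), tolerance = 1e-12)
    # depth-corrected linear values are invariant up to that common factor
    lin_base <- sweep(cnt, 2, sf0, "/")
    lin_scl <- sweep(cnt2, 2, attr(scl, "size_factors"), "/")
    expect_equal(lin_scl, lin_base * c_mult^(1 / 4), tolerance = 1e-12)
  }
})

test_that("size factors agree with the established median-of-ratios
           implementation", {
  set.seed(11)
  cnt <- matrix(rpois(120, 80) + 1L, 20, 6,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:6)))
  ours <- attr(size_factor_normalize(mk(cnt, scale = "count")),
               "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("per-batch centering removes additive batch offsets", {
  set.seed(5)
  n <- 6
  st <- toy_samples(n)
  st$batch <- rep(c("b1", "b2"), each = n)   # first 6 cols vs last 6
  vals <- matrix(rnorm(2 * 2 * n, 8), 2, 2 * n,
                 dimnames = list(c("g1", "g2"), st$sample_id))
  shifted <- vals
  shifted[, st$batch == "b2"] <- shifted[, st$batch == "b2"] + 3
  cen <- center_batches(mk(shifted), st)
  # batch means per gene equalize at the gene's grand mean
  for (b in c("b1", "b2"))
    expect_equal(rowMeans(cen$values[, st$batch == b]),
                 rowMeans(shifted))
  # within-batch contrasts are untouched (only an additive offset moves)
  off <- cen$values - shifted
  for (b in c("b1", "b2"))
    expect_lt(max(apply(off[, st$batch == b], 1, function(z)
      diff(range(z)))), 1e-12)
})

test_that("feature and sample names survive every stage", {
  co <- simulate_cohort(simulation_config(n_patients = 4,
                                          n_background_genes = 10,
                                          n_window_genes = 2), seed = 2)
  m <- quantile_normalize(co$expression)
  expect_identical(sample_ids(m), co$samples$sample_id)
  m2 <- average_technical_replicates(m, co$probes)
  m3 <- collapse_probes_to_genes(m2, co$probes)
  expect_identical(sample_ids(m3), co$samples$sample_id)
  expect_true(all(c("CCND1", "CCND2") %in% feature_ids(m3)))
})
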