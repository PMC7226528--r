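toy_annotation <- function() {
  # anchor occupies [10.0, 10.1] Mb; window at 1 Mb flank = [9.0, 11.1) Mb
  gene_annotation(
    gene_symbol = c("FAR_UP", "EDGE_UP", "NEAR_UP", "ANCH", "NEAR_DN",
                    "EDGE_DN", "FAR_DN", "OTHER_CHR"),
    chromosome = c(rep("chr11", 7), "chr2"),
    start = c(7.0e6, 8.95e6, 9.45e6, 10.0e6, 10.4e6, 11.05e6, 12.6e6,
              10.0e6),
    end = c(7.1e6, 9.05e6, 9.55e6, 10.1e6, 10.5e6, 11.15e6, 12.7e6,
            10.1e6))
}

test_that("window selection keeps overlapping genes with side labels", {
  ann <- toy_annotation()
  g <- select_window_genes(ann, window_spec("ANCH", flank = 1e6))
  expect_equal(g$gene_symbol,
               c("EDGE_UP", "NEAR_UP", "ANCH", "NEAR_DN", "EDGE_DN"))
  expect_equal(g$side,
               c("upstream", "upstream", "anchor", "downstream",
                 "downstream"))
  # a gene centred 0.5 Mb from the anchor start is upstream and included
  expect_true("NEAR_UP" %in% g$gene_symbol)
  # 1.5 Mb beyond the anchor end is out
  expect_false("FAR_DN" %in% g$gene_symbol)
  expect_false("OTHER_CHR" %in% g$gene_symbol)
  expect_error(select_window_genes(ann, window_spec("NOPE")),
               "anchor not in annotation")
})

test_that("membership is monotone in the flank", {
  set.seed(17)
  for (i in 1:10) {
    n <- 30
    starts <- sort(sample(1e6:2e7, n))
    ann <- gene_annotation(sprintf("G%02d", 1:n), "chr1", starts,
                           starts + 5e4)
    anchor <- sprintf("G%02d", sample(5:25, 1))
    flanks <- sort(sample(1e5:5e6, 4))
    prev <- character(0)
    for (f in flanks) {
      cur <- select_window_genes(ann, window_spec(anchor, f))$gene_symbol
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("reflecting coordinates about the anchor midpoint swaps sides", {
  ann <- toy_annotation()
  ann <- ann[ann$chromosome == "chr11", ]
  class(ann) <- c("gene_annotation", "data.frame")
  a <- ann[ann$gene_symbol == "ANCH", ]
  ctr <- a$start + a$end                     # reflection: x -> ctr - x
  ref <- gene_annotation(ann$gene_symbol, ann$chromosome,
                         ctr - ann$end, ctr - ann$start)
  g1 <- select_window_genes(ann, window_spec("ANCH", 1e6))
  g2 <- select_window_genes(ref, window_spec("ANCH", 1e6))
  expect_setequal(g1$gene_symbol, g2$gene_symbol)
  side1 <- setNames(g1$side, g1$gene_symbol)
  side2 <- setNames(g2$side, g2$gene_symbol)
  swap <- c(upstream = "downstream", downstream = "upstream",
            anchor = "anchor")
  expect_equal(unname(swap[side1[names(side2)]]), unname(side2))
})

test_that("the fold-change profile masks unexpressed genes but keeps them
           listed", {
  ann <- gene_annotation(c("A", "DN1", "DN2"), "chr1",
                         c(1e6, 1.2e6, 1.4e6), c(1.01e6, 1.21e6, 1.41e6))
  n <- 3
  normal <- matrix(c(8, 8, 3), 3, n, dimnames = list(c("A", "DN1", "DN2")))
  tumor <- normal + 1.0
  m <- toy_gene_matrix(normal, tumor)
  wp <- window_lfc_matrix(m, toy_samples(n), ann, window_spec("A", 1e6))
  expect_equal(wp$genes$gene_symbol, c("A", "DN1", "DN2"))
  expect_equal(wp$genes$expressed, c(TRUE, TRUE, FALSE))
  expect_equal(unname(wp$lfc["DN1", ]), rep(1.0, n))
  expect_true(all(is.na(wp$lfc["DN2", ])))

  # nothing expressed -> error
  lo <- toy_gene_matrix(normal - 6, tumor - 6)
  expect_error(window_lfc_matrix(lo, toy_samples(n), ann,
                                 window_spec("A", 1e6)),
               "no expressed gene")
})

test_that("co-amplification scores count qualifying downstream genes", {
  ann <- gene_annotation(c("A", sprintf("DN%d", 1:5)), "chr1",
                         c(1e6, 1.1e6 + 1:5 * 1e5),
                         c(1.01e6, 1.11e6 + 1:5 * 1e5))
  normal <- matrix(8, 6, 2, dimnames = list(c("A", sprintf("DN%d", 1:5))))
  tumor <- normal
  tumor[c("DN1", "DN2", "DN3"), 2] <- 8 + 1.5   # patient 2 amplified-like
  m <- toy_gene_matrix(normal, tumor)
  wp <- window_lfc_matrix(m, toy_samples(2), ann, window_spec("A", 1e6))
  cc <- coamplification_call(wp)
  expect_equal(cc$score_count, c(0L, 3L))
  expect_equal(cc$score_frac, c(0, 0.6))
  expect_equal(cc$flag, c(FALSE, TRUE))

  # no expressed downstream genes leaves the flag undefined
  ann2 <- gene_annotation(c("A", "UP1"), "chr1", c(1e6, 8.5e5),
                          c(1.01e6, 8.6e5))
  vals <- matrix(8, 2, 4, dimnames = list(c("A", "UP1"), sample_ids(m)))
  m2 <- expression_matrix(vals, level = "gene", scale = "log2")
  wp2 <- window_lfc_matrix(m2, toy_samples(2), ann2, window_spec("A", 1e6))
  cc2 <- coamplification_call(wp2)
  expect_true(all(is.na(cc2$flag)))
})

test_that("simulated amplified patients separate from unamplified ones", {
  cfg <- simulation_config(n_patients = 150, probes_per_gene = 1,
                           replicate_fraction = 0, n_background_genes = 0,
                           window_unexpressed_fraction = 0,
                           class_probs_a = list(
                             hpv_pos = c(up = 1, not = 0, down = 0),
                             hpv_neg = c(up = 1, not = 0, down = 0)),
                           p_amp = 0.5)
  co <- simulate_cohort(cfg, seed = 33)
  m <- collapse_cohort(co)
  wp <- window_lfc_matrix(m, co$samples, co$annotation,
                          window_spec("CCND1"))
  cc <- coamplification_call(wp)
  amp <- co$truth$amplified[match(cc$patient_id, co$truth$patient_id)]
  sens <- mean(cc$flag[amp])
  spec <- mean(!cc$flag[!amp])
  expect_gt(sens, 0.95)
  expect_gt(spec, 0.95)
  # block-effect recovery: mean downstream lfc difference tracks amp_mu
  down <- wp$genes$side == "downstream" & wp$genes$expressed
  diffm <- mean(wp$lfc[down, amp]) - mean(wp$lfc[down, !amp])
  nobs <- sum(down) * sum(amp)
  expect_lt(abs(diffm - cfg$amp_mu), 3 * cfg$lfc_sd / sqrt(nobs) +
              3 * cfg$lfc_sd / sqrt(sum(down) * sum(!amp)))
})
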