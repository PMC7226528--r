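test_that("expression tables round-trip through TSV unchanged", {
  vals <- matrix(c(5.25, 6.5, 7.125, 8, 1.5, 2.75), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m <- expression_matrix(vals, level = "gene", scale = "log2")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  back <- read_expression(f, scale = "log2", level = "gene")
  expect_identical(back$values, m$values)
  expect_identical(feature_ids(back), feature_ids(m))
  expect_identical(sample_ids(back), sample_ids(m))
})

test_that("malformed expression input is rejected with a specific error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts1", "g1\t1\t2"), f)
  expect_error(read_expression(f), "duplicate sample ids")

  writeLines(c("id\ts1\ts2", "g1\t1\t-1"), f)
  expect_error(read_expression(f, scale = "count"), "non-negative")

  writeLines(c("id\ts1\ts2", "g1\t1\tx", "g2\t2\t3"), f)
  expect_error(read_expression(f), "column 's2', row 'g1'")

  expect_error(
    expression_matrix(matrix(1.5, 1, 1, dimnames = list("g", "s")),
                      scale = "count"), "integers")
  expect_error(
    expression_matrix(matrix(c(1, 2), 2, 1,
                             dimnames = list(c("g", "g"), "s")),
                      level = "gene"), "duplicate feature ids")
})

test_that("BED and GFF3 normalize to identical 0-based half-open intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr11\t69000000\t69100000\tGENE1\t0\t+", bed)
  a <- read_gene_annotation(bed)
  expect_equal(a$start, 69000000)
  expect_equal(a$end, 69100000)
  expect_equal(a$gene_symbol, "GENE1")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t101\t200\t.\t+\t.\tID=g1;Name=GENE1",
               "chr1\tt\tmRNA\t101\t200\t.\t+\t.\tID=m1;Parent=g1"), gff)
  g <- read_gene_annotation(gff)
  expect_equal(nrow(g), 1L)   # only type == gene
  expect_equal(g$start, 100)
  expect_equal(g$end, 200)

  # the same interval expressed in both conventions is internally identical
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tGENE1\t0\t+", bed2)
  b2 <- read_gene_annotation(bed2)
  expect_equal(b2[, c("start", "end")], g[, c("start", "end")])

  # idempotence through the package's own writer
  back <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(g, back)
  expect_equal(read_gene_annotation(back)[, 1:4], g[, 1:4])
})

test_that("degenerate annotation inputs error", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tGENE1", bed)
  expect_error(read_gene_annotation(bed), "start >= end")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", f)
  expect_error(read_gene_annotation(f), "unknown annotation format")
  expect_error(gene_annotation("g", "chr1", 200, 100), "start >= end")
})

test_that("pairing keeps exactly the tumor+normal patients", {
  st <- toy_samples(3)
  pr <- validate_pairing(st)
  expect_equal(length(pr$paired_ids), 3L)

  # tumor-only patient is excluded and counted
  st2 <- sample_table(c(st$sample_id, "P99_T"), c(st$patient_id, "P99"),
                      c(st$tissue, "tumor"))
  pr2 <- validate_pairing(st2)
  expect_equal(length(pr2$paired_ids), 3L)
  expect_equal(pr2$n_tumor_only, 1L)

  # two tumor samples for one patient is an ambiguity, not a choice
  st3 <- sample_table(c("a", "b", "c"), c("P1", "P1", "P1"),
                      c("tumor", "tumor", "normal"))
  expect_error(validate_pairing(st3), "ambiguous pairing")
})

test_that("a cohort-shaped sample list pairs like the study cohort", {
  # 82 paired patients, 8 tumor-only, 4 normal-only: 90 tumor + 86 normal
  pid <- sprintf("P%03d", 1:94)
  sid <- c(paste0(pid[1:90], "_T"), paste0(pid[c(1:82, 91:94)], "_N"))
  st <- sample_table(sid, sub("_[TN]$", "", sid),
                     ifelse(grepl("_T$", sid), "tumor", "normal"))
  expect_equal(sum(st$tissue == "tumor"), 90L)
  expect_equal(sum(st$tissue == "normal"), 86L)
  pr <- validate_pairing(st)
  expect_equal(length(pr$paired_ids), 82L)
  expect_equal(pr$n_tumor_only, 8L)
  expect_equal(pr$n_normal_only, 4L)
})

test_that("paired count never exceeds either tissue count", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    tissue <- sample(c("tumor", "normal"), n, replace = TRUE)
    patient <- sample(sprintf("P%d", 1:10), n, replace = TRUE)
    keep <- !duplicated(paste(patient, tissue))
    st <- sample_table(sprintf("s%d", seq_len(sum(keep))), patient[keep],
                       tissue[keep])
    pr <- validate_pairing(st)
    expect_lte(length(pr$paired_ids),
               min(sum(st$tissue == "tumor"), sum(st$tissue == "normal")))
  }
})

test_that("DFS events derive from the four-state vital status", {
  ct <- clinical_table(c("a", "b", "c", "d"), c(10, 20, 30, 40), c(1, 0, 0, 1),
                       dfs_months = c(5, 15, 25, 35),
                       dfs_status = c("recidive", "disease_free",
                                      "exitus_other", "exitus_disease"))
  expect_equal(ct$dfs_event, c(1L, 0L, 0L, 1L))
  expect_error(clinical_table("a", -1, 1), "negative")
  expect_error(clinical_table("a", 1, 1, dfs_months = 2,
                              dfs_status = "gone"), "dfs_status")
})

test_that("a full cohort round-trips through its on-disk form", {
  co <- simulate_cohort(simulation_config(n_patients = 6,
                                          n_background_genes = 5,
                                          n_window_genes = 2), seed = 11)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$expression$values, co$expression$values)
  expect_equal(back$samples$sample_id, co$samples$sample_id)
  expect_equal(back$clinical$os_months, co$clinical$os_months)
  expect_equal(back$annotation$start, co$annotation$start)
  expect_equal(back$truth$class_a, co$truth$class_a)
})
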