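test_that("builtin genome builds are valid and complete", {
  hg <- load_genome_build("hg19")
  expect_setequal(hg$chromosomes$chrom, c(as.character(1:22), "X"))
  expect_true("13" %in% hg$acrocentric_p_arms)
  expect_setequal(hg$acrocentric_p_arms, c("13", "14", "15", "22"))
  toy <- load_genome_build("toy")
  expect_equal(nrow(toy$chromosomes), 3)
  expect_true(all(toy$chromosomes$centromere_start <
                    toy$chromosomes$centromere_end))
})

test_that("invalid build configs are rejected", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tlength\tcentromere_start\tcentromere_end\tacrocentric",
    "1\t1000\t2000\t3000\tFALSE"), tf)
  expect_error(load_genome_build(tf), "centromere")
  writeLines(c(
    "chrom\tlength\tcentromere_start\tcentromere_end\tacrocentric",
    "1\t-5\t1\t2\tFALSE"), tf)
  expect_error(load_genome_build(tf))
})

test_that("genome build round-trips through its config format", {
  toy <- load_genome_build("toy")
  tf <- tempfile(fileext = ".tsv")
  write_genome_build(toy, tf)
  expect_equal(load_genome_build(tf), toy)
})

test_that("segment reader parses, sorts and validates", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tchrom\tstart\tend\ttotal_cn\tmajor_cn\tminor_cn",
    "S1\t1\t50000001\t100000000\t3\t2\t1",
    "S1\t1\t1\t50000000\t2\t1\t1",
    "S1\t2\t1\t80000000\t2\t1\t1"), tf)
  profs <- read_segments(tf)
  expect_length(profs, 1)
  expect_equal(nrow(profs$S1$segments), 3)
  # out-of-order input comes back sorted, so scores are unaffected
  expect_equal(profs$S1$segments$start[1], 1)
  build <- load_genome_build("toy")
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tchrom\tstart\tend\ttotal_cn\tmajor_cn\tminor_cn",
    "S1\t1\t1\t50000000\t2\t1\t1",
    "S1\t1\t50000001\t100000000\t3\t2\t1",
    "S1\t2\t1\t80000000\t2\t1\t1"), tf2)
  sorted <- read_segments(tf2)
  expect_equal(scar_scores(profs, build), scar_scores(sorted, build))
})

test_that("segment invariant violations name the offender", {
  bad <- data.frame(chrom = "1", start = c(1, 50), end = c(100, 200),
                    total_cn = 2, major_cn = 1, minor_cn = 1)
  expect_error(segment_profile("S9", bad), "S9.*chromosome 1")
  bad2 <- data.frame(chrom = "1", start = 1, end = 100,
                     total_cn = 3, major_cn = 1, minor_cn = 2)
  expect_error(segment_profile("S9", bad2), "major_cn < minor_cn")
  bad3 <- data.frame(chrom = "1", start = 1, end = 100,
                     total_cn = 4, major_cn = 2, minor_cn = 1)
  expect_error(segment_profile("S9", bad3), "total_cn")
})

test_that("segment tables round-trip", {
  sim <- simulate_profile(n_lst_pairs = 1, n_tai_runs = 1, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_segments(sim$profile, tf)
  back <- read_segments(tf)[[1]]
  expect_equal(back$segments, sim$profile$segments)
})

test_that("variant reader validates and counts callers", {
  tf <- tempfile(fileext = ".tsv")
  write_variants(toy_variant_rows(), tf)
  v <- read_variants(tf)
  expect_equal(nrow(v), 5)
  expect_equal(v$n_callers, c(1, 3, 2, 2, 2))
  expect_equal(v[, setdiff(names(v), "n_callers")], toy_variant_rows())

  bad <- toy_variant_rows()
  bad$alt_reads[1] <- 120
  expect_error(validate_variants(bad), "alt_reads > depth at row 1")
  bad <- toy_variant_rows()
  bad$consequence_class[2] <- "missense"
  expect_error(validate_variants(bad), "consequence_class 'missense'")
  bad <- toy_variant_rows()
  bad$callers[3] <- "MuSE;Mystery"
  expect_error(validate_variants(bad), "caller")
})

test_that("empty variant file with header parses to empty table", {
  tf <- tempfile(fileext = ".tsv")
  write_variants(toy_variant_rows()[0, ], tf)
  v <- read_variants(tf)
  expect_equal(nrow(v), 0)
  expect_true("n_callers" %in% names(v))
})

test_that("expression reader enforces shape and uniqueness", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tA\tB\tC",
               "g1\t1\t2\t3", "g2\t4\t5\t6",
               "g3\t7\t8\t9", "g4\t0\t0\t1"), tf)
  m <- read_expression(tf, scale = "counts")
  expect_equal(dim(m$values), c(4, 3))
  writeLines(c("gene\tA\tB", "g1\t1\t2", "g1\t3\t4"), tf)
  expect_error(read_expression(tf), "duplicate gene")
  m2 <- expression_matrix(matrix(1:4, 2, 2,
                                 dimnames = list(c("g1", "g2"),
                                                 c("A", "B"))),
                          scale = "counts")
  expect_error(log2_tpm(m2), "gene_lengths")
})

test_that("expression matrices round-trip", {
  vals <- matrix(round(runif(12), 4), 4, 3,
                 dimnames = list(paste0("g", 1:4), paste0("S", 1:3)))
  m <- expression_matrix(vals, "log2tpm")
  tf <- tempfile(fileext = ".tsv")
  write_expression(m, tf)
  expect_equal(read_expression(tf, "log2tpm")$values, vals)
})

test_that("GMT parsing dedups members and flags malformed lines", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tg1\tg2\tg3",
               "SET2\tdesc\tg4\tg5\tg5"), tf)
  sets <- read_gmt(tf)
  expect_length(sets, 2)
  expect_length(sets$SET1, 3)
  expect_length(sets$SET2, 2) # duplicate member counted once
  writeLines("ONLYNAME\tdesc", tf)
  expect_error(read_gmt(tf), "line 1")
  writeLines(character(0), tf)
  expect_length(read_gmt(tf), 0)
})

test_that("target size is the merged interval union in Mb", {
  tf <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000000", tf)
  expect_equal(read_target_size(tf), 1)
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), tf)
  expect_equal(read_target_size(tf), 150 / 1e6)
  writeLines(c("chr1\t0\t100", "chr1\t100\t200"), tf)
  expect_equal(read_target_size(tf), 200 / 1e6)
  writeLines(c("chr1\t10\t5"), tf)
  expect_error(read_target_size(tf), "end <= start")
})

test_that("target size is invariant under reordering and splitting", {
  tf <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t500", "chr2\t100\t900", "chr1\t600\t800"), tf)
  base <- read_target_size(tf)
  writeLines(c("chr1\t600\t800", "chr2\t100\t500", "chr2\t500\t900",
               "chr1\t0\t250", "chr1\t250\t500"), tf)
  expect_equal(read_target_size(tf), base)
})

test_that("bundled cohort fixture matches the study cohort layout", {
  rec <- read_cohort(cohort_fixture())
  expect_equal(sum(rec$analyzed), 13)
  expect_equal(sum(!rec$analyzed), 5)
  p30 <- rec[rec$sample == "P30", ]
  expect_equal(p30$germline_gene, "BRCA2")
  expect_equal(p30$rcb, "pCR")
  expect_true(p30$er_positive)
  # weak partial ER staining still counts as ER-positive
  expect_true(rec$er_positive[rec$sample == "P16"])
  expect_false(rec$tnbc[rec$sample == "P16"])
})

test_that("cohort reader rejects unknown RCB classes", {
  rec <- utils::read.table(cohort_fixture(), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  rec$rcb[1] <- "RCB-IV"
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(rec, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_cohort(tf), "RCB-IV")
})

test_that("cohort tables round-trip", {
  rec <- read_cohort(cohort_fixture())
  tf <- tempfile(fileext = ".tsv")
  write_cohort(rec, tf)
  expect_equal(read_cohort(tf), rec)
})
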