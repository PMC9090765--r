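# Random segment profiles for oracle-equivalence testing.

# build with tiny chromosomes so the per-base wGII oracle is tractable
mini_build <- function() {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(c(
    "chrom\tlength\tcentromere_start\tcentromere_end\tacrocentric",
    "1\t100000\t45000\t55000\tFALSE",
    "2\t100000\t45000\t55000\tFALSE",
    "3\t100000\t45000\t55000\tTRUE"), tf)
  load_genome_build(tf)
}

# random profile: per chromosome, random breakpoints, random dropped
# intervals (capture gaps), random allele-specific states incl. runs of
# identical neighbors and sub-3Mb fragments
random_profile <- function(build, seed, max_breaks = 8, cn_max = 3) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(build$chromosomes))) {
    chrom <- build$chromosomes$chrom[i]
    len <- build$chromosomes$length[i]
    nb <- sample(0:max_breaks, 1)
    bounds <- sort(unique(c(1, sample.int(len - 1, nb) + 1, len + 1)))
    for (j in seq_len(length(bounds) - 1)) {
      if (runif(1) < 0.15) next # unsegmented gap
      mj <- sample(0:cn_max, 1)
      mn <- sample(0:mj, 1)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = bounds[j], end = bounds[j + 1] - 1,
        total_cn = mj + mn, major_cn = mj, minor_cn = mn,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    rows[[1]] <- data.frame(chrom = build$chromosomes$chrom[1],
                            start = 1, end = 1000, total_cn = 2,
                            major_cn = 1, minor_cn = 1,
                            stringsAsFactors = FALSE)
  }
  segment_profile(paste0("R", seed), do.call(rbind, rows))
}

# split some segments into abutting halves without changing copy number
refine_profile <- function(profile, seed) {
  set.seed(seed)
  seg <- profile$segments
  rows <- list()
  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    if (s$end - s$start >= 2 && runif(1) < 0.5) {
      cut <- sample(seq(s$start, s$end - 1), 1)
      a <- s; a$end <- cut
      b <- s; b$start <- cut + 1
      rows <- c(rows, list(a, b))
    } else {
      rows <- c(rows, list(s))
    }
  }
  segment_profile(profile$sample_id, do.call(rbind, rows))
}

toy_variant_rows <- function() {
  data.frame(
    sample = "T1", chrom = "1",
    pos = c(100, 200, 300, 400, 500),
    ref = c("C", "G", "T", "A", "C"),
    alt = c("A", "T", "C", "G", "T"),
    gene = paste0("G", 1:5),
    consequence_class = c("nonsynonymous", "nonsynonymous", "synonymous",
                          "nonsynonymous", "nonsynonymous"),
    depth = c(100, 19, 80, 50, 30),
    alt_reads = c(20, 8, 40, 2, 15),
    vaf = c(0.2, 0.421, 0.5, 0.04, 0.5),
    callers = c("MuSE", "MuTect;Strelka2;VarScan2", "MuSE;MuTect2",
                "MuSE;Strelka2", "MuTect;SomaticSniper"),
    trinucleotide_context = c("ACA", "AGC", "ATG", "CAG", "GCT"),
    stringsAsFactors = FALSE)
}

cohort_fixture <- function() {
  system.file("extdata", "cohort_clinical.tsv", package = "neoparp")
}
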