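build <- load_genome_build("toy")

mk_prof <- function(...) {
  segment_profile("T", do.call(rbind, lapply(list(...), function(x) {
    data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
               total_cn = x[[4]] + x[[5]], major_cn = x[[4]],
               minor_cn = x[[5]], stringsAsFactors = FALSE)
  })))
}

test_that("median copy number is the length-weighted lower median", {
  p <- mk_prof(list("1", 1, 150e6, 1, 1), list("2", 1, 50e6, 3, 1))
  expect_equal(median_total_cn(p, build), 2) # 150 Mb @2 vs 50 Mb @4
  p <- mk_prof(list("1", 1, 100e6, 2, 1), list("2", 1, 80e6, 2, 1))
  expect_equal(median_total_cn(p, build), 3) # uniform CN 3
  p <- mk_prof(list("1", 1, 100e6, 1, 1), list("2", 1, 100e6, 3, 1))
  expect_equal(median_total_cn(p, build), 2) # even split: lower median
})

test_that("wGII averages per-chromosome deviant fractions", {
  flat <- mk_prof(list("1", 1, 100e6, 1, 1), list("2", 1, 50e6, 1, 1))
  expect_equal(weighted_gii(flat, build), 0)
  p <- mk_prof(list("1", 1, 50e6, 1, 1), list("1", 50e6 + 1, 100e6, 3, 1),
               list("2", 1, 100e6, 1, 1))
  expect_equal(weighted_gii(p, build), 0.25)
})

test_that("LST counts both members of close long pairs", {
  single <- mk_prof(list("1", 1, 50e6, 1, 1))
  expect_equal(lst_score(single, build), 0)
  pair <- mk_prof(list("1", 1, 15e6, 1, 1),
                  list("1", 15e6 + 1, 30e6, 2, 1))
  expect_equal(lst_score(pair, build), 2)
  gapped <- mk_prof(list("1", 1, 15e6, 1, 1),
                    list("1", 19e6 + 1, 34e6, 2, 1)) # 4 Mb gap
  expect_equal(lst_score(gapped, build), 0)
  at_gap <- mk_prof(list("1", 1, 15e6, 1, 1),
                    list("1", 18e6 + 1, 33e6, 2, 1)) # exactly 3 Mb
  expect_equal(lst_score(at_gap, build), 2)
})

test_that("LST short-segment dropping follows merge-drop-remerge", {
  # two 15 Mb segments with the same profile separated by a 2 Mb
  # different fragment: the fragment is dropped, the halves re-merge,
  # and no transition remains
  p <- mk_prof(list("1", 1, 15e6, 1, 1),
               list("1", 15e6 + 1, 17e6, 2, 1),
               list("1", 17e6 + 1, 32e6, 1, 1))
  expect_equal(lst_score(p, build), 0)
  # same geometry but the outer profiles differ: dropping the fragment
  # leaves two long segments 2 Mb apart, a qualifying pair
  p2 <- mk_prof(list("1", 1, 15e6, 1, 1),
                list("1", 15e6 + 1, 17e6, 2, 1),
                list("1", 17e6 + 1, 32e6, 2, 2))
  expect_equal(lst_score(p2, build), 2)
})

test_that("TAI counts imbalanced terminal runs stopping short of the centromere", {
  balanced <- mk_prof(list("1", 1, 200e6, 2, 2))
  expect_equal(tai_score(balanced, build), 0)
  # q-terminal imbalanced run on a 200 Mb chromosome (centromere 90-100)
  p <- mk_prof(list("1", 1, 90e6 - 1, 1, 1),
               list("1", 100e6 + 1, 150e6, 1, 1),
               list("1", 150e6 + 1, 200e6, 2, 1))
  expect_equal(tai_score(p, build), 1)
  # acrocentric p-arm (toy chromosome 3) is ignored
  p3 <- mk_prof(list("3", 1, 50e6, 2, 1),
                list("3", 50e6 + 1, 200e6, 1, 1))
  expect_equal(tai_score(p3, build), 0)
  p1 <- mk_prof(list("1", 1, 50e6, 2, 1),
                list("1", 50e6 + 1, 200e6, 1, 1))
  expect_equal(tai_score(p1, build), 1)
  # imbalance reaching the centromere does not count
  pc <- mk_prof(list("1", 1, 95e6, 2, 1),
                list("1", 95e6 + 1, 200e6, 1, 1))
  expect_equal(tai_score(pc, build), 0)
})

test_that("scores match the naive oracles on random profiles", {
  for (seed in 1:50) {
    p <- random_profile(build, seed)
    expect_equal(lst_score(p, build), lst_naive(p, build),
                 info = paste("seed", seed))
    expect_equal(tai_score(p, build), tai_naive(p, build),
                 info = paste("seed", seed))
  }
  mb <- mini_build()
  for (seed in 1:50) {
    p <- random_profile(mb, seed + 1000)
    expect_equal(weighted_gii(p, mb), wgii_naive(p, mb, unit = 1),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("refining segments leaves all three scores unchanged", {
  for (seed in 1:20) {
    p <- random_profile(build, seed)
    q <- refine_profile(p, seed + 500)
    expect_equal(scar_scores(p, build), scar_scores(q, build))
  }
})

test_that("planting one more event moves the score by its known step", {
  for (k in 0:2) {
    a <- simulate_profile(build, n_lst_pairs = k, n_tai_runs = k,
                          seed = 11)
    b <- simulate_profile(build, n_lst_pairs = k + 1, n_tai_runs = k,
                          seed = 11)
    d <- simulate_profile(build, n_lst_pairs = k, n_tai_runs = k + 1,
                          seed = 11)
    expect_equal(lst_score(b$profile, build),
                 lst_score(a$profile, build) + 2)
    expect_equal(tai_score(d$profile, build),
                 tai_score(a$profile, build) + 1)
  }
})

test_that("scores are independent of segment input order", {
  p <- random_profile(build, 42)
  seg <- p$segments
  set.seed(99)
  shuffled <- segment_profile(p$sample_id,
                              seg[sample.int(nrow(seg)), ])
  expect_equal(scar_scores(p, build), scar_scores(shuffled, build))
})

test_that("per-arm LST mode splits chromosomes at the centromere", {
  # two long different segments, the second straddling the centromere:
  # a pair per chromosome, but none per arm
  p <- mk_prof(list("1", 1, 88e6, 1, 1),
               list("1", 89e6 + 1, 110e6, 2, 1))
  expect_equal(lst_score(p, build), 2)
  expect_equal(lst_score(p, build, per_arm = TRUE), 0)
})
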