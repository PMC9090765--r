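mk_ranked <- function(genes, stats) {
  out <- data.frame(gene = genes, statistic = stats,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  out
}
hand_ranked <- mk_ranked(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))

test_that("log2 TPM follows the closed-form arithmetic", {
  vals <- matrix(c(10, 90), 2, 1,
                 dimnames = list(c("g1", "g2"), "S1"))
  m <- expression_matrix(vals, "counts",
                         gene_lengths = c(g1 = 1000, g2 = 1000))
  out <- log2_tpm(m)
  expect_equal(out$scale, "log2tpm")
  expect_equal(unname(out$values[, 1]),
               log2(c(1e5, 9e5) + 1), tolerance = 1e-12)
  expect_equal(unname(out$values[, 1]), c(16.610, 19.779),
               tolerance = 1e-4)
})

test_that("TPM is scale-invariant and zero counts map to zero", {
  vals <- matrix(c(10, 90, 0, 20, 180, 0), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("A", "B")))
  lens <- c(g1 = 500, g2 = 2000, g3 = 1000)
  out <- log2_tpm(expression_matrix(vals, "counts", lens))
  expect_equal(out$values[, "A"], out$values[, "B"]) # B = 2x A counts
  expect_equal(unname(out$values["g3", ]), c(0, 0))
  zero <- expression_matrix(matrix(0, 1, 1,
                                   dimnames = list("g1", "S")),
                            "counts", c(g1 = 1000))
  expect_error(log2_tpm(zero), "zero total rate")
})

test_that("gene ranking is a deterministic Welch t ordering", {
  set.seed(31)
  n <- 100
  vals <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(sprintf("g%03d", 1:n),
                                 sprintf("S%02d", 1:10)))
  labels <- stats::setNames(rep(c("SENSITIVE", "RESISTANT"), each = 5),
                            colnames(vals))
  vals["g001", labels == "SENSITIVE"] <-
    vals["g001", labels == "SENSITIVE"] + 5
  m <- expression_matrix(vals, "log2tpm")
  ranked <- rank_genes(m, labels)
  expect_equal(ranked$gene[1], "g001") # 5 SD planted gene ranks first
  # cross-check a single statistic against stats::t.test
  g <- "g050"
  tt <- t.test(vals[g, labels == "SENSITIVE"],
               vals[g, labels == "RESISTANT"], var.equal = FALSE)
  expect_equal(ranked$statistic[ranked$gene == g],
               unname(tt$statistic), tolerance = 1e-12)
  # label swap negates every statistic and reverses the order
  flipped <- rank_genes(m, stats::setNames(
    ifelse(labels == "SENSITIVE", "RESISTANT", "SENSITIVE"),
    names(labels)))
  expect_equal(flipped$statistic,
               rev(-ranked$statistic))
  # constant gene gets statistic zero
  vals2 <- rbind(vals, gzzz = 1)
  ranked2 <- rank_genes(expression_matrix(vals2, "log2tpm"), labels)
  expect_equal(ranked2$statistic[ranked2$gene == "gzzz"], 0)
})

test_that("the enrichment score matches hand evaluation", {
  res <- gsea_preranked(hand_ranked, list(S = c("g1", "g4")),
                        n_perm = 200, seed = 1, min_size = 1)
  expect_equal(res$es, 0.75)
  expect_equal(leading_edge(res), "g1")
  # negative mirror: set at the bottom of the ranking
  res2 <- gsea_preranked(hand_ranked, list(S = c("g5", "g6")),
                         n_perm = 200, seed = 1, min_size = 1)
  expect_equal(res2$es, -1)
  expect_equal(leading_edge(res2), c("g5", "g6"))
  # degenerate set covering the whole ranking
  res3 <- gsea_preranked(hand_ranked, list(ALL = paste0("g", 1:6)),
                         n_perm = 100, seed = 1, min_size = 1)
  expect_equal(res3$es, 1)
})

test_that("enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  n <- 400
  genes <- sprintf("g%04d", 1:n)
  stats_vec <- sort(rnorm(n), decreasing = TRUE)
  ranked <- mk_ranked(genes, stats_vec)
  for (i in 1:20) {
    m <- sample(5:60, 1)
    members <- sample(genes, m)
    ours <- gsea_preranked(ranked, list(S = members), n_perm = 100,
                           seed = i)
    ref <- fgsea::calcGseaStat(
      stats::setNames(stats_vec, genes),
      sort(match(members, genes)), gseaParam = 1)
    expect_equal(ours$es, ref, tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("unweighted ES is invariant under monotone statistic transforms", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:50)
  stats_vec <- sort(rnorm(50), decreasing = TRUE)
  members <- sample(genes, 12)
  r1 <- mk_ranked(genes, stats_vec)
  r2 <- mk_ranked(genes, sort(10 + tanh(stats_vec), decreasing = TRUE))
  e1 <- gsea_preranked(r1, list(S = members), n_perm = 100, seed = 2,
                       weight_exponent = 0)
  e2 <- gsea_preranked(r2, list(S = members), n_perm = 100, seed = 2,
                       weight_exponent = 0)
  expect_equal(e1$es, e2$es)
  # reversing the ranking flips the ES sign (weight exponent 0)
  r3 <- mk_ranked(rev(genes), rev(-stats_vec))
  e3 <- gsea_preranked(r3, list(S = members), n_perm = 100, seed = 2,
                       weight_exponent = 0)
  expect_equal(e3$es, -e1$es)
})

test_that("fixed seeds give bit-identical GSEA results", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:200)
  ranked <- mk_ranked(genes, sort(rnorm(200), decreasing = TRUE))
  sets <- list(A = sample(genes, 20), B = sample(genes, 30))
  r1 <- gsea_preranked(ranked, sets, n_perm = 300, seed = 7)
  r2 <- gsea_preranked(ranked, sets, n_perm = 300, seed = 7)
  expect_identical(r1, r2)
})

test_that("leading edges are always inside the set", {
  set.seed(40)
  genes <- sprintf("g%03d", 1:150)
  for (i in 1:30) {
    ranked <- mk_ranked(genes, sort(rnorm(150), decreasing = TRUE))
    members <- sample(genes, sample(5:40, 1))
    res <- gsea_preranked(ranked, list(S = members), n_perm = 100,
                          seed = i)
    le <- leading_edge(res)
    expect_true(all(le %in% members))
    expect_gte(length(le), 1)
  }
})

test_that("BH adjustment matches the hand-worked step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)),
               c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.07, 5)), rep(0.07, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), 1:50) # monotone in the input
})

test_that("over-representation uses the exact hypergeometric tail", {
  sets <- list(S = paste0("g", 1:5))
  res <- overrepresentation_test(paste0("g", 1:5), sets,
                                 background = paste0("g", 1:10))
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  disj <- overrepresentation_test(paste0("g", 6:10), sets,
                                  background = paste0("g", 1:10))
  expect_equal(disj$p, 1)
  # growing the background never weakens a fixed overlap
  p_small <- overrepresentation_test(paste0("g", 1:5), sets, 20)$p
  p_big <- overrepresentation_test(paste0("g", 1:5), sets, 200)$p
  expect_lte(p_big, p_small)
  expect_error(overrepresentation_test(paste0("g", 1:5), sets, 3),
               "smaller than query")
})

test_that("signature scores are cohort-centered mean z-scores", {
  vals <- matrix(5, 10, 4, dimnames = list(sprintf("g%02d", 1:10),
                                           paste0("S", 1:4)))
  m <- expression_matrix(vals, "log2tpm")
  expect_equal(unname(signature_score(m, rownames(vals))), rep(0, 4))
  set.seed(8)
  vals2 <- matrix(rnorm(10 * 6), 10, 6,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  paste0("S", 1:6)))
  vals2[, 1] <- vals2[, 1] + 2 # one sample high on every set gene
  m2 <- expression_matrix(vals2, "log2tpm")
  sc <- signature_score(m2, rownames(vals2))
  expect_equal(names(which.max(sc)), "S1")
  # z-scoring centers each gene across the cohort, so scores sum to 0
  expect_lt(abs(sum(sc)), 1e-9)
  expect_error(signature_score(m2, "absent"), "intersect")
})
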