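#' Convert raw counts to log2(TPM + 1)
#'
#' Per sample: the count of each gene is divided by its length in
#' kilobases, the resulting rates are scaled to sum to one million
#' (transcripts per million), and values are returned as log2(TPM + 1).
#' Doubling all counts in a sample leaves its TPM vector unchanged.
#'
#' @param mat an [expression_matrix()] with `scale = "counts"` and
#'   `gene_lengths`
#' @return an `expression_matrix` with `scale = "log2tpm"`
#' @export
log2_tpm <- function(mat) {
  if (mat$scale != "counts") stop("input scale must be counts")
  if (is.null(mat$gene_lengths)) {
    stop("gene_lengths required to compute TPM from counts")
  }
  kb <- mat$gene_lengths[rownames(mat$values)] / 1000
  rate <- mat$values / kb
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("zero total rate in sample ",
         colnames(mat$values)[which(totals == 0)[1]])
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  expression_matrix(log2(tpm + 1), scale = "log2tpm",
                    gene_lengths = mat$gene_lengths)
}

#' Rank genes by differential expression between response groups
#'
#' Computes a per-gene Welch t statistic on log2 expression, oriented as
#' SENSITIVE minus RESISTANT (positive = higher in sensitive tumors),
#' and returns the genes sorted by decreasing statistic with ties broken
#' by gene id, so the ranking is fully deterministic. A gene with zero
#' variance in both groups gets statistic 0 (no evidence either way)
#' rather than an error; this matters for planted constant genes in
#' simulations.
#'
#' @param mat an `expression_matrix` at log2tpm scale
#' @param groups named character vector (`"SENSITIVE"`/`"RESISTANT"`)
#'   per sample, or a factor-like vector aligned with the matrix columns
#' @return a `ranked_genes` data.frame: `gene`, `statistic`, sorted
#'   descending
#' @export
rank_genes <- function(mat, groups) {
  x <- mat$values
  if (!is.null(names(groups))) groups <- groups[colnames(x)]
  if (anyNA(groups)) stop("group label missing for some samples")
  a <- x[, groups == "SENSITIVE", drop = FALSE]
  b <- x[, groups == "RESISTANT", drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop("need at least 2 samples per response group")
  }
  stat <- welch_t(a, b)
  ord <- order(-stat, rownames(x), method = "radix")
  out <- data.frame(gene = rownames(x)[ord], statistic = stat[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# row-wise Welch t statistic, a minus b; 0 when both variances are 0
welch_t <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  ifelse(se2 == 0, 0, (ma - mb) / sqrt(se2))
}

#' Preranked gene-set enrichment analysis
#'
#' The classic weighted Kolmogorov-Smirnov statistic on a ranked gene
#' list: walking down the ranking, the running sum rises by
#' `|statistic|^weight_exponent` (normalized by the in-set total) at
#' each set member and falls by `1/(N - |S|)` otherwise; the enrichment
#' score ES is the running-sum value of maximal absolute deviation.
#' Significance comes from `n_perm` random gene-label permutations
#' (equivalently, random re-draws of the set positions): the normalized
#' score NES is ES divided by the mean |null ES| of matching sign, and
#' the nominal p-value is the matching-sign null tail frequency with +1
#' smoothing. Benjamini-Hochberg adjustment is applied across all scored
#' sets. Sets smaller than `min_size` after intersection with the
#' ranking are skipped with a message.
#'
#' @param ranked a [rank_genes()] result
#' @param sets a [read_gmt()] collection (or named list of gene vectors)
#' @param n_perm number of permutations for the null
#' @param seed integer seed for the permutation null
#' @param weight_exponent exponent on |statistic| for hit increments
#'   (0 = unweighted KS, 1 = classic weighted GSEA)
#' @param min_size minimum in-ranking set size
#' @return data.frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p_nominal`, `p_adjusted`, `leading_edge`
#'   (semicolon-joined genes)
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_size = 5) {
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  stat <- ranked$statistic
  genes <- ranked$gene
  n <- length(genes)
  rows <- list()
  set_rng(seed)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    m <- length(members)
    if (m < min_size) {
      message("gsea_preranked: skipping '", nm, "' (", m,
              " genes in ranking < ", min_size, ")")
      next
    }
    pos <- sort(match(members, genes))
    if (m == n) {
      # degenerate set covering the whole ranking: the running sum is
      # monotone to 1 and the permutation null is a point mass
      rows[[nm]] <- data.frame(
        set = nm, size = m, es = 1, nes = NA_real_, p_nominal = 1,
        leading_edge = paste(genes, collapse = ";"),
        stringsAsFactors = FALSE)
      next
    }
    obs <- es_from_positions(pos, stat, n, weight_exponent)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(n, m)), stat, n,
                        weight_exponent)$es
    }, numeric(1))
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else
      null_es[null_es < 0]
    p_nom <- (1 + sum(abs(same_sign) >= abs(obs$es))) /
      (1 + length(same_sign))
    nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
      obs$es / mean(abs(same_sign))
    } else {
      NA_real_
    }
    le <- if (obs$es >= 0) {
      genes[pos[pos <= obs$peak]]
    } else {
      genes[pos[pos >= obs$peak]]
    }
    rows[[nm]] <- data.frame(
      set = nm, size = m, es = obs$es, nes = nes, p_nominal = p_nom,
      leading_edge = paste(le, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(set = character(), size = integer(),
                      es = numeric(), nes = numeric(),
                      p_nominal = numeric(), p_adjusted = numeric(),
                      leading_edge = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- benjamini_hochberg(out$p_nominal)
  out[, c("set", "size", "es", "nes", "p_nominal", "p_adjusted",
          "leading_edge")]
}

# Enrichment score from sorted hit positions. The running sum is
# piecewise linear and decreasing between hits, so its extrema occur at
# hit positions (local maxima) and just before hits (local minima);
# only those candidates are evaluated, making the null loop O(m) per
# permutation instead of O(N). Returns the signed ES and the ranking
# position of the peak (for positive ES) or trough (negative ES).
es_from_positions <- function(pos, stat, n, weight_exponent = 1) {
  m <- length(pos)
  w <- abs(stat[pos])^weight_exponent
  nr <- sum(w)
  hit_cum <- if (nr > 0) cumsum(w) / nr else seq_len(m) / m
  miss_step <- 1 / (n - m)
  idx <- seq_len(m)
  top <- hit_cum - (pos - idx) * miss_step            # just after hit i
  bottom <- c(0, hit_cum[-m]) - (pos - idx) * miss_step # just before hit i
  hi <- max(top)
  lo <- min(bottom)
  if (hi >= -lo) { # ties between +/- resolve to the positive side
    i <- which.max(top)
    list(es = hi, peak = pos[i])
  } else {
    i <- which.min(bottom)
    list(es = lo, peak = pos[i])
  }
}

#' Leading-edge genes of an enrichment result
#'
#' The set members that drive the enrichment score: for a positive ES,
#' the in-set genes at or before the running-sum peak (the genes with
#' the largest expression change in the enriched direction); for a
#' negative ES, the in-set genes at or after the trough.
#'
#' @param result one row of a [gsea_preranked()] result (or the full
#'   data.frame plus `set` naming the row)
#' @param set optional set name when `result` has several rows
#' @return character vector of leading-edge genes
#' @export
leading_edge <- function(result, set = NULL) {
  if (!is.null(set)) result <- result[result$set == set, , drop = FALSE]
  if (nrow(result) != 1) stop("expected exactly one enrichment row")
  le <- result$leading_edge
  if (!nzchar(le)) character(0) else strsplit(le, ";", fixed = TRUE)[[1]]
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1), with input validation.
#'
#' @param p_values numeric vector in [0, 1]
#' @return adjusted p-values
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation (hypergeometric) test
#'
#' One-sided hypergeometric tail probability of observing at least the
#' seen overlap between a query gene list and each set, given a
#' background universe, with Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of genes (a leading edge, typically)
#' @param sets named list of gene sets
#' @param background character vector of background genes (must contain
#'   the query) or an integer background size
#' @return data.frame `set`, `overlap`, `set_size`, `p`, `fdr`
#' @export
overrepresentation_test <- function(query, sets, background) {
  if (is.character(background)) {
    if (!all(query %in% background)) {
      stop("query genes missing from background")
    }
    bg_n <- length(unique(background))
    sets <- lapply(sets, intersect, background)
  } else {
    bg_n <- as.integer(background)
  }
  query <- unique(query)
  q_n <- length(query)
  if (bg_n < q_n) stop("background smaller than query")
  rows <- lapply(names(sets), function(nm) {
    s_n <- length(unique(sets[[nm]]))
    k <- length(intersect(query, sets[[nm]]))
    p <- stats::phyper(k - 1, s_n, bg_n - s_n, q_n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = s_n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out
}

#' Per-sample gene-set signature score
#'
#' Mean of row-wise z-scored expression over the genes of a set: each
#' gene is centered and scaled across the cohort (zero-variance genes
#' contribute 0), then averaged within each sample. Positive scores mean
#' the sample expresses the set above the cohort average. This is the
#' scoring used for the hypoxia and EMT/stem-cell signature calls.
#'
#' @param mat an `expression_matrix` at log2tpm scale
#' @param set character vector of gene ids
#' @return named numeric vector of per-sample scores
#' @export
signature_score <- function(mat, set) {
  x <- mat$values[rownames(mat$values) %in% set, , drop = FALSE]
  if (nrow(x) == 0) stop("gene set does not intersect the matrix")
  if (ncol(x) < 2) stop("need at least 2 samples to z-score")
  mu <- rowMeans(x)
  sdev <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdev == 0, 1, sdev)
  z[sdev == 0, ] <- 0
  colMeans(z)
}
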