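#' Brute-force reference implementations of the scar scores
#'
#' Deliberately naive re-implementations used to cross-check the scoring
#' functions and to attach ground truth to simulated profiles:
#' `wgii_naive` expands the profile position by position and counts
#' deviations from the expanded (lower) median; `lst_naive` enumerates
#' every segment pair per chromosome after an explicit merge/drop/merge
#' loop; `tai_naive` walks inwards from each chromosome end one segment
#' at a time. They share no code with [weighted_gii()], [lst_score()] or
#' [tai_score()].
#'
#' @param profile a [segment_profile()]
#' @param build a genome build
#' @param unit expansion unit in bp for `wgii_naive`; every segment
#'   boundary must align to it (start on `unit * k + 1`, end on
#'   `unit * k`), so `unit = 1` is always valid but only tractable on
#'   small builds.
#' @return the score, as computed by brute force
#' @keywords internal
#' @export
wgii_naive <- function(profile, build = load_genome_build("toy"),
                       unit = 1) {
  seg <- autosomal_segments(profile, build)
  if (any((seg$start - 1) %% unit != 0 | seg$end %% unit != 0)) {
    stop("segment boundaries not aligned to unit ", unit)
  }
  expand <- function(s) {
    rep(s$total_cn, times = (s$end - s$start + 1) / unit)
  }
  all_cn <- sort(expand(seg))
  med <- all_cn[floor((length(all_cn) + 1) / 2)]
  fracs <- c()
  for (chr in unique(seg$chrom)) {
    cn <- expand(seg[seg$chrom == chr, , drop = FALSE])
    fracs <- c(fracs, mean(cn != med))
  }
  mean(fracs)
}

#' @rdname wgii_naive
#' @param min_segment,max_gap,min_keep as in [lst_score()]
#' @export
lst_naive <- function(profile, build = load_genome_build("toy"),
                      min_segment = 10e6, max_gap = 3e6, min_keep = 3e6) {
  seg <- autosomal_segments(profile, build)
  total <- 0
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    s <- naive_merge(s)
    s <- s[(s$end - s$start + 1) >= min_keep, , drop = FALSE]
    s <- naive_merge(s)
    n <- nrow(s)
    if (n < 2) next
    counts <- rep(FALSE, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        len_i <- s$end[i] - s$start[i] + 1
        len_j <- s$end[j] - s$start[j] + 1
        gap <- max(s$start[j], s$start[i]) - min(s$end[i], s$end[j]) - 1
        same <- s$major_cn[i] == s$major_cn[j] &&
          s$minor_cn[i] == s$minor_cn[j]
        if (len_i >= min_segment && len_j >= min_segment &&
            !same && gap <= max_gap) {
          counts[i] <- TRUE
        }
      }
    }
    total <- total + sum(counts)
  }
  total
}

# repeated pairwise merge until no two adjacent segments share a profile
naive_merge <- function(s) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(s)) {
      if (s$major_cn[i] == s$major_cn[i + 1] &&
          s$minor_cn[i] == s$minor_cn[i + 1]) {
        s$end[i] <- s$end[i + 1]
        s <- s[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged) break
  }
  s
}

#' @rdname wgii_naive
#' @export
tai_naive <- function(profile, build = load_genome_build("toy")) {
  seg <- autosomal_segments(profile, build)
  total <- 0
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cen_start <- build$chromosomes$centromere_start[
      build$chromosomes$chrom == chr]
    cen_end <- build$chromosomes$centromere_end[
      build$chromosomes$chrom == chr]
    n <- nrow(s)
    # p end
    if (!(chr %in% build$acrocentric_p_arms)) {
      i <- 1
      while (i <= n && s$major_cn[i] != s$minor_cn[i]) i <- i + 1
      if (i > 1 && s$end[i - 1] < cen_start) total <- total + 1
    }
    # q end
    i <- n
    while (i >= 1 && s$major_cn[i] != s$minor_cn[i]) i <- i - 1
    if (i < n && s$start[i + 1] > cen_end) total <- total + 1
  }
  total
}
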