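#' Length-weighted median total copy number
#'
#' The reference level against which gains and losses are defined for the
#' weighted genome instability index: the median of `total_cn` over the
#' autosomal segments of a profile, weighting each segment by its length
#' (equivalent to expanding the profile per base). When the weight splits
#' exactly in half, the lower median is returned, so the result is always
#' an observed copy-number state.
#'
#' @param profile a [segment_profile()]
#' @param build a [load_genome_build()] result (identifies autosomes)
#' @return the length-weighted (lower) median total copy number
#' @export
median_total_cn <- function(profile, build = load_genome_build("toy")) {
  seg <- autosomal_segments(profile, build)
  if (nrow(seg) == 0) {
    stop("sample ", profile$sample_id, ": no autosomal segments")
  }
  ord <- order(seg$total_cn)
  cn <- seg$total_cn[ord]
  len <- segment_length(seg)[ord]
  half <- sum(len) / 2
  cn[which(cumsum(len) >= half)[1]]
}

autosomal_segments <- function(profile, build) {
  profile$segments[profile$segments$chrom %in% build_autosomes(build), ,
                   drop = FALSE]
}

#' Weighted genome instability index
#'
#' Fraction of the genome whose total copy number deviates from the
#' sample's median copy number, computed separately per autosome and then
#' averaged without weighting, so a long chromosome does not dominate the
#' score. The per-chromosome denominator is the segmented length of that
#' chromosome (capture data leaves unsegmented gaps which carry no
#' copy-number evidence).
#'
#' @inheritParams median_total_cn
#' @return wGII in [0, 1]
#' @examples
#' build <- load_genome_build("toy")
#' prof <- segment_profile("S1", data.frame(
#'   chrom = c("1", "1", "2"),
#'   start = c(1, 50e6 + 1, 1), end = c(50e6, 100e6, 100e6),
#'   total_cn = c(2, 4, 2), major_cn = c(1, 3, 1), minor_cn = c(1, 1, 1)))
#' weighted_gii(prof, build) # (0.5 + 0) / 2 = 0.25
#' @export
weighted_gii <- function(profile, build = load_genome_build("toy")) {
  seg <- autosomal_segments(profile, build)
  if (nrow(seg) == 0) {
    stop("sample ", profile$sample_id, ": no autosomal segments")
  }
  med <- median_total_cn(profile, build)
  len <- segment_length(seg)
  frac <- vapply(unique(seg$chrom), function(chr) {
    on <- seg$chrom == chr
    sum(len[on & seg$total_cn != med]) / sum(len[on])
  }, numeric(1))
  mean(frac)
}

#' Large-scale state transition (LST) score
#'
#' Counts, summed over autosomes, the segments at least `min_segment`
#' long that lie within `max_gap` of a neighboring segment also at least
#' `min_segment` long but with a different allele-specific copy-number
#' profile (a differing (major, minor) pair). Before counting, adjacent
#' segments with identical profiles are merged, segments shorter than
#' `min_keep` are dropped entirely (rather than smoothed into their
#' neighbors), and identical neighbors are re-merged. Both members of a
#' qualifying pair count, so one isolated transition contributes 2; a
#' segment with qualifying neighbors on both sides still counts once.
#'
#' By default the score is computed per chromosome; `per_arm = TRUE`
#' splits each chromosome at the centromere first, the convention of the
#' original array-based protocol. `drop_before_merge = TRUE` drops
#' sub-`min_keep` segments before the first merge instead of after it.
#'
#' @inheritParams median_total_cn
#' @param min_segment minimum qualifying segment length (bp)
#' @param max_gap maximum gap between qualifying neighbors (bp)
#' @param min_keep segments shorter than this are dropped (bp)
#' @param per_arm compute on chromosome arms instead of chromosomes
#' @param drop_before_merge drop short segments before the first merge
#' @return nonnegative integer LST count
#' @export
lst_score <- function(profile, build = load_genome_build("toy"),
                      min_segment = 10e6, max_gap = 3e6, min_keep = 3e6,
                      per_arm = FALSE, drop_before_merge = FALSE) {
  seg <- autosomal_segments(profile, build)
  total <- 0L
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    if (per_arm) {
      cen <- build$chromosomes[build$chromosomes$chrom == chr, ]
      parts <- list(s[s$end < cen$centromere_start, , drop = FALSE],
                    s[s$start > cen$centromere_end, , drop = FALSE])
    } else {
      parts <- list(s)
    }
    for (p in parts) {
      total <- total + lst_count_one(p, min_segment, max_gap, min_keep,
                                     drop_before_merge)
    }
  }
  total
}

lst_count_one <- function(s, min_segment, max_gap, min_keep,
                          drop_before_merge) {
  if (drop_before_merge) {
    s <- s[segment_length(s) >= min_keep, , drop = FALSE]
  }
  s <- merge_identical_neighbors(s)
  s <- s[segment_length(s) >= min_keep, , drop = FALSE]
  s <- merge_identical_neighbors(s)
  n <- nrow(s)
  if (n < 2) return(0L)
  len <- segment_length(s)
  long <- len >= min_segment
  counted <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      gap <- s$start[j] - s$end[i] - 1
      if (gap > max_gap) break # sorted: later j only further away
      differs <- s$major_cn[i] != s$major_cn[j] ||
        s$minor_cn[i] != s$minor_cn[j]
      if (long[i] && long[j] && differs) {
        counted[i] <- TRUE
        counted[j] <- TRUE
      }
    }
  }
  sum(counted)
}

# Merge runs of consecutive segments with identical (major, minor),
# absorbing any gap between them.
merge_identical_neighbors <- function(s) {
  n <- nrow(s)
  if (n < 2) return(s)
  new_run <- c(TRUE, s$major_cn[-1] != s$major_cn[-n] |
                 s$minor_cn[-1] != s$minor_cn[-n])
  run <- cumsum(new_run)
  out <- s[new_run, , drop = FALSE]
  out$end <- vapply(split(s$end, run), max, numeric(1))
  rownames(out) <- NULL
  out
}

#' Telomeric allelic imbalance (TAI) score
#'
#' Counts chromosome ends whose terminal run of segments is allele
#' imbalanced (`major_cn != minor_cn`) without the imbalance extending to
#' the centromere: for each autosome, the maximal run of consecutive
#' imbalanced segments anchored at the p- and at the q-terminal segment
#' scores 1 if it is non-empty and stops short of the centromere
#' (p-run end before `centromere_start`; q-run start after
#' `centromere_end`). A run reaching or crossing the centromere scores
#' nothing. P-termini of acrocentric chromosomes (13, 14, 15 and 22 in
#' the human builds) are skipped, since exome capture gives no
#' copy-number estimates there. The outermost segment of a profile is
#' treated as reaching the telomere: capture segmentation never extends
#' to the literal chromosome ends, so requiring that would make the score
#' identically zero on exome data. There is no minimum run length.
#'
#' @inheritParams median_total_cn
#' @return nonnegative integer TAI count
#' @export
tai_score <- function(profile, build = load_genome_build("toy")) {
  seg <- autosomal_segments(profile, build)
  total <- 0L
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    cen <- build$chromosomes[build$chromosomes$chrom == chr, ]
    imbalanced <- s$major_cn != s$minor_cn
    n <- nrow(s)
    if (!(chr %in% build$acrocentric_p_arms)) {
      run_len <- match(FALSE, imbalanced, nomatch = n + 1) - 1
      if (run_len > 0 && s$end[run_len] < cen$centromere_start) {
        total <- total + 1L
      }
    }
    run_len <- match(FALSE, rev(imbalanced), nomatch = n + 1) - 1
    if (run_len > 0 && s$start[n - run_len + 1] > cen$centromere_end) {
      total <- total + 1L
    }
  }
  total
}

#' Scar scores for a set of profiles
#'
#' Convenience wrapper computing the three copy-number scar statistics
#' plus the median copy number for each sample.
#'
#' @param profiles named list of [segment_profile()]s (or one profile)
#' @param build genome build
#' @param ... passed to [lst_score()]
#' @return data.frame with columns `sample, wgii, lst, tai,
#'   median_total_cn`
#' @export
scar_scores <- function(profiles, build = load_genome_build("toy"), ...) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sample = p$sample_id,
               wgii = weighted_gii(p, build),
               lst = lst_score(p, build, ...),
               tai = tai_score(p, build),
               median_total_cn = median_total_cn(p, build),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
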