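#' Dichotomize residual cancer burden into response groups
#'
#' The primary endpoint dichotomy: pCR and RCB-I are SENSITIVE, RCB-II
#' and RCB-III are RESISTANT. The alternative `pcr_only` mode compares
#' pathologic complete response against everything else.
#'
#' @param rcb character vector of RCB classes (`pCR`, `RCB-I`, `RCB-II`,
#'   `RCB-III`)
#' @param pcr_only if TRUE, only pCR counts as SENSITIVE
#' @return character vector of `"SENSITIVE"` / `"RESISTANT"`
#' @export
dichotomize_response <- function(rcb, pcr_only = FALSE) {
  if (!all(rcb %in% rcb_classes)) {
    stop("unknown RCB class: ",
         paste(setdiff(rcb, rcb_classes), collapse = ", "))
  }
  sensitive <- if (pcr_only) "pCR" else c("pCR", "RCB-I")
  ifelse(rcb %in% sensitive, "SENSITIVE", "RESISTANT")
}

#' Two-group comparison by pooled-variance t test
#'
#' Unpaired two-sided Student's t test (pooled variance, n1 + n2 - 2
#' degrees of freedom) of a per-sample quantity between response
#' groups, with the fold change between group means reported on the
#' linear scale in both directions (so a sensitive/resistant ratio of
#' 2.2 reads "2.2x lower in resistant tumors").
#'
#' @param values named numeric vector of per-sample values
#' @param labels `"SENSITIVE"`/`"RESISTANT"` per sample (aligned or
#'   named)
#' @return list with `t_statistic`, `p_value`, `df`, `group_means`,
#'   `fold_change_sens_over_res`, `fold_change_res_over_sens`,
#'   `degenerate` (TRUE when the pooled variance is zero, in which case
#'   the p-value is NA)
#' @export
group_compare <- function(values, labels) {
  if (!is.null(names(values)) && !is.null(names(labels))) {
    labels <- labels[names(values)]
  }
  a <- values[labels == "SENSITIVE"]
  b <- values[labels == "RESISTANT"]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 samples per group")
  }
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  means <- c(SENSITIVE = mean(a), RESISTANT = mean(b))
  if (sp2 == 0) {
    tt <- if (means[1] == means[2]) 0 else NA_real_
    p <- if (means[1] == means[2]) 1 else NA_real_
    degenerate <- means[1] != means[2]
  } else {
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), df)
    degenerate <- FALSE
  }
  list(t_statistic = unname(tt), p_value = unname(p), df = df,
       group_means = means,
       fold_change_sens_over_res = unname(means[1] / means[2]),
       fold_change_res_over_sens = unname(means[2] / means[1]),
       degenerate = degenerate)
}

#' Shieldin (SHLD2) loss call
#'
#' TRUE only for concomitant loss of copy number and expression: the
#' segment overlapping the SHLD2 locus must have total copy number below
#' the sample's median copy number AND the sample's SHLD2 expression
#' z-score (across the cohort) must fall below `z_cutoff`. Either signal
#' alone is not called a loss. When no segment covers the locus the call
#' is NA (unknown) and downstream consumers exclude the sample with a
#' message.
#'
#' @param profile a [segment_profile()] for the sample (or NULL if
#'   unavailable)
#' @param locus list with `chrom`, `start`, `end` of the SHLD2 locus
#' @param expression_z the sample's SHLD2 expression z-score
#' @param build genome build (for the median copy number)
#' @param z_cutoff expression threshold, default -1
#' @return TRUE / FALSE / NA
#' @export
shld2_loss_call <- function(profile, locus, expression_z,
                            build = load_genome_build("toy"),
                            z_cutoff = -1) {
  cn_loss <- shld2_cn_loss(profile, locus, build)
  if (is.na(cn_loss)) return(NA)
  cn_loss && (expression_z < z_cutoff)
}

#' @rdname shld2_loss_call
#' @export
shld2_cn_loss <- function(profile, locus,
                          build = load_genome_build("toy")) {
  seg <- profile$segments
  hit <- seg$chrom == locus$chrom & seg$start <= locus$end &
    seg$end >= locus$start
  if (!any(hit)) return(NA)
  med <- median_total_cn(profile, build)
  any(seg$total_cn[hit] < med)
}

#' Composite resistance classifier
#'
#' The disjunctive rule: a sample is predicted RESISTANT iff it shows
#' shieldin (SHLD2) loss OR a high hypoxia signature OR a high EMT/stem
#' cell signature; with none of the three it is predicted SENSITIVE.
#' Samples with any unresolved (NA) flag are excluded with a message.
#'
#' @param calls data.frame with columns `sample`, `shld2_loss`,
#'   `hypoxia_high`, `emt_stem_high` (logical), and optionally
#'   `observed` response labels
#' @return the input with a `predicted` column added, unresolved rows
#'   dropped
#' @export
composite_resistance_call <- function(calls) {
  flags <- c("shld2_loss", "hypoxia_high", "emt_stem_high")
  stopifnot(all(c("sample", flags) %in% names(calls)))
  unresolved <- !stats::complete.cases(calls[, flags])
  if (any(unresolved)) {
    message("composite_resistance_call: excluding ",
            paste(calls$sample[unresolved], collapse = ", "),
            " (unresolved biomarker flag)")
    calls <- calls[!unresolved, , drop = FALSE]
  }
  calls$predicted <- ifelse(
    calls$shld2_loss | calls$hypoxia_high | calls$emt_stem_high,
    "RESISTANT", "SENSITIVE")
  calls
}

#' Cohort summary statistics
#'
#' Reproduces the cohort-level descriptive statistics from a clinical
#' table: sample count, germline gene counts, TNBC fraction, ER-positive
#' fraction within each germline gene, TP53-mutant fraction, RCB class
#' fractions, and the median mutation burden. Fractions are also given
#' as nearest-integer percents.
#'
#' @param records cohort data.frame from [read_cohort()] (analyzed
#'   samples only, typically `records[records$analyzed, ]`)
#' @return list of summary statistics
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0) stop("empty cohort")
  n <- nrow(records)
  pct <- function(k) round(100 * k / n)
  by_gene <- table(factor(records$germline_gene,
                          levels = c("BRCA1", "BRCA2")))
  er_by_gene <- vapply(c("BRCA1", "BRCA2"), function(g) {
    on <- records$germline_gene == g
    if (!any(on)) return(NA_real_)
    round(100 * mean(records$er_positive[on]))
  }, numeric(1))
  rcb_counts <- table(factor(records$rcb, levels = rcb_classes))
  list(
    n = n,
    n_brca1 = unname(by_gene["BRCA1"]),
    n_brca2 = unname(by_gene["BRCA2"]),
    tnbc_fraction = mean(records$tnbc),
    tnbc_pct = pct(sum(records$tnbc)),
    er_positive_pct_by_gene = er_by_gene,
    tp53_mutant_fraction = mean(records$tp53 != "wt"),
    tp53_mutant_pct = pct(sum(records$tp53 != "wt")),
    rcb_counts = rcb_counts,
    rcb_pct = stats::setNames(as.numeric(round(100 * rcb_counts / n)),
                              names(rcb_counts)),
    median_mutations_per_mb = stats::median(records$mutations_per_mb)
  )
}
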