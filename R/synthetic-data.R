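#' Simulate an allele-specific copy-number profile with planted scars
#'
#' Builds a profile on a genome build (default the 3 x 200 Mb toy build)
#' consisting of balanced (1,1) baseline segments plus planted events
#' with known scores:
#' \itemize{
#'   \item each LST pair is two abutting segments of 10--13 Mb with
#'     distinct allele-specific profiles, flanked by >3 Mb unsegmented
#'     gaps so the adjacent baseline segments cannot themselves qualify;
#'     each pair contributes exactly 2 to the LST score;
#'   \item each TAI run is a 5 Mb imbalanced terminal segment (below the
#'     10 Mb LST threshold, so the two event types never interact)
#'     ending well before the centromere; each contributes exactly 1.
#' }
#' Segment boundaries fall on whole megabases so the per-unit
#' brute-force oracles apply exactly. The attached truth is recomputed
#' from the naive oracles on every call and the generator stops if the
#' planted counts are not recovered.
#'
#' @param build genome build (events are laid out on 200 Mb
#'   toy-style chromosomes; the default toy build offers 6 LST slots
#'   and 5 TAI slots)
#' @param n_lst_pairs number of planted LST pairs
#' @param n_tai_runs number of planted telomeric imbalance runs
#' @param seed integer seed
#' @param sample_id sample name
#' @param reserve_chrom optional chromosome name kept free of planted
#'   events (baseline only), e.g. to overlay locus-level edits
#' @return list with `profile` (a [segment_profile()]) and `truth`
#'   (list: `lst_truth`, `tai_truth`, `wgii_truth`, planted counts)
#' @export
simulate_profile <- function(build = load_genome_build("toy"),
                             n_lst_pairs = 2, n_tai_runs = 1, seed = 1,
                             sample_id = "SIM", reserve_chrom = NULL) {
  set_rng(seed)
  chroms <- setdiff(build$chromosomes$chrom, reserve_chrom)
  if (!length(chroms)) stop("no chromosomes available for events")
  cen <- build$chromosomes
  if (any(cen$length[cen$chrom %in% chroms] < 200e6) ||
      any(cen$centromere_start[cen$chrom %in% chroms] != 90e6)) {
    stop("event layout needs 200 Mb chromosomes with centromeres at ",
         "90-100 Mb; use the toy build or a larger custom build")
  }
  lst_slots <- rbind(
    data.frame(chrom = chroms, slot = 1),
    data.frame(chrom = chroms, slot = 2))
  tai_q <- data.frame(chrom = chroms, end = "q")
  tai_p <- data.frame(chrom = setdiff(chroms, build$acrocentric_p_arms),
                      end = "p")
  tai_slots <- rbind(tai_q, tai_p)
  if (n_lst_pairs > nrow(lst_slots)) {
    stop("cannot fit ", n_lst_pairs, " LST pairs (", nrow(lst_slots),
         " slots); use a build with more chromosomes")
  }
  if (n_tai_runs > nrow(tai_slots)) {
    stop("cannot fit ", n_tai_runs, " TAI runs (", nrow(tai_slots),
         " slots); use a build with more chromosomes")
  }
  profiles_pool <- list(c(2, 1), c(3, 1), c(2, 2), c(3, 2))
  lst_use <- lst_slots[seq_len(n_lst_pairs), , drop = FALSE]
  tai_use <- tai_slots[seq_len(n_tai_runs), , drop = FALSE]
  mb <- 1e6
  rows <- list()
  add <- function(chrom, start_mb, end_mb, mj, mn) {
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = chrom, start = start_mb * mb + 1, end = end_mb * mb,
      total_cn = mj + mn, major_cn = mj, minor_cn = mn,
      stringsAsFactors = FALSE)
  }
  for (chrom in build$chromosomes$chrom) {
    has_p_tai <- chrom %in% tai_use$chrom[tai_use$end == "p"]
    has_q_tai <- chrom %in% tai_use$chrom[tai_use$end == "q"]
    pairs_here <- sum(lst_use$chrom == chrom)
    # p arm
    if (has_p_tai) {
      imb <- profiles_pool[[sample(c(1, 2, 4), 1)]] # imbalanced only
      add(chrom, 0, 5, imb[1], imb[2])
      add(chrom, 5, 89, 1, 1)
    } else {
      add(chrom, 0, 89, 1, 1)
    }
    # q arm: cursor walk from the centromere end at 100 Mb
    cursor <- 100
    if (pairs_here > 0) {
      for (k in seq_len(pairs_here)) {
        cursor <- cursor + 4 # unsegmented gap isolating the pair
        prof_ids <- sample(seq_along(profiles_pool), 2)
        la <- sample(10:13, 1)
        lb <- sample(10:13, 1)
        pa <- profiles_pool[[prof_ids[1]]]
        pb <- profiles_pool[[prof_ids[2]]]
        add(chrom, cursor, cursor + la, pa[1], pa[2])
        cursor <- cursor + la
        add(chrom, cursor, cursor + lb, pb[1], pb[2])
        cursor <- cursor + lb
        cursor <- cursor + 4
      }
    }
    if (has_q_tai) {
      add(chrom, cursor, 195, 1, 1)
      imb <- profiles_pool[[sample(c(1, 2, 4), 1)]]
      add(chrom, 195, 200, imb[1], imb[2])
    } else {
      add(chrom, cursor, 200, 1, 1)
    }
  }
  profile <- segment_profile(sample_id, do.call(rbind, rows))
  truth <- list(
    n_lst_pairs = n_lst_pairs,
    n_tai_runs = n_tai_runs,
    lst_truth = lst_naive(profile, build),
    tai_truth = tai_naive(profile, build),
    wgii_truth = wgii_naive(profile, build, unit = mb)
  )
  if (truth$lst_truth != 2 * n_lst_pairs ||
      truth$tai_truth != n_tai_runs) {
    stop("internal error: planted scar counts not recovered by oracles")
  }
  list(profile = profile, truth = truth)
}

#' Simulate a 96-channel mutation catalog from known exposures
#'
#' A multinomial draw of `n_mutations` substitutions from the mixture
#' distribution of the given signature profiles.
#'
#' @param signatures a [signature_matrix()]
#' @param exposures named nonnegative weights over (a subset of) the
#'   signature names, summing to 1 (tolerance 1e-6)
#' @param n_mutations catalog size
#' @param seed integer seed
#' @return list with `catalog` (a `mutation_catalog`) and `truth`
#'   (the exposure vector used)
#' @export
simulate_catalog <- function(signatures, exposures, n_mutations,
                             seed = 1) {
  if (any(exposures < 0)) stop("negative exposure")
  if (abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must sum to 1 (got ", sum(exposures), ")")
  }
  if (!all(names(exposures) %in% colnames(signatures))) {
    stop("unknown signature in exposures")
  }
  set_rng(seed)
  mix <- as.numeric(unclass(signatures)[, names(exposures), drop = FALSE]
                    %*% exposures)
  counts <- stats::setNames(numeric(96), mut_channels())
  if (n_mutations > 0) {
    draw <- stats::rmultinom(1, n_mutations, mix)[, 1]
    counts[] <- draw
  }
  list(catalog = new_mutation_catalog(counts), truth = exposures)
}

#' Simulate a log2-scale expression cohort with planted pathways
#'
#' Gaussian noise on the log2 scale around per-gene baselines, with
#' whole gene sets shifted by `effect_log2` in one response group:
#' resistance-associated sets are shifted up in RESISTANT samples,
#' sensitivity-associated sets up in SENSITIVE samples. Planted sets
#' must be disjoint. (The pipeline's ranking statistics operate on log2
#' TPM, so additive Gaussian structure on that scale is the minimal
#' model the analysis assumes; count-level dispersion is deliberately
#' not modelled.)
#'
#' @param n_genes total number of genes (ids `g0001`, ...; planted set
#'   members get the set name as prefix)
#' @param labels named character vector of `"SENSITIVE"`/`"RESISTANT"`
#'   per sample
#' @param planted_sets named list; each element a list with `size`
#'   (genes) and `direction` (`"RESISTANT"` or `"SENSITIVE"`)
#' @param effect_log2 planted shift in log2 units
#' @param noise_sd Gaussian noise SD in log2 units
#' @param seed integer seed
#' @return list with `matrix` (an `expression_matrix`, log2tpm scale),
#'   `sets` (named list of planted gene ids) and `truth`
#' @export
simulate_expression_cohort <- function(n_genes, labels,
                                       planted_sets = list(),
                                       effect_log2 = 2, noise_sd = 1,
                                       seed = 1) {
  set_rng(seed)
  n_planted <- sum(vapply(planted_sets, function(s) s$size, numeric(1)))
  if (n_planted > n_genes) stop("planted sets larger than n_genes")
  samples <- names(labels)
  if (is.null(samples)) {
    samples <- sprintf("S%02d", seq_along(labels))
    names(labels) <- samples
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sets <- list()
  cursor <- 0
  for (nm in names(planted_sets)) {
    size <- planted_sets[[nm]]$size
    idx <- cursor + seq_len(size)
    gene_ids[idx] <- sprintf("%s_%03d", nm, seq_len(size))
    sets[[nm]] <- gene_ids[idx]
    cursor <- cursor + size
  }
  baseline <- stats::runif(n_genes, 3, 9)
  values <- matrix(baseline, n_genes, length(samples)) +
    matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
           n_genes, length(samples))
  dimnames(values) <- list(gene_ids, samples)
  cursor <- 0
  for (nm in names(planted_sets)) {
    size <- planted_sets[[nm]]$size
    dir <- planted_sets[[nm]]$direction %||% "RESISTANT"
    idx <- cursor + seq_len(size)
    values[idx, labels[samples] == dir] <-
      values[idx, labels[samples] == dir] + effect_log2
    cursor <- cursor + size
  }
  values[values < 0] <- 0
  list(matrix = expression_matrix(values, "log2tpm"),
       sets = sets,
       truth = list(planted_sets = sets, effect_log2 = effect_log2,
                    noise_sd = noise_sd, labels = labels))
}

#' Simulate a multi-caller somatic variant table
#'
#' Per variant: each of the six callers supports it independently with
#' probability `caller_support_prob`; depth is Poisson(`depth_mean`)
#' floored at 1; the latent VAF is Beta(`vaf_shape1`, `vaf_shape2`) and
#' `alt_reads = round(vaf * depth)` (the stored VAF column is the
#' realized `alt_reads / depth`); the consequence class is
#' nonsynonymous with probability `fraction_nonsynonymous`. Reference,
#' alternate and trinucleotide context are drawn uniformly and
#' consistently.
#'
#' @param n_variants number of variants
#' @param caller_support_prob per-caller support probability
#' @param depth_mean Poisson mean read depth
#' @param vaf_shape1,vaf_shape2 Beta parameters of the latent VAF
#' @param fraction_nonsynonymous probability of the nonsynonymous class
#' @param seed integer seed
#' @param sample_id sample name
#' @return validated variant data.frame (see [read_variants()])
#' @export
simulate_variant_table <- function(n_variants, caller_support_prob = 0.5,
                                   depth_mean = 40, vaf_shape1 = 5,
                                   vaf_shape2 = 5,
                                   fraction_nonsynonymous = 0.7,
                                   seed = 1, sample_id = "SIM") {
  stopifnot(caller_support_prob >= 0, caller_support_prob <= 1,
            fraction_nonsynonymous >= 0, fraction_nonsynonymous <= 1,
            depth_mean > 0, vaf_shape1 > 0, vaf_shape2 > 0)
  set_rng(seed)
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = numeric(), ref = character(),
                      alt = character(), gene = character(),
                      consequence_class = character(), depth = numeric(),
                      alt_reads = numeric(), vaf = numeric(),
                      callers = character(),
                      trinucleotide_context = character(),
                      stringsAsFactors = FALSE)
  if (n_variants == 0) return(validate_variants(empty))
  bases <- c("A", "C", "G", "T")
  n_support <- stats::rbinom(n_variants, length(default_callers),
                             caller_support_prob)
  callers <- vapply(n_support, function(k) {
    paste(sort(sample(default_callers, k)), collapse = ";")
  }, character(1))
  depth <- pmax(1, stats::rpois(n_variants, depth_mean))
  latent_vaf <- stats::rbeta(n_variants, vaf_shape1, vaf_shape2)
  alt_reads <- round(latent_vaf * depth)
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                character(1))
  ctx <- paste0(sample(bases, n_variants, replace = TRUE), ref,
                sample(bases, n_variants, replace = TRUE))
  cls <- ifelse(stats::runif(n_variants) < fraction_nonsynonymous,
                "nonsynonymous",
                sample(c("synonymous", "intronic", "noncoding"),
                       n_variants, replace = TRUE))
  tab <- data.frame(
    sample = sample_id, chrom = "1",
    pos = sort(sample.int(2e8, n_variants)),
    ref = ref, alt = alt,
    gene = sprintf("GENE%04d", seq_len(n_variants)),
    consequence_class = cls, depth = depth, alt_reads = alt_reads,
    vaf = round(alt_reads / depth, 6), callers = callers,
    trinucleotide_context = ctx, stringsAsFactors = FALSE)
  validate_variants(tab)
}

#' Simulate a full synthetic cohort under the disjunctive
#' resistance model
#'
#' Generates every input the cohort pipeline consumes for `n_samples`
#' tumors, with ground truth attached. Response labels follow the study
#' proportions (7 sensitive : 6 resistant at the default n = 13). Each
#' resistant sample is planted with at least one resistance mechanism
#' -- shieldin (SHLD2) loss, hypoxia signature, or EMT/stem signature --
#' drawn independently (each with probability 0.5, forced to at least
#' one); shieldin loss is capped at 3 samples per cohort, matching the
#' recurrence actually observed for copy-number loss. Sensitive samples
#' carry no planted mechanism.
#'
#' Planted effects: SHLD2-loss samples get a (1,0) segment over the
#' SHLD2 locus plus a `shld2_drop_log2` drop in SHLD2 expression (deep
#' loss, consistent with deletion); hypoxia/EMT samples get
#' `effect_log2` upshifts of the corresponding 30-gene sets. All other
#' expression is baseline plus Gaussian noise (`noise_sd`). Each sample
#' also gets 0--2 planted LST pairs and TAI runs (chromosome 2 is
#' reserved for the SHLD2 locus) and a mutation catalog drawn from a
#' signature-3-dominant mixture, emulating an HR-deficient cohort.
#'
#' @param seed integer seed
#' @param n_samples cohort size
#' @param n_genes expression genes (includes SHLD2 and the two planted
#'   30-gene sets)
#' @param effect_log2 hypoxia/EMT planted shift (log2 units)
#' @param shld2_drop_log2 SHLD2 expression drop in loss samples
#' @param noise_sd expression noise SD (log2 units)
#' @param signatures reference signatures (default the bundled
#'   synthetic reference)
#' @return list: `labels`, `truth` (per-sample planted flags and scar
#'   truths), `profiles`, `expression`, `catalogs`, `variants`,
#'   `shld2_locus`, `sets` (hypoxia/EMT gene sets), `build`
#' @export
simulate_cohort <- function(seed = 1, n_samples = 13, n_genes = 500,
                            effect_log2 = 2, shld2_drop_log2 = 5,
                            noise_sd = 0.5,
                            signatures = synthetic_signature_reference()) {
  build <- load_genome_build("toy")
  n_resistant <- round(n_samples * 6 / 13)
  samples <- sprintf("SIM%02d", seq_len(n_samples))
  labels <- stats::setNames(
    rep(c("SENSITIVE", "RESISTANT"),
        c(n_samples - n_resistant, n_resistant)), samples)
  set_rng(seed)
  resistant <- which(labels == "RESISTANT")
  flags <- matrix(FALSE, n_samples, 3,
                  dimnames = list(samples,
                                  c("shld2", "hypoxia", "emt_stem")))
  for (i in resistant) {
    f <- stats::runif(3) < 0.5
    if (!any(f)) f[sample.int(3, 1)] <- TRUE
    flags[i, ] <- f
  }
  over <- which(flags[, "shld2"])
  if (length(over) > 3) {
    drop <- over[-seq_len(3)]
    flags[drop, "shld2"] <- FALSE
    for (i in drop) { # keep the at-least-one-mechanism invariant
      if (!any(flags[i, ])) {
        flags[i, sample(c("hypoxia", "emt_stem"), 1)] <- TRUE
      }
    }
  }
  shld2_locus <- list(chrom = "2", start = 120e6, end = 120.1e6)
  # copy-number profiles: scars on chromosomes 1 and 3, SHLD2 on 2
  profile_seeds <- sample.int(1e6, n_samples)
  n_lst <- sample(0:2, n_samples, replace = TRUE)
  n_tai <- sample(0:2, n_samples, replace = TRUE)
  catalog_seeds <- sample.int(1e6, n_samples)
  sig3 <- stats::runif(n_samples, 0.55, 0.8)
  variant_seeds <- sample.int(1e6, n_samples)
  expr_seed <- sample.int(1e6, 1)

  profiles <- list()
  truth_rows <- list()
  catalogs <- list()
  variants <- list()
  for (i in seq_len(n_samples)) {
    sim <- simulate_profile(build, n_lst_pairs = n_lst[i],
                            n_tai_runs = n_tai[i],
                            seed = profile_seeds[i],
                            sample_id = samples[i],
                            reserve_chrom = "2")
    seg <- sim$profile$segments
    if (flags[i, "shld2"]) {
      keep <- seg$chrom != "2"
      locus_rows <- data.frame(
        chrom = "2",
        start = c(1, 119e6 + 1, 121e6 + 1),
        end = c(119e6, 121e6, 200e6),
        total_cn = c(2, 1, 2), major_cn = c(1, 1, 1),
        minor_cn = c(1, 0, 1), stringsAsFactors = FALSE)
      seg <- rbind(seg[keep, ], locus_rows)
    }
    profiles[[samples[i]]] <- segment_profile(samples[i], seg)
    if (flags[i, "shld2"]) {
      # the locus overlay changes chromosome 2, so re-derive the scar
      # truths from the final profile with the naive oracles
      sim$truth$lst_truth <- lst_naive(profiles[[samples[i]]], build)
      sim$truth$tai_truth <- tai_naive(profiles[[samples[i]]], build)
      sim$truth$wgii_truth <- wgii_naive(profiles[[samples[i]]], build,
                                         unit = 1e6)
    }
    cat_sim <- simulate_catalog(
      signatures,
      exposures = c(Signature3 = sig3[i],
                    Signature5 = (1 - sig3[i]) * 0.6,
                    Signature16 = (1 - sig3[i]) * 0.4),
      n_mutations = 150, seed = catalog_seeds[i])
    catalogs[[samples[i]]] <- cat_sim$catalog
    variants[[samples[i]]] <- simulate_variant_table(
      200, caller_support_prob = 0.55, depth_mean = 60,
      seed = variant_seeds[i], sample_id = samples[i])
    truth_rows[[i]] <- data.frame(
      sample = samples[i], label = unname(labels[i]),
      shld2_planted = flags[i, "shld2"],
      hypoxia_planted = flags[i, "hypoxia"],
      emt_stem_planted = flags[i, "emt_stem"],
      lst_truth = sim$truth$lst_truth,
      tai_truth = sim$truth$tai_truth,
      wgii_truth = sim$truth$wgii_truth,
      signature3_truth = sig3[i], stringsAsFactors = FALSE)
  }
  # expression: baseline cohort, then planted biomarker structure
  expr <- simulate_expression_cohort(
    n_genes = n_genes, labels = labels,
    planted_sets = list(HYPOXIA = list(size = 30,
                                       direction = "RESISTANT"),
                        EMT_STEM = list(size = 30,
                                        direction = "RESISTANT")),
    effect_log2 = 0, noise_sd = noise_sd, seed = expr_seed)
  values <- expr$matrix$values
  rownames(values)[nrow(values)] <- "SHLD2"
  values["SHLD2", flags[, "shld2"]] <-
    values["SHLD2", flags[, "shld2"]] - shld2_drop_log2
  values[expr$sets$HYPOXIA, flags[, "hypoxia"]] <-
    values[expr$sets$HYPOXIA, flags[, "hypoxia"]] + effect_log2
  values[expr$sets$EMT_STEM, flags[, "emt_stem"]] <-
    values[expr$sets$EMT_STEM, flags[, "emt_stem"]] + effect_log2
  values[values < 0] <- 0
  list(labels = labels,
       truth = do.call(rbind, truth_rows),
       profiles = profiles,
       expression = expression_matrix(values, "log2tpm"),
       catalogs = catalogs,
       variants = do.call(rbind, c(variants, make.row.names = FALSE)),
       shld2_locus = shld2_locus,
       sets = expr$sets,
       build = build)
}

#' Synthetic reference signature matrix
#'
#' Four synthetic, well-separated 96-channel signatures (each
#' concentrated on six disjoint channels), named after the signature
#' families reported in BRCA-mutant breast tumors. These are synthetic
#' stand-ins constructed for simulation and testing, not the published
#' reference profiles; the bundled
#' `extdata/synthetic_signatures.tsv` is this matrix on disk.
#'
#' @return a [signature_matrix()] with columns `Signature3`,
#'   `Signature5`, `Signature16`, `SignatureU2`
#' @export
synthetic_signature_reference <- function() {
  channels <- mut_channels()
  names <- c("Signature3", "Signature5", "Signature16", "SignatureU2")
  weights <- c(0.30, 0.25, 0.15, 0.12, 0.10, 0.08)
  profiles <- matrix(0, 96, 4, dimnames = list(channels, names))
  for (j in seq_len(4)) {
    idx <- seq(j, by = 16, length.out = 6)
    profiles[idx, j] <- weights
  }
  signature_matrix(profiles)
}
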