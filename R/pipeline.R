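#' Read a flat key-value pipeline config
#'
#' One `key = value` pair per line; blank lines and `#` comments
#' ignored. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path config file
#' @return named list of character values
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  cfg <- as.list(stats::setNames(vals, keys))
  cfg$.dir <- dirname(normalizePath(path))
  cfg
}

cfg_path <- function(cfg, key, required = TRUE) {
  v <- cfg[[key]]
  if (is.null(v) || !nzchar(v)) {
    if (required) stop("config key '", key, "' is required")
    return(NULL)
  }
  if (!file.exists(v) && !is.null(cfg$.dir)) {
    v <- file.path(cfg$.dir, v)
  }
  if (!file.exists(v)) stop("missing input file for '", key, "': ", v)
  v
}

cfg_num <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Per-sample biomarker calls and the composite prediction
#'
#' Applies the three biomarker rules to a cohort: shieldin loss
#' (copy-number loss over the SHLD2 locus AND expression z-score below
#' `z_cutoff`), high hypoxia signature and high EMT/stem signature
#' (per-sample mean z-score above `score_cutoff`), then the disjunctive
#' composite call.
#'
#' @param profiles named list of [segment_profile()]s
#' @param expression an `expression_matrix` (log2tpm) containing the
#'   SHLD2 gene and the signature genes
#' @param shld2_locus list(`chrom`, `start`, `end`)
#' @param hypoxia_set,emt_set gene id vectors
#' @param build genome build
#' @param shld2_gene row name of SHLD2 in the matrix
#' @param score_cutoff signature-high threshold (cohort z-score units)
#' @param z_cutoff SHLD2 expression threshold
#' @return data.frame of per-sample flags, scores and the `predicted`
#'   label
#' @export
classify_cohort <- function(profiles, expression, shld2_locus,
                            hypoxia_set, emt_set,
                            build = load_genome_build("toy"),
                            shld2_gene = "SHLD2", score_cutoff = 0,
                            z_cutoff = -1) {
  samples <- names(profiles)
  missing_expr <- setdiff(samples, colnames(expression$values))
  if (length(missing_expr)) {
    stop("expression matrix missing sample(s): ",
         paste(missing_expr, collapse = ", "))
  }
  hyp <- signature_score(expression, hypoxia_set)[samples]
  emt <- signature_score(expression, emt_set)[samples]
  shld2_z <- signature_score(expression, shld2_gene)[samples]
  rows <- lapply(samples, function(sm) {
    cn_loss <- shld2_cn_loss(profiles[[sm]], shld2_locus, build)
    data.frame(
      sample = sm,
      shld2_cn_loss = cn_loss,
      shld2_z = unname(shld2_z[sm]),
      hypoxia_score = unname(hyp[sm]),
      emt_stem_score = unname(emt[sm]),
      shld2_loss = if (is.na(cn_loss)) NA else
        cn_loss && shld2_z[sm] < z_cutoff,
      hypoxia_high = unname(hyp[sm]) > score_cutoff,
      emt_stem_high = unname(emt[sm]) > score_cutoff,
      stringsAsFactors = FALSE)
  })
  composite_resistance_call(do.call(rbind, rows))
}

#' Run the cohort pipeline from a config file
#'
#' End-to-end, file-driven analysis of one cohort: reads segments,
#' variants, expression, response labels, reference signatures and
#' (optionally) gene sets and a capture BED; computes per-sample scar
#' scores, consensus-filtered mutation burden, signature exposures,
#' signature scores and biomarker calls with the composite resistance
#' prediction; and runs the response group comparisons (pooled t) on
#' every per-sample statistic, plus preranked GSEA when a GMT is given.
#' Deterministic for a fixed `seed` config key.
#'
#' Config keys (flat `key = value` file, paths relative to it):
#' `segments`, `variants`, `expression`, `response` (TSV with `sample`
#' and either `rcb` or `label`), `signatures`, optional `catalogs`
#' (channel x sample TSV; default: catalogs are built from the VAF/
#' caller-filtered variants), optional `targets` (BED) else
#' `target_mb`, optional `gene_sets` (GMT; must contain `hypoxia_set`
#' and `emt_set`), `build` (default toy), `shld2_gene`, `shld2_chrom`,
#' `shld2_start`, `shld2_end`, `score_cutoff`, `z_cutoff`,
#' `signature_of_interest` (default Signature3), `seed`, `n_perm`.
#'
#' @param config path to a config file, or a pre-parsed list
#' @param out_dir optional directory for the output TSVs
#'   (`per_sample.tsv`, `comparisons.tsv`, `enrichment.tsv`)
#' @return list with `per_sample`, `comparisons`, `enrichment`
#'   (NULL without gene sets), `summary`
#' @export
run_cohort_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  build <- load_genome_build(cfg$build %||% "toy")
  seed <- cfg_num(cfg, "seed", 1)
  profiles <- read_segments(cfg_path(cfg, "segments"))
  variants <- read_variants(cfg_path(cfg, "variants"))
  expression <- read_expression(cfg_path(cfg, "expression"))
  response <- utils::read.table(cfg_path(cfg, "response"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  signatures <- read_signatures(cfg_path(cfg, "signatures"))
  samples <- names(profiles)
  if (!is.null(response$rcb)) {
    response$label <- dichotomize_response(response$rcb)
  }
  labels <- stats::setNames(response$label, response$sample)
  missing_lab <- setdiff(samples, names(labels))
  if (length(missing_lab)) {
    stop("response table missing sample(s): ",
         paste(missing_lab, collapse = ", "))
  }
  missing_var <- setdiff(samples, unique(variants$sample))
  if (length(missing_var)) {
    stop("variant table missing sample(s): ",
         paste(missing_var, collapse = ", "))
  }
  target_mb <- if (!is.null(cfg$targets)) {
    read_target_size(cfg_path(cfg, "targets"))
  } else {
    cfg_num(cfg, "target_mb", 40)
  }
  catalogs_file <- cfg_path(cfg, "catalogs", required = FALSE)
  catalogs <- if (!is.null(catalogs_file)) {
    read_catalog_matrix(catalogs_file)
  }
  sig_name <- cfg$signature_of_interest %||% "Signature3"

  scars <- scar_scores(profiles, build)
  per_sample <- lapply(samples, function(sm) {
    v <- variants[variants$sample == sm, , drop = FALSE]
    nonsyn <- consensus_filter(v)
    catalog <- if (!is.null(catalogs)) {
      catalogs[[sm]]
    } else {
      build_catalog(consensus_filter(v, require_nonsynonymous = FALSE))
    }
    exposure <- if (sum(catalog) >= 1) {
      refit_exposures(catalog, signatures)
    } else {
      NULL
    }
    data.frame(
      sample = sm,
      label = unname(labels[sm]),
      tmb = tmb(nonsyn, target_mb),
      n_mutations = nrow(nonsyn),
      signature3 = if (is.null(exposure)) NA_real_ else
        signature_fraction(exposure, sig_name),
      stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, per_sample)
  per_sample <- merge(per_sample, scars, by = "sample", sort = FALSE)

  shld2_locus <- list(chrom = cfg$shld2_chrom %||% "2",
                      start = cfg_num(cfg, "shld2_start", 120e6),
                      end = cfg_num(cfg, "shld2_end", 120.1e6))
  sets_file <- cfg_path(cfg, "gene_sets", required = FALSE)
  enrichment <- NULL
  if (!is.null(sets_file)) {
    sets <- read_gmt(sets_file)
    hyp_name <- cfg$hypoxia_set %||% "HYPOXIA"
    emt_name <- cfg$emt_set %||% "EMT_STEM"
    calls <- classify_cohort(
      profiles, expression, shld2_locus,
      hypoxia_set = sets[[hyp_name]], emt_set = sets[[emt_name]],
      build = build, shld2_gene = cfg$shld2_gene %||% "SHLD2",
      score_cutoff = cfg_num(cfg, "score_cutoff", 0),
      z_cutoff = cfg_num(cfg, "z_cutoff", -1))
    per_sample <- merge(per_sample, calls, by = "sample", sort = FALSE)
    ranked <- rank_genes(expression, labels)
    enrichment <- gsea_preranked(ranked, sets,
                                 n_perm = cfg_num(cfg, "n_perm", 1000),
                                 seed = seed)
  }
  metrics <- intersect(c("tmb", "signature3", "wgii", "lst", "tai"),
                       names(per_sample))
  comparisons <- lapply(metrics, function(m) {
    gc <- group_compare(stats::setNames(per_sample[[m]],
                                        per_sample$sample), labels)
    data.frame(metric = m, t_statistic = gc$t_statistic,
               p_value = gc$p_value,
               mean_sensitive = gc$group_means["SENSITIVE"],
               mean_resistant = gc$group_means["RESISTANT"],
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL
  summary <- list(n = length(samples),
                  n_resistant = sum(labels[samples] == "RESISTANT"))
  if ("predicted" %in% names(per_sample)) {
    obs_res <- per_sample$label == "RESISTANT"
    pred_res <- per_sample$predicted == "RESISTANT"
    summary$sensitivity <- if (any(obs_res))
      mean(pred_res[obs_res]) else NA_real_
    summary$specificity <- if (any(!obs_res))
      mean(!pred_res[!obs_res]) else NA_real_
  }
  out <- list(per_sample = per_sample, comparisons = comparisons,
              enrichment = enrichment, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per_sample, file.path(out_dir, "per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comparisons,
                       file.path(out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment)) {
      utils::write.table(enrichment,
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Read and write a catalog matrix (channel x sample TSV)
#'
#' @param path TSV with a `channel` column plus one column per sample
#' @return named list of `mutation_catalog`s
#' @export
read_catalog_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts0 <- stats::setNames(numeric(96), mut_channels())
  out <- lapply(names(tab)[-1], function(sm) {
    counts <- counts0
    counts[tab$channel] <- tab[[sm]]
    new_mutation_catalog(counts)
  })
  stats::setNames(out, names(tab)[-1])
}

#' @rdname read_catalog_matrix
#' @param catalogs named list of `mutation_catalog`s
#' @export
write_catalog_matrix <- function(catalogs, path) {
  tab <- data.frame(channel = mut_channels(),
                    vapply(catalogs, as.numeric,
                           numeric(96)), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write every input file of a simulated cohort
#'
#' Materializes a [simulate_cohort()] result as the file set the
#' pipeline consumes, plus the ground-truth table and a ready-to-run
#' config.
#'
#' @param sim a [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @param seed seed recorded in the config (for the GSEA null)
#' @return the config file path, invisibly
#' @export
write_cohort_inputs <- function(sim, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(sim$profiles, file.path(dir, "segments.tsv"))
  write_variants(sim$variants, file.path(dir, "variants.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_catalog_matrix(sim$catalogs, file.path(dir, "catalogs.tsv"))
  write_signatures(synthetic_signature_reference(),
                   file.path(dir, "signatures.tsv"))
  write_gmt(sim$sets, file.path(dir, "sets.gmt"))
  utils::write.table(
    data.frame(sample = names(sim$labels), label = unname(sim$labels)),
    file.path(dir, "response.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("chr1\t0\t40000000"), file.path(dir, "targets.bed"))
  cfg <- c(
    "segments = segments.tsv",
    "variants = variants.tsv",
    "expression = expression.tsv",
    "catalogs = catalogs.tsv",
    "signatures = signatures.tsv",
    "gene_sets = sets.gmt",
    "response = response.tsv",
    "targets = targets.bed",
    "build = toy",
    paste("shld2_chrom =", sim$shld2_locus$chrom),
    paste("shld2_start =", format(sim$shld2_locus$start,
                                  scientific = FALSE)),
    paste("shld2_end =", format(sim$shld2_locus$end,
                                scientific = FALSE)),
    paste("seed =", seed))
  cfg_file <- file.path(dir, "config.txt")
  writeLines(cfg, cfg_file)
  invisible(cfg_file)
}
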