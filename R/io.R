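#' Allele-specific copy-number segment profiles
#'
#' A `segment_profile` holds one sample's ordered allele-specific
#' copy-number segments (1-based inclusive coordinates). Invariants
#' enforced on construction: `start <= end`, `major_cn >= minor_cn >= 0`,
#' `total_cn = major_cn + minor_cn`, and per chromosome the segments are
#' sorted and non-overlapping.
#'
#' @param sample_id sample identifier
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `total_cn`, `major_cn`, `minor_cn`
#' @return a `segment_profile` object
#' @export
segment_profile <- function(sample_id, segments) {
  req <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns ", paste(req, collapse = ", "))
  }
  segments <- segments[, req]
  segments$chrom <- as.character(segments$chrom)
  for (col in req[-1]) segments[[col]] <- as.numeric(segments[[col]])
  bad <- which(segments$start > segments$end)
  if (length(bad)) {
    stop("sample ", sample_id, ": start > end at row ", bad[1])
  }
  bad <- which(segments$major_cn < segments$minor_cn | segments$minor_cn < 0)
  if (length(bad)) {
    stop("sample ", sample_id, ": major_cn < minor_cn (or negative) at row ",
         bad[1])
  }
  bad <- which(segments$total_cn != segments$major_cn + segments$minor_cn)
  if (length(bad)) {
    stop("sample ", sample_id,
         ": total_cn != major_cn + minor_cn at row ", bad[1])
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("sample ", sample_id, ": overlapping segments on chromosome ", chr)
    }
  }
  structure(list(sample_id = sample_id, segments = segments),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile", x$sample_id, "-", nrow(x$segments), "segments on",
      length(unique(x$segments$chrom)), "chromosomes\n")
  invisible(x)
}

segment_length <- function(segments) segments$end - segments$start + 1

#' Read and write segment tables
#'
#' The segment table is a TSV with header
#' `sample chrom start end total_cn major_cn minor_cn`, one row per
#' segment, coordinates 1-based inclusive (SEG-like, as emitted by
#' allele-specific copy-number callers after post-processing).
#'
#' @param path file path
#' @return `read_segments`: named list of [segment_profile()] objects,
#'   one per sample, segments sorted per chromosome.
#' @export
read_segments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "total_cn", "major_cn",
           "minor_cn")
  if (!all(req %in% names(tab))) {
    stop("segment file must have columns ", paste(req, collapse = ", "))
  }
  out <- lapply(split(tab, tab$sample), function(s) {
    segment_profile(s$sample[1], s[, -1])
  })
  out[unique(tab$sample)]
}

#' @rdname read_segments
#' @param profiles named list of `segment_profile`s (or a single one)
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    cbind(sample = p$sample_id, p$segments)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

variant_consequences <- c("nonsynonymous", "synonymous", "intronic",
                          "intergenic", "noncoding", "splicing", "other")

#' Default somatic caller universe
#'
#' The six callers whose consensus defines the variant filter.
#' @export
default_callers <- c("MuSE", "MuTect", "MuTect2", "SomaticSniper",
                     "Strelka2", "VarScan2")

#' Read and write somatic variant tables
#'
#' Variants are rows of a TSV with columns `sample, chrom, pos, ref, alt,
#' gene, consequence_class, depth, alt_reads, vaf, callers,
#' trinucleotide_context`; `callers` is a semicolon-joined list of caller
#' names. Validation: `alt_reads <= depth`, `vaf` in [0,1] and consistent
#' with `alt_reads/depth` (tolerance 0.01 -- callers disagree on VAF
#' definitions, so the column is only sanity-checked), consequence class
#' from the known vocabulary, callers within `caller_universe`.
#'
#' @param path file path
#' @param caller_universe allowed caller names
#' @return data.frame of validated variant records (empty but typed for a
#'   header-only file); `callers` remains semicolon-joined,
#'   `n_callers` is added.
#' @export
read_variants <- function(path, caller_universe = default_callers) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = list(chrom = "character"))
  validate_variants(tab, caller_universe)
}

#' @rdname read_variants
#' @param tab a data.frame of variant records to validate in place
#' @export
validate_variants <- function(tab, caller_universe = default_callers) {
  req <- c("sample", "chrom", "pos", "ref", "alt", "gene",
           "consequence_class", "depth", "alt_reads", "vaf", "callers",
           "trinucleotide_context")
  if (!all(req %in% names(tab))) {
    stop("variant table must have columns ", paste(req, collapse = ", "))
  }
  tab <- tab[, req]
  if (nrow(tab) == 0) {
    tab$n_callers <- integer(0)
    return(tab)
  }
  bad <- which(tab$alt_reads > tab$depth)
  if (length(bad)) stop("alt_reads > depth at row ", bad[1])
  bad <- which(!(tab$consequence_class %in% variant_consequences))
  if (length(bad)) {
    stop("unknown consequence_class '", tab$consequence_class[bad[1]],
         "' at row ", bad[1])
  }
  bad <- which(tab$vaf < 0 | tab$vaf > 1)
  if (length(bad)) stop("vaf outside [0,1] at row ", bad[1])
  bad <- which(tab$depth > 0 &
                 abs(tab$vaf - tab$alt_reads / tab$depth) > 0.01)
  if (length(bad)) {
    stop("vaf inconsistent with alt_reads/depth at row ", bad[1])
  }
  caller_list <- strsplit(tab$callers, ";", fixed = TRUE)
  known <- vapply(caller_list, function(x) all(x %in% caller_universe),
                  logical(1))
  if (any(!known)) {
    stop("unknown caller name at row ", which(!known)[1])
  }
  tab$n_callers <- vapply(caller_list, function(x) length(unique(x)),
                          integer(1))
  tab
}

#' @rdname read_variants
#' @param variants a validated variant data.frame
#' @export
write_variants <- function(variants, path) {
  variants$n_callers <- NULL
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices
#'
#' TSV with gene ids in the first column, one column per sample.
#' `scale` records whether values are raw counts or log2(TPM+1); TPM
#' conversion via [log2_tpm()] needs `gene_lengths` (bp, named by gene).
#'
#' @param path file path
#' @param scale `"counts"` or `"log2tpm"`
#' @param gene_lengths optional named numeric vector of gene lengths (bp)
#' @return an `expression_matrix`: list with `values` (genes x samples
#'   numeric matrix), `scale`, `gene_lengths`.
#' @export
read_expression <- function(path, scale = c("log2tpm", "counts"),
                            gene_lengths = NULL) {
  scale <- match.arg(scale)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression cell")
  rownames(values) <- genes
  expression_matrix(values, scale, gene_lengths)
}

#' @rdname read_expression
#' @param values genes x samples numeric matrix with dimnames
#' @export
expression_matrix <- function(values, scale = c("log2tpm", "counts"),
                              gene_lengths = NULL) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene and sample dimnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene id")
  if (anyDuplicated(colnames(values))) stop("duplicate sample id")
  if (!is.null(gene_lengths) &&
      !all(rownames(values) %in% names(gene_lengths))) {
    stop("gene_lengths missing for some genes")
  }
  structure(list(values = values, scale = scale,
                 gene_lengths = gene_lengths),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples, scale =", x$scale, "\n")
  invisible(x)
}

#' @rdname read_expression
#' @param mat an `expression_matrix`
#' @export
write_expression <- function(mat, path) {
  tab <- data.frame(gene = rownames(mat$values), mat$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Members are de-duplicated
#' within each set.
#'
#' @param path GMT file
#' @return named list of character vectors (class `gene_set_collection`,
#'   with a `provenance` attribute holding the path)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  structure(sets, provenance = path, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets named list of gene vectors
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Unique target territory of a capture design
#'
#' Reads a BED file (0-based, half-open), merges overlapping or abutting
#' intervals per chromosome, and returns the union length in megabases --
#' the denominator of tumor mutation burden.
#'
#' @param path BED file (first three columns used)
#' @return total unique targeted length in Mb
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100", "chr1\t50\t150"), bed)
#' read_target_size(bed) # 150 bp = 0.00015 Mb
#' @export
read_target_size <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (any(tab$end <= tab$start)) {
    stop("BED interval with end <= start at row ",
         which(tab$end <= tab$start)[1])
  }
  total <- 0
  for (chr in unique(tab$chrom)) {
    s <- tab[tab$chrom == chr, ]
    s <- s[order(s$start, s$end), ]
    cur_start <- s$start[1]
    cur_end <- s$end[1]
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        if (s$start[i] <= cur_end) {
          cur_end <- max(cur_end, s$end[i])
        } else {
          total <- total + (cur_end - cur_start)
          cur_start <- s$start[i]
          cur_end <- s$end[i]
        }
      }
    }
    total <- total + (cur_end - cur_start)
  }
  total / 1e6
}

rcb_classes <- c("pCR", "RCB-I", "RCB-II", "RCB-III")

#' Read a cohort clinical table
#'
#' TSV with columns `sample, germline_gene, er_status, tp53, rcb,
#' tnbc_subtype, mutations_per_mb, purity, ploidy, analyzed`. The bundled
#' fixture (`system.file("extdata", "cohort_clinical.tsv", package =
#' "neoparp")`) transcribes the study cohort: 13 analyzed plus 5 excluded
#' low-purity samples.
#'
#' Derived columns: `tnbc` (er_status equal to "TNBC") and `er_positive`.
#' Any nonzero ER staining counts as ER-positive, including weak partial
#' positivity such as "ER 5% weak" (required for the cohort's 2/10
#' ER-positive rate among gBRCA1 carriers to come out right).
#'
#' @param path TSV file
#' @return data.frame of validated cohort records
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample", "germline_gene", "er_status", "tp53", "rcb",
           "tnbc_subtype", "mutations_per_mb", "purity", "ploidy",
           "analyzed")
  if (!all(req %in% names(tab))) {
    stop("cohort table must have columns ", paste(req, collapse = ", "))
  }
  bad <- which(!(tab$rcb %in% rcb_classes))
  if (length(bad)) {
    stop("unknown RCB class '", tab$rcb[bad[1]], "' at row ", bad[1])
  }
  bad <- which(!(tab$germline_gene %in% c("BRCA1", "BRCA2")))
  if (length(bad)) stop("missing or unknown germline gene at row ", bad[1])
  if (any(tab$mutations_per_mb < 0)) stop("negative mutations_per_mb")
  if (any(tab$purity < 0 | tab$purity > 1)) stop("purity outside [0,1]")
  tab$tnbc <- tab$er_status == "TNBC"
  tab$er_positive <- grepl("^ER ?[+]|^ER ?[0-9]", tab$er_status)
  tab
}

#' @rdname read_cohort
#' @param records cohort data.frame
#' @export
write_cohort <- function(records, path) {
  records$tnbc <- NULL
  records$er_positive <- NULL
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
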