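#' Consensus somatic-variant filter
#'
#' Keeps variants supported by at least `min_callers` of the caller
#' panel, covered by at least `min_depth` reads, with a variant allele
#' frequency of at least `min_vaf`, and (by default) annotated as
#' nonsynonymous. These are the defaults used throughout the pipeline
#' (2 callers, 20 reads, 5% VAF); the signature-catalog path sets
#' `require_nonsynonymous = FALSE` since mutational signatures draw on
#' all substitutions regardless of coding consequence.
#'
#' VAF is recomputed as `alt_reads / depth` for filtering; the stored
#' `vaf` column is only validated at read time.
#'
#' @param variants validated variant table from [read_variants()]
#' @param min_callers minimum number of supporting callers
#' @param min_depth minimum read depth
#' @param min_vaf minimum variant allele frequency
#' @param require_nonsynonymous keep only nonsynonymous variants
#' @return the surviving rows, input order preserved
#' @export
consensus_filter <- function(variants, min_callers = 2, min_depth = 20,
                             min_vaf = 0.05,
                             require_nonsynonymous = TRUE) {
  stopifnot(min_callers >= 1, min_vaf >= 0, min_vaf <= 1)
  if (nrow(variants) == 0) return(variants)
  vaf <- ifelse(variants$depth > 0,
                variants$alt_reads / variants$depth, 0)
  keep <- variants$n_callers >= min_callers &
    variants$depth >= min_depth &
    vaf >= min_vaf
  if (require_nonsynonymous) {
    keep <- keep & variants$consequence_class == "nonsynonymous"
  }
  variants[keep, , drop = FALSE]
}

#' Tumor mutation burden
#'
#' Nonsynonymous mutations per megabase of uniquely targeted exome. The
#' input is expected to be already consensus-filtered with
#' `require_nonsynonymous = TRUE`; the target size comes from
#' [read_target_size()] on the capture BED.
#'
#' @param variants filtered variant table (or an integer count)
#' @param target_mb unique targeted territory in Mb
#' @return mutations per Mb
#' @export
tmb <- function(variants, target_mb) {
  if (target_mb <= 0) stop("target_mb must be positive")
  n <- if (is.data.frame(variants)) nrow(variants) else variants
  n / target_mb
}

#' The 96 trinucleotide substitution channels
#'
#' Pyrimidine-centered channel labels of the form `A[C>A]A`, in the
#' package's canonical order: byte-wise lexicographic, which is also the
#' order catalogs are written to disk (bit-exact across platforms).
#'
#' @return character vector of 96 channel labels
#' @export
mut_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = bases, sub = subs, b5 = bases,
                      stringsAsFactors = FALSE)
  labels <- paste0(grid$b5, "[", grid$sub, "]", grid$b3)
  sort(labels, method = "radix")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

#' Build a 96-channel mutation catalog
#'
#' Tallies single-nucleotide variants into the 96 pyrimidine-centered
#' trinucleotide channels. Variants whose reference base is a purine are
#' reverse-complemented into the pyrimidine frame (so `A[G>T]C` is
#' counted as `G[C>A]T`). Non-SNV records (multi-base ref or alt) are
#' ignored with a message. The middle base of `trinucleotide_context`
#' must equal the reference base.
#'
#' @param variants validated variant table with `trinucleotide_context`
#' @return a `mutation_catalog`: named numeric vector over
#'   [mut_channels()]
#' @export
build_catalog <- function(variants) {
  counts <- stats::setNames(numeric(96), mut_channels())
  if (nrow(variants) == 0) return(new_mutation_catalog(counts))
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T") &
    variants$ref != variants$alt
  if (any(!is_snv)) {
    message("build_catalog: ignoring ", sum(!is_snv), " non-SNV record(s)")
  }
  v <- variants[is_snv, , drop = FALSE]
  if (nrow(v) == 0) return(new_mutation_catalog(counts))
  ctx <- toupper(v$trinucleotide_context)
  bad <- which(nchar(ctx) != 3 | substr(ctx, 2, 2) != v$ref)
  if (length(bad)) {
    stop("trinucleotide context '", v$trinucleotide_context[bad[1]],
         "' inconsistent with ref '", v$ref[bad[1]], "' for variant ",
         v$chrom[bad[1]], ":", v$pos[bad[1]])
  }
  chan <- fold_channel(ctx, v$ref, v$alt)
  tab <- table(chan)
  counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  new_mutation_catalog(counts)
}

# pyrimidine-frame channel label for (context, ref, alt); vectorized
fold_channel <- function(ctx, ref, alt) {
  purine <- ref %in% c("A", "G")
  ctx[purine] <- revcomp(ctx[purine])
  ref[purine] <- chartr("AG", "TC", ref[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
}

new_mutation_catalog <- function(counts) {
  stopifnot(length(counts) == 96,
            identical(names(counts), mut_channels()),
            all(counts >= 0))
  structure(counts, class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("mutation_catalog:", sum(x), "mutations over",
      sum(x > 0), "of 96 channels\n")
  invisible(x)
}

#' Read and write mutation catalogs
#'
#' 96-row TSV `channel<TAB>count`, channels in the canonical
#' lexicographic order of [mut_channels()].
#'
#' @param path file path
#' @return a `mutation_catalog`
#' @export
read_catalog <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  counts <- stats::setNames(numeric(96), mut_channels())
  if (!all(tab$channel %in% names(counts))) stop("unknown channel label")
  counts[tab$channel] <- tab$count
  new_mutation_catalog(counts)
}

#' @rdname read_catalog
#' @param catalog a `mutation_catalog`
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(channel = names(catalog), count = as.numeric(catalog)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
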