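#' Genome builds for scar scoring
#'
#' A `genome_build` carries, per chromosome, the length and the centromere
#' interval, plus the set of acrocentric chromosomes whose p-arms are
#' skipped by the telomeric-allelic-imbalance score (exome capture has no
#' coverage on acrocentric p-arms). All coordinates are 1-based inclusive.
#'
#' Two builds ship with the package:
#' \describe{
#'   \item{`"toy"`}{three 200 Mb chromosomes with centromeres at
#'     90--100 Mb; chromosome 3 is acrocentric. The default substrate of
#'     the synthetic generators, small enough for brute-force oracles.}
#'   \item{`"hg19"`}{the 22 human autosomes plus X with hg19 lengths and
#'     UCSC centromere gap intervals; 13, 14, 15 and 22 acrocentric.}
#' }
#'
#' @param name builtin name (`"toy"`, `"hg19"`) or path to a build config
#'   file written by [write_genome_build()] (tab-separated:
#'   `chrom length centromere_start centromere_end acrocentric`).
#' @return an object of class `genome_build`: a list with elements
#'   `chromosomes` (data.frame: `chrom`, `length`, `centromere_start`,
#'   `centromere_end`), `acrocentric_p_arms` (character) and
#'   `coordinate_convention` (`"1-based inclusive"`).
#' @examples
#' build <- load_genome_build("toy")
#' build$chromosomes
#' @export
load_genome_build <- function(name = "toy") {
  if (name == "toy") {
    chroms <- data.frame(
      chrom = c("1", "2", "3"),
      length = rep(200e6, 3),
      centromere_start = rep(90e6, 3),
      centromere_end = rep(100e6, 3),
      stringsAsFactors = FALSE
    )
    return(new_genome_build(chroms, acrocentric = "3"))
  }
  if (name %in% c("hg19", "hg19-like")) {
    return(new_genome_build(hg19_chromosome_table(),
                            acrocentric = c("13", "14", "15", "22")))
  }
  if (!file.exists(name)) {
    stop("unknown builtin build and no such file: ", name)
  }
  tab <- utils::read.table(name, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric", "logical"))
  new_genome_build(tab[, c("chrom", "length", "centromere_start",
                           "centromere_end")],
                   acrocentric = tab$chrom[tab$acrocentric])
}

#' @rdname load_genome_build
#' @param build a `genome_build`
#' @param path output file
#' @export
write_genome_build <- function(build, path) {
  tab <- build$chromosomes
  tab$acrocentric <- tab$chrom %in% build$acrocentric_p_arms
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_genome_build <- function(chroms, acrocentric = character()) {
  stopifnot(is.data.frame(chroms),
            all(c("chrom", "length", "centromere_start",
                  "centromere_end") %in% names(chroms)))
  chroms$chrom <- as.character(chroms$chrom)
  if (anyDuplicated(chroms$chrom)) stop("duplicate chromosome names")
  if (any(chroms$length <= 0)) stop("nonpositive chromosome length")
  bad <- !(chroms$centromere_start > 0 &
             chroms$centromere_start < chroms$centromere_end &
             chroms$centromere_end < chroms$length)
  if (any(bad)) {
    stop("invalid centromere interval on chromosome ",
         paste(chroms$chrom[bad], collapse = ", "))
  }
  acrocentric <- as.character(acrocentric)
  if (!all(acrocentric %in% chroms$chrom)) {
    stop("acrocentric chromosome not in build")
  }
  structure(list(chromosomes = chroms[, c("chrom", "length",
                                          "centromere_start",
                                          "centromere_end")],
                 acrocentric_p_arms = acrocentric,
                 coordinate_convention = "1-based inclusive"),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", nrow(x$chromosomes), "chromosomes;",
      "acrocentric p-arms:",
      if (length(x$acrocentric_p_arms))
        paste(x$acrocentric_p_arms, collapse = ", ") else "none", "\n")
  invisible(x)
}

# Autosomes named "1".."22" (or with a stripped "chr" prefix) present in
# the build, in build order.
build_autosomes <- function(build) {
  chr <- sub("^chr", "", build$chromosomes$chrom)
  build$chromosomes$chrom[chr %in% as.character(1:22)]
}

# hg19 chromosome lengths with UCSC gap-track centromere intervals.
hg19_chromosome_table <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X"),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560),
    centromere_start = c(121535434, 92326171, 90504854, 49660117, 46405641,
                         58830166, 58054331, 43838887, 47367679, 39254935,
                         51644205, 34856694, 16000000, 16000000, 17000000,
                         35335801, 22263006, 15460898, 24681782, 26369569,
                         11288129, 13000000, 58632012),
    centromere_end = c(124535434, 95326171, 93504854, 52660117, 49405641,
                       61830166, 61054331, 46838887, 50367679, 42254935,
                       54644205, 37856694, 19000000, 19000000, 20000000,
                       38335801, 25263006, 18460898, 27681782, 29369569,
                       14288129, 16000000, 61632012),
    stringsAsFactors = FALSE
  )
}
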