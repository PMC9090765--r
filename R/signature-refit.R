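#' Reference signature matrices
#'
#' A `signature_matrix` is a 96 x k nonnegative matrix, one column per
#' mutational signature, each column summing to 1 (tolerance 1e-6), rows
#' in the canonical [mut_channels()] order. The on-disk format is a
#' COSMIC-v2-style TSV: `channel<TAB>sig1<TAB>sig2...`.
#'
#' A small synthetic reference of four well-separated signatures ships
#' with the package (`system.file("extdata",
#' "synthetic_signatures.tsv", package = "neoparp")`); it stands in for
#' published references, which cannot be redistributed here, and is used
#' by the simulators and tests.
#'
#' @param path TSV file
#' @return a `signature_matrix`
#' @export
read_signatures <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  signature_matrix(m)
}

#' @rdname read_signatures
#' @param profiles 96 x k numeric matrix, rownames = channel labels,
#'   colnames = signature names
#' @export
signature_matrix <- function(profiles) {
  if (is.null(rownames(profiles)) ||
      !setequal(rownames(profiles), mut_channels())) {
    stop("signature profiles must be indexed by the 96 channel labels")
  }
  profiles <- profiles[mut_channels(), , drop = FALSE]
  if (any(profiles < 0)) stop("negative signature profile entry")
  sums <- colSums(profiles)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("signature profile does not sum to 1: ",
         paste(colnames(profiles)[abs(sums - 1) > 1e-6], collapse = ", "))
  }
  structure(profiles, class = c("signature_matrix", "matrix"))
}

#' @rdname read_signatures
#' @param signatures a `signature_matrix`
#' @export
write_signatures <- function(signatures, path) {
  tab <- data.frame(channel = rownames(signatures),
                    unclass(signatures), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Refit mutational-signature exposures
#'
#' Estimates the per-signature contribution to an observed 96-channel
#' catalog by constrained forward selection: the catalog is (optionally
#' rescaled channel-wise, e.g. by an exome-to-genome trinucleotide
#' frequency correction, then) normalized to the 96-simplex, and weights
#' are grown from zero by repeatedly adding, for the single signature
#' whose optimal step size on [0, 1 - total weight] most reduces the sum
#' of squared channel errors, that step; iteration stops when the best
#' achievable improvement falls below `tol`. The optimal step has a
#' closed form (the least-squares projection of the current residual on
#' the signature profile, clipped to the feasible interval), so the fit
#' is deterministic and involves no randomness. Weights below
#' `discard_cutoff` are then zeroed and the survivors rescaled to the
#' pre-discard total, mirroring the discard convention of established
#' refitting tools.
#'
#' @param catalog a `mutation_catalog` with at least one mutation
#' @param signatures a [signature_matrix()]
#' @param discard_cutoff minimum reportable weight
#' @param context_scaling optional positive 96-vector multiplied into
#'   the catalog channel-wise before normalization (all-ones = no
#'   correction)
#' @param tol stopping tolerance on the squared-error improvement
#' @return a `signature_exposure`: list with `weights` (named, summing
#'   to at most 1), `residual_error` (L2 norm of normalized catalog
#'   minus reconstruction) and `sample_id` if the catalog carries one
#' @export
refit_exposures <- function(catalog, signatures, discard_cutoff = 0.06,
                            context_scaling = NULL, tol = 1e-3) {
  if (sum(catalog) < 1) stop("empty catalog")
  if (!identical(rownames(signatures), mut_channels()) ||
      !identical(names(catalog), mut_channels())) {
    stop("channel-order mismatch between catalog and signatures")
  }
  x <- as.numeric(catalog)
  if (!is.null(context_scaling)) {
    if (length(context_scaling) != 96 || any(context_scaling < 0)) {
      stop("context_scaling must be a nonnegative 96-vector")
    }
    x <- x * as.numeric(context_scaling)
  }
  t_vec <- x / sum(x)
  p <- unclass(signatures)
  k <- ncol(p)
  sig_names <- colnames(p)
  pp <- colSums(p^2)
  w <- stats::setNames(numeric(k), sig_names)
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > 500) break
    r <- t_vec - as.numeric(p %*% w)
    room <- 1 - sum(w)
    alpha <- pmax(0, pmin(room, colSums(p * r) / pp))
    gain <- 2 * alpha * colSums(p * r) - alpha^2 * pp
    best <- which(gain >= max(gain) - 1e-15)
    best <- best[order(sig_names[best])][1] # name-based tie-break
    if (gain[best] < tol) break
    w[best] <- w[best] + alpha[best]
  }
  pre_total <- sum(w)
  w[w < discard_cutoff] <- 0
  if (sum(w) > 0) w <- w * pre_total / sum(w)
  resid <- sqrt(sum((t_vec - as.numeric(p %*% w))^2))
  structure(list(weights = w, residual_error = resid),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("signature_exposure:",
      paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", "),
      sprintf("(residual %.4f)\n", x$residual_error))
  invisible(x)
}

#' Contribution of one signature
#'
#' @param exposure a [refit_exposures()] result
#' @param name signature name
#' @return the weight of that signature, 0 if absent from the fit
#' @export
signature_fraction <- function(exposure, name) {
  if (!name %in% names(exposure$weights)) return(0)
  unname(exposure$weights[name])
}
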