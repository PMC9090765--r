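# Every stochastic entry point takes an explicit integer seed and calls
# this, so reruns with the same arguments are byte-identical regardless
# of the session's RNG state.
set_rng <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
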