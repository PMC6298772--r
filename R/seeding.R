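#' Derive a named sub-seed from a master seed
#'
#' Every generated table gets its own RNG stream, derived deterministically
#' from the master seed and a stable stream name. Adding a new table to a
#' simulation therefore never perturbs the draws of existing tables.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (e.g. `"screen/plasmid"`).
#' @return An integer in `[0, 2^31)` usable with [set.seed()].
#' @export
subseed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147480009 # largest prime below 2^31 keeps arithmetic exact in doubles
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% m
  as.integer(((seed %% m) * 2654435 + h) %% m)
}

# evaluate code under the named sub-stream, restoring the caller's RNG state
with_stream <- function(seed, name, code) {
  withr::with_seed(subseed(seed, name), code)
}
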