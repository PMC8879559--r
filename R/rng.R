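# Seed handling: every stochastic entry point takes an explicit seed and
# runs under a private RNG state, restoring the caller's stream afterwards.
# Stage seeds are derived from a master seed by hashing a stage tag, so any
# stage of an experiment can be re-run in isolation with the same draws.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage tag to a new seed in
#' `[0, 2^31 - 2]`, using a multiplicative string hash. Used throughout the
#' experiment driver so that each pipeline stage consumes an independent,
#' reproducible stream.
#'
#' @param master integer master seed.
#' @param tag character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(tag) == 1, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}
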