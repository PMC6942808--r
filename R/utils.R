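#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores whatever global RNG state existed beforehand.  All stochastic
#' functions in this package route their randomness through this helper, so
#' no call ever mutates the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically fans one master seed out to per-stage seeds so that the
#' pipeline stages draw from independent, reproducible streams.  The
#' derivation is a fixed affine map modulo a Mersenne prime, kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stage stage name (character scalar).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
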