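#' @useDynLib focmpanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Seed handling utilities
#'
#' The package derives every source of randomness from a single user-facing
#' integer seed. \code{substream_seed} expands that seed into independent
#' per-purpose substreams by a fixed affine map modulo a Mersenne prime, so
#' that, e.g., cohort generation, validation-cohort generation, and CV fold
#' assignment never share a stream. \code{with_seed} evaluates an expression
#' under a given seed and restores the caller's RNG state afterwards.
#'
#' @param seed Integer master seed.
#' @param purpose Integer substream index (>= 0).
#' @return \code{substream_seed}: an integer seed < 2^31.
#' @export
substream_seed <- function(seed, purpose) {
  # affine map mod 2^31 - 1; coefficients are arbitrary fixed odd constants
  as.integer((as.numeric(seed) * 48271 + as.numeric(purpose) * 16807 + 1) %%
               2147483647)
}

#' @rdname substream_seed
#' @param expr Expression to evaluate.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
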