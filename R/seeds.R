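#' Derive a deterministic stream of sub-seeds from a master seed
#'
#' Multi-run ICA and order scans need one reproducible RNG seed per run.
#' Sub-seeds are produced by a Lehmer multiplicative congruential generator
#' (multiplier 48271, modulus 2^31 - 1) seeded from the master seed, so the
#' stream is fully determined by `seed` and never touches R's global RNG
#' state. All values are strictly below 2^31.
#'
#' @param seed Master seed (single integerish value).
#' @param n Number of sub-seeds to draw.
#' @param stream Optional non-negative integer offsetting the stream, so that
#'   independent consumers (e.g. different decomposition orders in a scan)
#'   derive disjoint seed sequences from one master seed.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), n >= 0, is.numeric(stream), stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(seed)) + 1) %% m
  if (x == 0) x <- 1
  # burn-in decorrelates nearby master seeds; stream offsets skip ahead
  for (i in seq_len(8L + stream %% 64L)) x <- (48271 * x) %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (48271 * x) %% m
    out[i] <- x
  }
  as.integer(out)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_preserved_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}
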