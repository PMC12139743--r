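# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded generators do not disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Gaussian-kernel smoothing; sd in samples. Edge bins use a renormalized
# (truncated) kernel so the smoothed trace has no padding artifacts.
# sd <= 0 returns x unchanged.
gauss_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  num <- stats::convolve(x, k, type = "open")
  den <- stats::convolve(rep(1, n), k, type = "open")
  (num / den)[(half + 1L):(half + n)]
}
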