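# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library functions can be
#' deterministic without disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic per-unit sub-seed
#'
#' Splits one master seed into independent streams (one per plant, stage, ...)
#' so each unit is reproducible regardless of iteration order. Kept below
#' 2^31 - 1 to stay a valid R integer seed.
#' @noRd
split_seed <- function(seed, index, stream = 0L) {
  ((as.double(seed) %% 2147483647) * 48271 + index * 7919 + stream * 104729) %%
    2147483647
}

#' Trapezoidal quadrature weights for an arbitrary 1-D grid
#' @noRd
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two grid points for integration")
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
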