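# Internal helpers shared across modules.

#' Centered moving average
#'
#' Running mean with a centered window; edges use the available (shorter)
#' window so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param k window width in samples (odd values recommended; default 5).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, k = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
# Keeps simulator determinism contracts without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
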