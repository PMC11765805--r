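# Subpixel translation registration by Fourier cross-correlation.
#
# The integer shift is the cross-correlation peak; the subpixel refinement
# maximizes the continuous cross-correlation (evaluated exactly from the
# Fourier coefficients) around that peak, which is equivalent to
# upsampled-DFT peak localization.

signed_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k
}

# Shift of `img` relative to `ref`: img(y, x) ~= ref(y - sy, x - sx).
estimate_shift <- function(ref, img, refine = TRUE) {
  ny <- nrow(ref); nx <- ncol(ref)
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    warnf("flat image: correlation peak ambiguous, assuming zero shift")
    return(c(dx = 0, dy = 0))
  }
  P <- Conj(stats::fft(ref)) * stats::fft(img)
  cc <- Re(stats::fft(P, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) { s <- i - 1L; if (s > n %/% 2) s - n else s }
  sy <- wrap(pk[1], ny); sx <- wrap(pk[2], nx)
  if (refine) {
    fy <- signed_freqs(ny) / ny
    fx <- signed_freqs(nx) / nx
    obj <- function(s) {
      ey <- exp(2i * pi * fy * s[1])
      ex <- exp(2i * pi * fx * s[2])
      -Re(sum(P * (ey %o% ex)))
    }
    opt <- stats::optim(c(sy, sx), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 200))
    sy <- opt$par[1]; sx <- opt$par[2]
  }
  c(dx = sx, dy = sy)
}

# Translate an image by (dx, dy) via the Fourier shift theorem:
# out(y, x) = img(y - dy, x - dx) (circular).
fourier_shift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- signed_freqs(ny) / ny
  fx <- signed_freqs(nx) / nx
  ph <- exp(-2i * pi * fy * dy) %o% exp(-2i * pi * fx * dx)
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

#' Drift-correct a single-cell stack
#'
#' Estimates the per-frame translation against a reference frame by
#' Fourier cross-correlation with subpixel refinement, and applies the
#' inverse shift to every frame.
#'
#' @param stack `ny x nx x T` numeric array (one channel).
#' @param reference index of the reference frame (default 1).
#' @param refine subpixel refinement (default `TRUE`).
#' @return list with `corrected` (registered stack) and `shifts`
#'   (`T x 2` matrix of estimated per-frame shifts, columns `dx`, `dy`,
#'   relative to the reference frame).
#' @export
register_translation <- function(stack, reference = 1L, refine = TRUE) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  nt <- dim(stack)[3]
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dx", "dy")))
  if (nt == 1L) return(list(corrected = stack, shifts = shifts))
  ref <- stack[, , reference]
  corrected <- stack
  for (k in seq_len(nt)) {
    if (k == reference) next
    s <- estimate_shift(ref, stack[, , k], refine = refine)
    shifts[k, ] <- s
    corrected[, , k] <- fourier_shift(stack[, , k], -s[1], -s[2])
  }
  list(corrected = corrected, shifts = shifts)
}

#' Register all channels of a movie
#'
#' Shifts are estimated on `channel` (first channel by default) and applied
#' to every channel, so co-registered channels stay aligned.
#'
#' @param movie a `fork_movie`.
#' @param channel channel used for shift estimation.
#' @param refine subpixel refinement (default `TRUE`).
#' @return list with `movie` (drift-corrected) and `shifts`.
#' @export
register_movie <- function(movie, channel = movie$channels[1], refine = TRUE) {
  stopifnot(inherits(movie, "fork_movie"))
  reg <- register_translation(movie$data[[channel]], refine = refine)
  out <- movie
  out$data[[channel]] <- reg$corrected
  for (ch in setdiff(movie$channels, channel)) {
    arr <- movie$data[[ch]]
    for (k in seq_len(dim(arr)[3])) {
      if (any(reg$shifts[k, ] != 0))
        arr[, , k] <- fourier_shift(arr[, , k],
                                    -reg$shifts[k, 1], -reg$shifts[k, 2])
    }
    out$data[[ch]] <- arr
  }
  list(movie = out, shifts = reg$shifts)
}
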