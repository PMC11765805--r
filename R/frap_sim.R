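# Synthetic FRAP movies: one bleached focus, one unbleached reference
# focus, a uniform diffuse pool, and a recovery law with fast-diffusing,
# slow-bound and immobile components.

#' Ground-truth FRAP recovery parameters
#'
#' The bleached focus recovers as
#' `R(t) = A_f * (1 - exp(-k_f * t)) + A_s * (1 - exp(-k_s * t))` with an
#' immobile remainder `1 - A_f - A_s`. Times are in seconds. The fast
#' component stands for the freely diffusing pool, the slow component for
#' exchange of the fork-bound pool.
#'
#' @param A_f,k_f fast (diffusing) amplitude and rate (1/s).
#' @param A_s,k_s slow (bound-exchange) amplitude and rate (1/s); set
#'   `A_s = 0` for single-step recovery.
#' @param bleach_depth multiplicative factor left on the focus right after
#'   the bleach (0 = complete bleach).
#' @param bound_fraction steady-state bound fraction of the channel's
#'   nuclear pool during the FRAP acquisition.
#' @param n_pre number of pre-bleach frames imaged (default 6; the
#'   normalization requires six).
#' @param interval_s frame interval, seconds.
#' @param total_s imaged time after the bleach, seconds.
#' @return an object of class `frap_kinetics`.
#' @export
frap_kinetics <- function(A_f = 0.5, k_f = log(2) / 2, A_s = 0.35,
                          k_s = log(2) / 149, bleach_depth = 0.1,
                          bound_fraction = 0.3, n_pre = 6L,
                          interval_s = 1, total_s = 300) {
  stopifnot(A_f >= 0, A_s >= 0, k_f > 0, bleach_depth >= 0,
            bleach_depth < 1, bound_fraction > 0, bound_fraction < 1,
            n_pre >= 1, interval_s > 0, total_s > 0)
  if (A_s > 0 && k_s <= 0) stopf("k_s must be positive when A_s > 0")
  if (A_f + A_s > 1 + 1e-12)
    stopf("A_f + A_s = %.3f exceeds 1 (negative immobile fraction)",
          A_f + A_s)
  structure(list(A_f = A_f, k_f = k_f, A_s = A_s, k_s = k_s,
                 immobile = 1 - A_f - A_s, bleach_depth = bleach_depth,
                 bound_fraction = bound_fraction, n_pre = as.integer(n_pre),
                 interval_s = interval_s, total_s = total_s),
            class = "frap_kinetics")
}

# True recovery law, t in seconds since the bleach frame.
frap_recovery_law <- function(frap, t) {
  frap$A_f * (1 - exp(-frap$k_f * t)) +
    (if (frap$A_s > 0) frap$A_s * (1 - exp(-frap$k_s * t)) else 0)
}

#' Render a FRAP movie
#'
#' Pre-bleach frames show the steady state. From the bleach frame onward
#' the bleached focus carries
#' `depth + (1 - depth) * R(t)` of its pre-bleach amount, where `R` is the
#' recovery law of `frap`; the reference focus and the diffuse pool are
#' unchanged (free diffusion re-equilibrates faster than the frame
#' interval). The first focus of `geometry` is bleached, the second is the
#' reference.
#'
#' @param frap a [frap_kinetics()].
#' @param geometry a [scene_geometry()] with at least two foci.
#' @param optics an [optics_noise()].
#' @param channel channel name for the output movie.
#' @return list with `movie` (class `fork_movie`, with `bleach_frame`) and
#'   `truth` (class `frap_truth`).
#' @export
render_frap_movie <- function(frap, geometry, optics, channel = "PCNA") {
  stopifnot(inherits(frap, "frap_kinetics"),
            inherits(geometry, "scene_geometry"),
            inherits(optics, "optics_noise"))
  if (geometry$n_foci < 2)
    stopf("FRAP geometry needs a bleached and a reference focus (>= 2 foci)")
  bleach_frame <- frap$n_pre + 1L
  if (bleach_frame <= 5L)
    stopf("bleach frame must be later than frame 5")
  nt <- frap$n_pre + as.integer(ceiling(frap$total_s / frap$interval_s))
  times_s <- (seq_len(nt) - 1L) * frap$interval_s
  t_since <- pmax(times_s - times_s[bleach_frame], 0)

  dim <- geometry$dim
  budget <- rep_len(optics$budget, 1L)
  bound <- frap$bound_fraction * budget
  diffuse <- budget - bound
  amounts <- bound * geometry$weights
  factor <- rep(1, nt)
  post <- seq_len(nt) >= bleach_frame
  factor[post] <- frap$bleach_depth +
    (1 - frap$bleach_depth) * frap_recovery_law(frap, t_since[post])

  mask <- ellipse_mask(dim, geometry$center, geometry$semiaxes)
  base <- matrix(optics$background, dim[1], dim[2])
  base[mask] <- base[mask] + diffuse / sum(mask)
  for (i in seq_len(geometry$n_foci)[-1]) {
    base <- add_gaussian(base, geometry$foci[i, 1], geometry$foci[i, 2],
                         geometry$focus_sigmas[i], amounts[i])
  }
  arr <- array(0, c(dim[1], dim[2], nt))
  for (k in seq_len(nt)) {
    arr[, , k] <- add_gaussian(base, geometry$foci[1, 1], geometry$foci[1, 2],
                               geometry$focus_sigmas[1],
                               amounts[1] * factor[k])
  }
  arr <- with_local_seed(optics$seed, apply_noise(arr, optics))

  data <- stats::setNames(list(arr), channel)
  movie <- structure(list(data = data, channels = channel,
                          times_min = times_s / 60,
                          times_s = times_s,
                          frame_interval_s = frap$interval_s,
                          bleach_frame = bleach_frame,
                          t_treat_frame = NA_integer_,
                          t_washout_frame = NA_integer_),
                     class = "fork_movie")
  truth <- structure(list(frap = frap, geometry = geometry, optics = optics,
                          bleach_frame = bleach_frame, times_s = times_s,
                          focus_factor = factor,
                          pre_bleach_amount = amounts[1],
                          seed = optics$seed),
                     class = "frap_truth")
  list(movie = movie, truth = truth)
}
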