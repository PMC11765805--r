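# Synthetic time-lapse movies with fully known ground truth.
#
# A nucleus is an ellipse holding a total fluorophore budget per channel.
# At each frame the channel's kinetic schedule dictates which fraction of
# that budget is bound at foci (rendered as 2-D Gaussians) and which is
# freely diffusing (spread uniformly over the nucleus). Conservation of the
# total pool is therefore built in, exactly as assumed by diffuse-pool
# photometry.

#' Scene geometry for a synthetic nucleus
#'
#' Coordinates are 0-based pixel indices, x to the right, y down. Foci are
#' placed at least `margin_sigma` PSF widths inside the nucleus edge so that
#' their Gaussian mass is not clipped.
#'
#' @param dim image size, `c(ny, nx)` pixels.
#' @param center nucleus ellipse center `c(x, y)` in pixels.
#' @param semiaxes nucleus ellipse semi-axes `c(rx, ry)` in pixels.
#' @param n_foci number of replication foci.
#' @param focus_sigma PSF sigma of a focus, pixels.
#' @param foci optional `n x 2` matrix of focus centers (x, y); when `NULL`
#'   foci are placed deterministically from `seed`.
#' @param weights per-focus share of the bound pool; recycled and
#'   normalized to sum to 1 (default equal weights).
#' @param drift per-frame drift `c(dx, dy)` in pixels/frame.
#' @param sigma_jitter SD of per-focus multiplicative sigma variation
#'   (0 = identical foci).
#' @param margin_sigma minimum distance of a focus from the nucleus edge,
#'   in units of `focus_sigma`.
#' @param seed seed for deterministic focus placement.
#' @return an object of class `scene_geometry`.
#' @export
scene_geometry <- function(dim = c(128L, 128L),
                           center = (rev(dim) - 1) / 2,
                           semiaxes = c(0.75, 0.62) * rev(dim) / 2,
                           n_foci = 20L, focus_sigma = 2,
                           foci = NULL, weights = 1,
                           drift = c(0, 0), sigma_jitter = 0,
                           margin_sigma = 4, seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 16), focus_sigma > 0, n_foci >= 0)
  if (is.null(foci) && n_foci > 0) {
    foci <- place_foci(center, semiaxes, n_foci, focus_sigma * margin_sigma,
                       min_sep = 4 * focus_sigma, seed = seed)
  } else if (n_foci == 0) {
    foci <- matrix(numeric(0), ncol = 2)
  } else {
    foci <- as.matrix(foci)
    stopifnot(ncol(foci) == 2L, nrow(foci) == n_foci)
    d <- ((foci[, 1] - center[1]) / semiaxes[1])^2 +
         ((foci[, 2] - center[2]) / semiaxes[2])^2
    if (any(d >= 1))
      stopf("focus %d lies outside the nucleus ellipse", which(d >= 1)[1])
  }
  w <- rep_len(weights, max(n_foci, 1L))
  sig <- rep(focus_sigma, max(n_foci, 1L))
  if (sigma_jitter > 0 && n_foci > 0) {
    sig <- with_local_seed(seed + 1L,
      focus_sigma * exp(stats::rnorm(n_foci, 0, sigma_jitter)))
  }
  structure(list(dim = as.integer(dim), center = center,
                 semiaxes = semiaxes, n_foci = as.integer(n_foci),
                 foci = foci, weights = w / sum(w),
                 focus_sigma = focus_sigma, focus_sigmas = sig,
                 drift = drift), class = "scene_geometry")
}

# Deterministic rejection sampling of focus centers inside the shrunken
# nucleus ellipse, keeping foci min_sep apart.
place_foci <- function(center, semiaxes, n, margin, min_sep, seed) {
  ax <- pmax(semiaxes - margin, 1)
  with_local_seed(seed, {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < n && tries < 20000L) {
      tries <- tries + 1L
      u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
      if (u^2 + v^2 > 1) next
      p <- c(center[1] + u * ax[1], center[2] + v * ax[2])
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
        pts <- rbind(pts, p)
    }
    if (nrow(pts) < n)
      stopf("could not place %d foci with separation %.1f px", n, min_sep)
    unname(pts)
  })
}

#' Camera and illumination model
#'
#' @param budget total fluorophore budget per channel (arbitrary units);
#'   a single value is recycled across channels.
#' @param background camera offset added everywhere (a.u.).
#' @param photon_scale scale of Poisson photon noise: a pixel of mean `v`
#'   is drawn as `photon_scale * rpois(v / photon_scale)`; 0 disables
#'   photon noise. Default gives focus SNR of roughly 10 with the default
#'   scene.
#' @param read_sigma additive Gaussian read noise SD (a.u.); 0 disables.
#' @param bleach_rate acquisition photobleaching, fraction of the remaining
#'   pool lost per frame (default 0).
#' @param seed RNG seed making the rendered movie deterministic.
#' @return an object of class `optics_noise`.
#' @export
optics_noise <- function(budget = 6e5, background = 20,
                         photon_scale = 2, read_sigma = 3,
                         bleach_rate = 0, seed = 1L) {
  stopifnot(all(budget > 0), background >= 0, photon_scale >= 0,
            read_sigma >= 0, bleach_rate >= 0, bleach_rate < 1)
  structure(list(budget = budget, background = background,
                 photon_scale = photon_scale, read_sigma = read_sigma,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "optics_noise")
}

# Ellipse membership mask (pixel-center rule) for an optionally shifted
# nucleus. Returns a logical ny x nx matrix (rows = y, cols = x).
ellipse_mask <- function(dim, center, semiaxes, shift = c(0, 0)) {
  x <- (seq_len(dim[2]) - 1) - (center[1] + shift[1])
  y <- (seq_len(dim[1]) - 1) - (center[2] + shift[2])
  outer((y / semiaxes[2])^2, (x / semiaxes[1])^2, `+`) <= 1
}

# Add a 2-D Gaussian of integrated intensity `amount` at (cx, cy).
add_gaussian <- function(img, cx, cy, sigma, amount) {
  ny <- nrow(img); nx <- ncol(img)
  ex <- exp(-(((seq_len(nx) - 1) - cx)^2) / (2 * sigma^2))
  ey <- exp(-(((seq_len(ny) - 1) - cy)^2) / (2 * sigma^2))
  img + (amount / (2 * pi * sigma^2)) * (ey %o% ex)
}

apply_noise <- function(arr, optics) {
  if (optics$photon_scale > 0) {
    lam <- pmax(arr, 0) / optics$photon_scale
    arr[] <- optics$photon_scale * stats::rpois(length(lam), lam)
  }
  if (optics$read_sigma > 0)
    arr[] <- arr + stats::rnorm(length(arr), 0, optics$read_sigma)
  arr
}

#' Render a stalling/restart movie
#'
#' Produces a multi-channel time-lapse whose every hidden quantity is
#' recorded in the returned ground truth. Per frame and channel, the
#' schedule's bound fraction times the (photobleaching-corrected) budget is
#' split across foci; the remainder is spread uniformly over the nucleus.
#'
#' @param schedule a [kinetic_schedule()].
#' @param geometry a [scene_geometry()].
#' @param optics an [optics_noise()].
#' @param frame_interval_s frame interval in seconds (default 30).
#' @return a list with components `movie` (class `fork_movie`: named list
#'   `data` of `ny x nx x T` arrays, frame times, treatment frame indices)
#'   and `truth` (class `fork_truth`: the schedule, per-frame true bound
#'   fractions and per-focus bound amounts, seed).
#' @export
render_movie <- function(schedule, geometry, optics, frame_interval_s = 30) {
  stopifnot(inherits(schedule, "kinetic_schedule"),
            inherits(geometry, "scene_geometry"),
            inherits(optics, "optics_noise"))
  nt <- floor(schedule$t_end * 60 / frame_interval_s) + 1L
  times <- (seq_len(nt) - 1L) * frame_interval_s / 60
  chans <- names(schedule$channels)
  budgets <- rep_len(optics$budget, length(chans))
  names(budgets) <- chans
  dim <- geometry$dim

  fractions <- sapply(chans, function(ch) evaluate_schedule(schedule, times, ch))
  fractions <- matrix(fractions, nrow = nt,
                      dimnames = list(NULL, chans))
  bleach <- (1 - optics$bleach_rate)^(seq_len(nt) - 1L)

  data <- list()
  per_focus <- list()
  with_local_seed(optics$seed, {
    for (ch in chans) {
      arr <- array(0, c(dim[1], dim[2], nt))
      bound_t <- fractions[, ch] * budgets[[ch]] * bleach
      diffuse_t <- budgets[[ch]] * bleach - bound_t
      bad <- which(diffuse_t < 0)
      if (length(bad))
        stopf("budget insufficient: diffuse pool negative at frame %d (channel %s)",
              bad[1], ch)
      pf <- outer(bound_t, geometry$weights)
      per_focus[[ch]] <- pf
      for (k in seq_len(nt)) {
        shift <- geometry$drift * (k - 1L)
        mask <- ellipse_mask(dim, geometry$center, geometry$semiaxes, shift)
        img <- matrix(optics$background, dim[1], dim[2])
        img[mask] <- img[mask] + diffuse_t[k] / sum(mask)
        if (geometry$n_foci > 0) {
          for (i in seq_len(geometry$n_foci)) {
            img <- add_gaussian(img,
                                geometry$foci[i, 1] + shift[1],
                                geometry$foci[i, 2] + shift[2],
                                geometry$focus_sigmas[i], pf[k, i])
          }
        }
        arr[, , k] <- img
      }
      arr <- apply_noise(arr, optics)
      data[[ch]] <- arr
    }
  })

  treat_frame <- which(times >= schedule$t_treat - 1e-9)[1]
  wash_frame <- if (is.na(schedule$t_washout)) NA_integer_ else
    which(times >= schedule$t_washout - 1e-9)[1]
  movie <- structure(list(data = data, channels = chans, times_min = times,
                          frame_interval_s = frame_interval_s,
                          t_treat_frame = treat_frame,
                          t_washout_frame = wash_frame),
                     class = "fork_movie")
  truth <- structure(list(schedule = schedule, geometry = geometry,
                          optics = optics, times_min = times,
                          fractions = fractions, per_focus = per_focus,
                          seed = optics$seed),
                     class = "fork_truth")
  list(movie = movie, truth = truth)
}

#' @export
print.fork_movie <- function(x, ...) {
  cat(sprintf("fork_movie: %d channel(s) [%s], %d frames of %dx%d px, %g s interval\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              length(x$times_min), dim(x$data[[1]])[1], dim(x$data[[1]])[2],
              x$frame_interval_s))
  invisible(x)
}
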