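# Single-focus tracking, 7x7 kymograms, and single-focus photometry.

#' Track a single focus through a movie
#'
#' Per frame, the focus center is the intensity-weighted centroid (after
#' local background subtraction) around the brightest pixel within
#' `search_radius` of the previous center. Frames whose peak does not rise
#' above the local background are flagged invalid and the track coasts at
#' the last valid position.
#'
#' @param movie a `fork_movie` (or a `ny x nx x T` array).
#' @param seed `c(x, y)` approximate focus position at the first frame,
#'   0-based pixels.
#' @param channel channel to track (movies only).
#' @param search_radius search radius around the previous center, pixels.
#' @param centroid_radius radius of the centroid window, pixels.
#' @param min_contrast required peak elevation over the local background,
#'   in local-noise SDs.
#' @return a `focus_track`: `centers` (`T x 2`, columns x, y, subpixel),
#'   `valid` flags, `search_radius`.
#' @export
track_focus <- function(movie, seed, channel = NULL, search_radius = 5,
                        centroid_radius = 5, min_contrast = 3) {
  arr <- if (inherits(movie, "fork_movie"))
    movie$data[[if (is.null(channel)) movie$channels[1] else channel]]
  else movie
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nt <- dim(arr)[3]
  if (seed[1] < 0 || seed[1] > nx - 1 || seed[2] < 0 || seed[2] > ny - 1)
    stopf("seed point (%.1f, %.1f) outside the image", seed[1], seed[2])
  centers <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("x", "y")))
  valid <- logical(nt)
  prev <- seed
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  for (k in seq_len(nt)) {
    fr <- arr[, , k]
    d2 <- outer((ys - prev[2])^2, (xs - prev[1])^2, `+`)
    sr <- d2 <= search_radius^2
    ann <- d2 >= (search_radius + 2)^2 & d2 <= (search_radius + 4)^2
    bg <- stats::median(fr[ann])
    noise <- stats::mad(fr[ann])
    pk <- arrayInd(which(sr)[which.max(fr[sr])], dim(fr))
    px <- xs[pk[2]]; py <- ys[pk[1]]
    if (fr[pk] - bg > min_contrast * max(noise, 1e-12)) {
      # background-subtracted centroid, one recentering pass
      ctr <- c(px, py)
      for (pass in 1:2) {
        w2 <- outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`) <= centroid_radius^2
        v <- pmax(fr - bg, 0) * w2
        s <- sum(v)
        if (s <= 0) break
        ctr <- c(sum(t(v) * xs) / s, sum(v * ys) / s)
      }
      centers[k, ] <- ctr
      valid[k] <- TRUE
      prev <- ctr
    } else {
      centers[k, ] <- prev
      valid[k] <- FALSE
    }
  }
  structure(list(centers = centers, valid = valid,
                 search_radius = search_radius), class = "focus_track")
}

#' Build a kymogram from a focus track
#'
#' Crops a 7x7 pixel window around the rounded focus center at every
#' frame and stitches the windows side by side. The local background per
#' frame is measured in a 1 px annulus at radius 5-6 px around the
#' (unrounded) center, or in an explicit region `L`.
#'
#' @param movie a `fork_movie` (or array).
#' @param track a `focus_track`.
#' @param channel channel (movies only).
#' @param background optional explicit background [roi] (region L); must
#'   not overlap the radius-3.5 measurement circle of any frame.
#' @param bg_radii annulus radii for the default local background.
#' @return a `kymogram`: `crops` (`7 x 7 x T`), `strip` (`7 x 7T`),
#'   `centers`, `offsets` (subpixel remainder of each center within its
#'   crop), `background` per frame, `radius` (3.5), `edge` flags for
#'   zero-padded frames, `valid` from the track.
#' @export
build_kymogram <- function(movie, track, channel = NULL,
                           background = NULL, bg_radii = c(5, 6)) {
  arr <- if (inherits(movie, "fork_movie"))
    movie$data[[if (is.null(channel)) movie$channels[1] else channel]]
  else movie
  stopifnot(inherits(track, "focus_track"))
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nt <- dim(arr)[3]
  stopifnot(nrow(track$centers) == nt)
  half <- 3L
  crops <- array(0, c(7L, 7L, nt))
  edge <- logical(nt)
  bgv <- numeric(nt)
  offsets <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("x", "y")))
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  if (!is.null(background)) {
    mL <- roi_mask(background, c(ny, nx))
    for (k in seq_len(nt)) {
      d2 <- outer((ys - track$centers[k, 2])^2,
                  (xs - track$centers[k, 1])^2, `+`)
      if (any(mL & d2 <= 3.5^2))
        stopf("background region L overlaps the measurement circle at frame %d", k)
    }
  }
  for (k in seq_len(nt)) {
    cx <- round(track$centers[k, 1]); cy <- round(track$centers[k, 2])
    offsets[k, ] <- c(track$centers[k, 1] - cx, track$centers[k, 2] - cy)
    rows <- (cy - half):(cy + half) + 1L
    cols <- (cx - half):(cx + half) + 1L
    rok <- rows >= 1L & rows <= ny
    cok <- cols >= 1L & cols <= nx
    edge[k] <- !(all(rok) && all(cok))
    crops[which(rok), which(cok), k] <- arr[rows[rok], cols[cok], k]
    if (is.null(background)) {
      d2 <- outer((ys - track$centers[k, 2])^2,
                  (xs - track$centers[k, 1])^2, `+`)
      ann <- d2 >= bg_radii[1]^2 & d2 <= bg_radii[2]^2
      bgv[k] <- mean(arr[, , k][ann])
    } else {
      bgv[k] <- mean(arr[, , k][mL])
    }
  }
  strip <- matrix(crops, nrow = 7L)
  structure(list(crops = crops, strip = strip, centers = track$centers,
                 offsets = offsets, background = bgv, radius = 3.5,
                 edge = edge, valid = track$valid), class = "kymogram")
}

#' Single-focus intensity trace from a kymogram
#'
#' `Q_t` is the mean intensity inside the radius-3.5 px circle centered on
#' the (unrounded) focus center, minus the local background;
#' `nM_t = Q_t / max(moving average of Q_t, 5 frames)`.
#'
#' @param kym a `kymogram`.
#' @return list with `Q` and `nM` traces.
#' @export
focus_trace <- function(kym) {
  stopifnot(inherits(kym, "kymogram"))
  nt <- dim(kym$crops)[3]
  rel <- -3:3
  Q <- numeric(nt)
  for (k in seq_len(nt)) {
    d2 <- outer((rel - kym$offsets[k, 2])^2, (rel - kym$offsets[k, 1])^2, `+`)
    inside <- d2 <= kym$radius^2
    Q[k] <- mean(kym$crops[, , k][inside]) - kym$background[k]
  }
  nM <- Q / max(moving_average(Q, 5L))
  list(Q = Q, nM = nM)
}
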