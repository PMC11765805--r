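# Diffuse-pool photometry: raw ROI traces and the derived bound-protein
# quantities.
#
# The background-corrected mean intensity of foci-free nuclear regions
# (D_t) tracks the freely diffusing pool. Referencing it against a window
# where the whole pool is free (after focus dissolution for PCNA-like
# channels, before treatment for RPA-like channels) yields the bound
# intensity E_t = T_ref - D_t, its max-normalized form nE_t, and the bound
# fraction F_t = E_t / T_ref of the total nuclear pool.

#' Measure raw ROI traces
#'
#' Per-frame mean pixel intensity of the nucleus region A, each foci-free
#' region B, and the background region C, for every channel.
#'
#' @param movie a `fork_movie` (registered if it drifts).
#' @param rois an [roi_set()].
#' @return an object of class `raw_traces`: per channel, vectors `A` and
#'   `C` and a `T x nB` matrix `B`; plus `times_min`.
#' @export
measure_raw <- function(movie, rois) {
  stopifnot(inherits(movie, "fork_movie"), inherits(rois, "roi_set"))
  dim2 <- dim(movie$data[[1]])[1:2]
  masks <- validate_roi_set(rois, dim2)
  nt <- dim(movie$data[[1]])[3]
  out <- list()
  for (ch in movie$channels) {
    arr <- movie$data[[ch]]
    mean_in <- function(mask) {
      idx <- which(mask)
      vapply(seq_len(nt), function(k) {
        fr <- arr[, , k]
        mean(fr[idx])
      }, numeric(1))
    }
    out[[ch]] <- list(
      A = mean_in(masks$A),
      B = vapply(masks$B, mean_in, numeric(nt)),
      C = mean_in(masks$C))
    if (is.null(dim(out[[ch]]$B)))
      out[[ch]]$B <- matrix(out[[ch]]$B, nrow = nt)
  }
  structure(list(traces = out, channels = movie$channels,
                 times_min = movie$times_min,
                 t_treat_frame = movie$t_treat_frame,
                 t_washout_frame = movie$t_washout_frame),
            class = "raw_traces")
}

#' Default reference window for a channel type
#'
#' Decay-type channels (PCNA-like) use a post-dissolution window 10-15 min
#' after treatment, when foci have dissolved and the whole pool diffuses
#' freely; rise-type channels (RPA-like) use all frames before treatment.
#'
#' @param raw a `raw_traces` (or `fork_movie`) carrying frame times and the
#'   treatment frame.
#' @param type `"decay"` or `"rise"`.
#' @param offset_min for decay channels, window start/end in minutes after
#'   treatment (default `c(10, 15)`).
#' @return integer vector of frame indices.
#' @export
reference_frames <- function(raw, type = c("decay", "rise"),
                             offset_min = c(10, 15)) {
  type <- match.arg(type)
  t <- raw$times_min
  tf <- raw$t_treat_frame
  if (is.na(tf)) stopf("no treatment frame recorded")
  t_treat <- t[tf]
  idx <- if (type == "decay")
    which(t >= t_treat + offset_min[1] & t <= t_treat + offset_min[2])
  else
    which(t < t_treat)
  if (length(idx) < 3L)
    stopf("reference window has %d frames; need at least 3", length(idx))
  idx
}

#' Bound-protein trace from raw ROI means
#'
#' Computes, per frame: the background-corrected diffuse intensity
#' `D_t = mean(B)_t - mean(C)_t`; the total-pool reference `T_ref` as the
#' mean of `D_t` over the reference window (optionally scaled by
#' `pool_correction` to compensate residual bound protein in the
#' reference window); the bound intensity `E_t = T_ref - D_t`; the bound
#' fraction `F_t = E_t / T_ref`; and the max-normalized bound intensity
#' `nE_t = E_t / max(moving average of E_t, 5 frames)`. Negative `E_t`
#' values are retained so noise statistics stay unbiased.
#'
#' @param raw a `raw_traces`.
#' @param channel channel name.
#' @param reference integer vector of reference-window frame indices
#'   (>= 3 frames), e.g. from [reference_frames()].
#' @param pool_correction multiplicative correction on `T_ref` (default 1,
#'   i.e. the reference window is taken as the full pool).
#' @return an object of class `bound_trace` with fields `times_min`, `D`,
#'   `T_ref`, `E`, `nE`, `F`, `reference`, `channel`.
#' @export
bound_trace <- function(raw, channel, reference, pool_correction = 1) {
  stopifnot(inherits(raw, "raw_traces"))
  if (!channel %in% raw$channels)
    stopf("unknown channel '%s'", channel)
  tr <- raw$traces[[channel]]
  nt <- length(tr$C)
  reference <- as.integer(reference)
  if (length(reference) < 3L)
    stopf("reference window must span at least 3 frames")
  if (any(reference < 1L | reference > nt))
    stopf("reference window outside the trace (1..%d)", nt)
  D <- rowMeans(tr$B) - tr$C
  T_ref <- mean(D[reference]) * pool_correction
  if (!is.finite(T_ref) || T_ref <= 0)
    stopf("reference intensity T_ref <= 0: background exceeds signal")
  E <- T_ref - D
  F_t <- E / T_ref
  nE <- E / max(moving_average(E, 5L))
  structure(list(times_min = raw$times_min, channel = channel,
                 D = D, T_ref = T_ref, E = E, nE = nE, F = F_t,
                 reference = reference, pool_correction = pool_correction,
                 t_treat_frame = raw$t_treat_frame,
                 t_washout_frame = raw$t_washout_frame),
            class = "bound_trace")
}

#' Aggregate bound traces across cells
#'
#' Aligns traces on their treatment frame and returns the per-frame mean,
#' SD and cell count of the bound fraction (or any chosen field). Frames
#' missing at trace edges are excluded per frame.
#'
#' @param traces list of `bound_trace` objects.
#' @param field which per-frame field to aggregate (default `"F"`).
#' @return data.frame with `frame_rel` (frames relative to treatment),
#'   `time_rel_min`, `mean`, `sd`, `n`.
#' @export
aggregate_cells <- function(traces, field = c("F", "E", "nE", "D")) {
  field <- match.arg(field)
  if (length(traces) == 0L) stopf("no traces to aggregate")
  stopifnot(all(vapply(traces, inherits, logical(1), "bound_trace")))
  tf <- vapply(traces, function(x) as.integer(x$t_treat_frame), integer(1))
  if (any(is.na(tf))) tf[is.na(tf)] <- 1L
  rel_lo <- min(1L - tf)
  rel_hi <- max(vapply(traces, function(x) length(x$D), integer(1)) - tf)
  rel <- rel_lo:rel_hi
  m <- matrix(NA_real_, length(rel), length(traces))
  for (j in seq_along(traces)) {
    v <- traces[[j]][[field]]
    idx <- seq_along(v) - tf[j]
    m[match(idx, rel), j] <- v
  }
  dt <- stats::median(diff(traces[[1]]$times_min))
  n_frame <- rowSums(!is.na(m))
  sd_frame <- apply(m, 1, stats::sd, na.rm = TRUE)
  sd_frame[n_frame == 1L] <- 0
  data.frame(frame_rel = rel,
             time_rel_min = rel * dt,
             mean = rowMeans(m, na.rm = TRUE),
             sd = sd_frame,
             n = n_frame)
}

#' Tidy export of bound traces
#'
#' One row per (cell, channel, frame) with the derived photometry columns.
#'
#' @param traces named list (cell id -> list of `bound_trace` per channel),
#'   or a flat list of `bound_trace`s with `cell_ids`.
#' @return data.frame with columns `cell_id`, `channel`, `frame`,
#'   `time_min`, `D_t`, `E_t`, `nE_t`, `F_t`.
#' @export
tidy_traces <- function(traces) {
  rows <- list()
  for (cell in names(traces)) {
    for (tr in traces[[cell]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell, channel = tr$channel,
        frame = seq_along(tr$D), time_min = tr$times_min,
        D_t = tr$D, E_t = tr$E, nE_t = tr$nE, F_t = tr$F)
    }
  }
  do.call(rbind, rows)
}
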