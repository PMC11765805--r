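# Exponential half-time fitting and rate estimation for stalling/restart
# traces.

new_kinetic_fit <- function(model, a, r, k, window, r2, fit) {
  structure(list(model = model, amplitude = a, residual = r, k = k,
                 t_half = log(2) / k, window = window, r2 = r2,
                 fit = fit), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit (%s): t1/2 = %.3g min, k = %.3g /min, R2 = %.3f\n",
              x$model, x$t_half, x$k, x$r2))
  invisible(x)
}

fit_exp <- function(time, y, window, model) {
  if (is.null(window)) window <- seq_along(time)
  window <- as.integer(window)
  if (length(window) < 6L)
    stopf("fit window has %d points; need at least 6", length(window))
  t <- time[window]; yy <- y[window]
  t0 <- t[1]
  if (stats::sd(yy) == 0) {
    # flat trace: rate unidentifiable; flag via r2 rather than fail
    return(new_kinetic_fit(model, yy[1], yy[1], NA_real_, window,
                           -Inf, NULL))
  }
  y1 <- mean(utils::head(yy, 3)); y2 <- mean(utils::tail(yy, 3))
  # crude initial rate from the half-crossing of the endpoint levels
  mid <- (y1 + y2) / 2
  cross <- if (model == "decay") which(yy <= mid)[1] else which(yy >= mid)[1]
  k0 <- if (!is.na(cross) && t[cross] > t0) log(2) / (t[cross] - t0)
        else 1 / max(diff(range(t)), 1e-6)
  df <- data.frame(t = t - t0, y = yy)
  fit <- tryCatch({
    if (model == "decay")
      minpack.lm::nlsLM(y ~ r + (a - r) * exp(-k * t), data = df,
                        start = list(a = y1, r = y2, k = max(k0, 1e-6)),
                        lower = c(a = -Inf, r = -Inf, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ b + a * (1 - exp(-k * t)), data = df,
                        start = list(a = y2 - y1, b = y1, k = max(k0, 1e-6)),
                        lower = c(a = -Inf, b = -Inf, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) {
    stopf("exponential fit did not converge (%s); starting values a=%.3g r=%.3g k=%.3g; residual range %.3g",
          conditionMessage(e), y1, y2, k0, diff(range(yy)))
  })
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((yy - mean(yy))^2)
  r2 <- if (tss > 0) 1 - rss / tss else -Inf
  if (model == "decay")
    new_kinetic_fit("decay", cf[["a"]], cf[["r"]], cf[["k"]], window, r2, fit)
  else
    new_kinetic_fit("rise", cf[["a"]] + cf[["b"]], cf[["b"]], cf[["k"]],
                    window, r2, fit)
}

#' Fit an exponential decay (focus dissolution)
#'
#' Least-squares fit of `y(t) = r + (a - r) * exp(-k (t - t0))` over the
#' window, with `t0` the window start (normally the treatment frame).
#' Returns the rate `k` (1/min) and half-time `t1/2 = ln 2 / k`.
#'
#' @param time frame times, minutes.
#' @param y trace (bound fraction, complexes per fork, ...).
#' @param window integer frame indices of the fit window (>= 6 points);
#'   `NULL` uses the whole trace.
#' @return a `kinetic_fit` object. A flat trace yields an unstable `k`
#'   flagged by `r2` near 0.
#' @export
fit_decay <- function(time, y, window = NULL) fit_exp(time, y, window, "decay")

#' Fit a saturating exponential rise (accumulation)
#'
#' As [fit_decay()] with `y(t) = b + a * (1 - exp(-k (t - t0)))`.
#'
#' @inheritParams fit_decay
#' @return a `kinetic_fit` object.
#' @export
fit_rise <- function(time, y, window = NULL) fit_exp(time, y, window, "rise")

#' Accumulation/removal rate of a complexes-per-fork trace
#'
#' Three conventions, all reported in trace units per minute with sign
#' (negative = removal):
#' `"onset-halfmax"` (default): linear-regression slope from the window
#' start until the trace first crosses halfway between its starting level
#' and its extreme; `"mean"`: net level change divided by elapsed time;
#' `"max-window"`: steepest sliding-window regression slope
#' (`slide` frames wide).
#'
#' @param time frame times, minutes.
#' @param y trace (e.g. `G_t` complexes per fork).
#' @param window integer frame indices (>= 3; `NULL` = whole trace).
#' @param mode rate convention.
#' @param slide sliding window width in frames for `"max-window"`.
#' @return list with `rate`, `mode`, and the frame `window` actually used.
#' @export
estimate_rate <- function(time, y, window = NULL,
                          mode = c("onset-halfmax", "mean", "max-window"),
                          slide = 5L) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- seq_along(time)
  window <- as.integer(window)
  if (length(window) < 3L) stopf("rate window must span at least 3 frames")
  t <- time[window]; yy <- y[window]
  slope <- function(i) {
    if (length(i) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(yy[i] ~ t[i]))[2])
  }
  res <- switch(mode,
    "mean" = (yy[length(yy)] - yy[1]) / (t[length(t)] - t[1]),
    "onset-halfmax" = {
      extreme <- if (abs(max(yy) - yy[1]) >= abs(min(yy) - yy[1]))
        max(yy) else min(yy)
      half <- (yy[1] + extreme) / 2
      idx <- if (extreme >= yy[1]) which(yy >= half)[1] else which(yy <= half)[1]
      if (is.na(idx) || idx < 3L) idx <- length(yy)
      slope(seq_len(idx))
    },
    "max-window" = {
      if (length(yy) < slide) stopf("trace shorter than the sliding window")
      sl <- vapply(seq_len(length(yy) - slide + 1L),
                   function(i) slope(i:(i + slide - 1L)), numeric(1))
      sl[which.max(abs(sl))]
    })
  list(rate = res, mode = mode, window = window)
}

#' Detect the plateau onset of a trace
#'
#' Earliest time after which the 5-frame moving average stays within
#' `tolerance` (as a fraction of the dynamic range) of its final level for
#' at least `min_span` minutes.
#'
#' @param time frame times, minutes.
#' @param y trace.
#' @param tolerance fraction of the dynamic range (default 0.05).
#' @param min_span minimum plateau duration, minutes (default 5).
#' @return plateau onset time in minutes, or `NA` when there is none.
#' @export
detect_plateau <- function(time, y, tolerance = 0.05, min_span = 5) {
  sm <- moving_average(y, 5L)
  final <- mean(utils::tail(sm, 5L))
  dr <- diff(range(sm))
  if (dr == 0) return(time[1])
  ok <- abs(sm - final) <= tolerance * dr
  # length of the trailing run where `ok` holds through the end
  run <- sum(cumprod(rev(ok)))
  if (run == 0L) return(NA_real_)
  onset <- length(ok) - run + 1L
  if (time[length(time)] - time[onset] < min_span) return(NA_real_)
  time[onset]
}
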