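# FRAP analysis: normalization chain, two-component decomposition into
# diffusing / bound / immobile fractions, bound-only recovery, and
# exchange-rate conversion.

#' Measure FRAP ROI traces from a movie
#'
#' Mean intensity inside a radius-`radius` circle at the bleached and the
#' reference (unbleached) focus, the nucleus mean, and the extracellular
#' background, per frame.
#'
#' @param movie a `fork_movie` from [render_frap_movie()] (or real data in
#'   the same layout); must carry `bleach_frame`.
#' @param geometry the [scene_geometry()] giving the two focus positions
#'   and the nucleus ellipse.
#' @param channel channel to measure.
#' @param radius measurement circle radius, pixels.
#' @return a `frap_record`: times (s), traces `bleached`, `unbleached`,
#'   `nucleus`, `background`, and `bleach_frame`.
#' @export
frap_traces <- function(movie, geometry, channel = movie$channels[1],
                        radius = 3.5) {
  stopifnot(inherits(movie, "fork_movie"), inherits(geometry, "scene_geometry"))
  if (is.null(movie$bleach_frame) || is.na(movie$bleach_frame))
    stopf("movie has no bleach frame recorded")
  dim2 <- geometry$dim
  circ <- function(p) roi_mask(roi_annulus(p, 0, radius), dim2)
  m_bl <- circ(geometry$foci[1, ])
  m_un <- circ(geometry$foci[2, ])
  m_nuc <- ellipse_mask(dim2, geometry$center, geometry$semiaxes)
  bg_side <- max(6, floor(min(geometry$center - geometry$semiaxes) - 2))
  m_bg <- roi_mask(roi_rect(0, 0, bg_side, bg_side), dim2)
  arr <- movie$data[[channel]]
  nt <- dim(arr)[3]
  mean_in <- function(m) vapply(seq_len(nt),
                                function(k) mean(arr[, , k][m]), numeric(1))
  structure(list(times_s = if (!is.null(movie$times_s)) movie$times_s
                           else movie$times_min * 60,
                 bleached = mean_in(m_bl), unbleached = mean_in(m_un),
                 nucleus = mean_in(m_nuc), background = mean_in(m_bg),
                 bleach_frame = movie$bleach_frame),
            class = "frap_record")
}

#' Normalize a FRAP record
#'
#' The four-step chain: (a) subtract the background from both focus
#' traces; (b) normalize each focus trace so its mean over the six frames
#' before the bleach is 1; (c) divide the bleached by the unbleached trace,
#' canceling acquisition photobleaching; (d) affine-map the ratio so the
#' first post-bleach value is exactly 0 and the pre-bleach mean is exactly
#' 1.
#'
#' @param record a `frap_record` (or a list with fields `times_s`,
#'   `bleached`, `unbleached`, `background`, `bleach_frame`).
#' @return a `frap_curve`: `times_s`, `t_post_s` (seconds since bleach,
#'   0 at the bleach frame), normalized `value`, `bleach_frame`,
#'   `pre_frames`, and `degenerate` (TRUE when no bleach depth was
#'   detectable, with a warning).
#' @export
normalize_frap <- function(record) {
  bf <- record$bleach_frame
  if (is.null(bf) || bf < 7L)
    stopf("need at least 6 pre-bleach frames (bleach frame is %s)",
          if (is.null(bf)) "missing" else bf)
  n <- length(record$bleached)
  if (length(record$unbleached) != n || anyNA(record$unbleached))
    stopf("unbleached reference focus trace missing or incomplete")
  pre <- (bf - 6L):(bf - 1L)
  bl <- record$bleached - record$background
  un <- record$unbleached - record$background
  if (any(un == 0)) stopf("unbleached trace hits zero after background subtraction")
  bl <- bl / mean(bl[pre])
  un <- un / mean(un[pre])
  r <- bl / un
  m_pre <- mean(r[pre])
  degenerate <- FALSE
  denom <- m_pre - r[bf]
  if (abs(denom) < 1e-9) {
    warnf("no detectable bleach depth: normalization is degenerate")
    degenerate <- TRUE
    y <- r
  } else {
    y <- (r - r[bf]) / denom
  }
  structure(list(times_s = record$times_s,
                 t_post_s = record$times_s - record$times_s[bf],
                 value = y, bleach_frame = bf, pre_frames = pre,
                 degenerate = degenerate),
            class = "frap_curve")
}

#' Two-component FRAP fit
#'
#' Fits `A_f (1 - exp(-k_f t)) + A_s (1 - exp(-k_s t))` to the post-bleach
#' part of a normalized curve. A single-component model is fitted first;
#' the two-component model is kept only when it reduces the residual sum
#' of squares by at least 5% AND satisfies the identifiability constraint
#' `k_f >= 10 k_s` with non-negative amplitudes summing to at most 1.
#' Otherwise the single-component fallback is returned (`A_s = 0`,
#' `k_s = NA`), which covers single-step recovery.
#'
#' @param curve a `frap_curve` from [normalize_frap()].
#' @return a `frap_fit`: `model` ("two" or "single"), `A_f`, `k_f`, `A_s`,
#'   `k_s`, `immobile = 1 - A_f - A_s`, `t_half_fast`, `t_half_slow`
#'   (ln 2 / k_s for two-component fits, ln 2 / k_f for single), `rss`.
#' @export
fit_two_component <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  if (isTRUE(curve$degenerate)) stopf("cannot fit a degenerate FRAP curve")
  post <- curve$t_post_s >= 0
  t <- curve$t_post_s[post]; y <- curve$value[post]
  plateau <- mean(utils::tail(y, max(3L, length(y) %/% 10L)))
  k0 <- {
    half <- plateau / 2
    i <- which(y >= half)[1]
    if (!is.na(i) && t[i] > 0) log(2) / t[i] else 1 / max(t)
  }
  df <- data.frame(t = t, y = y)
  single <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = df,
                      start = list(A = min(plateau, 1), k = k0),
                      lower = c(A = 0, k = 1e-8)),
    error = function(e) NULL)
  two <- tryCatch(
    minpack.lm::nlsLM(y ~ Af * (1 - exp(-kf * t)) + As * (1 - exp(-ks * t)),
                      data = df,
                      start = list(Af = 0.6 * plateau, kf = max(k0 * 5, 1e-4),
                                   As = 0.4 * plateau, ks = max(k0 / 5, 1e-6)),
                      lower = c(Af = 0, kf = 1e-8, As = 0, ks = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(single) && is.null(two))
    stopf("FRAP fit failed under both models (plateau %.3g, k0 %.3g)",
          plateau, k0)
  rss1 <- if (is.null(single)) Inf else sum(stats::resid(single)^2)
  rss2 <- if (is.null(two)) Inf else sum(stats::resid(two)^2)
  use_two <- FALSE
  if (!is.null(two)) {
    cf <- stats::coef(two)
    # order components so kf is the fast one
    if (cf[["kf"]] < cf[["ks"]])
      cf <- c(Af = cf[["As"]], kf = cf[["ks"]], As = cf[["Af"]], ks = cf[["kf"]])
    use_two <- rss2 <= 0.95 * rss1 &&
      cf[["kf"]] >= 10 * cf[["ks"]] &&
      cf[["Af"]] + cf[["As"]] <= 1 + 1e-6 &&
      cf[["As"]] > 1e-4
  }
  if (use_two) {
    structure(list(model = "two", A_f = cf[["Af"]], k_f = cf[["kf"]],
                   A_s = cf[["As"]], k_s = cf[["ks"]],
                   immobile = max(0, 1 - cf[["Af"]] - cf[["As"]]),
                   t_half_fast = log(2) / cf[["kf"]],
                   t_half_slow = log(2) / cf[["ks"]],
                   rss = rss2), class = "frap_fit")
  } else {
    if (is.null(single))
      stopf("two-component fit rejected and single-component fit failed")
    cf <- stats::coef(single)
    structure(list(model = "single", A_f = cf[["A"]], k_f = cf[["k"]],
                   A_s = 0, k_s = NA_real_,
                   immobile = max(0, 1 - cf[["A"]]),
                   t_half_fast = log(2) / cf[["k"]],
                   t_half_slow = log(2) / cf[["k"]],
                   rss = rss1), class = "frap_fit")
  }
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap_fit (%s): A_f=%.3f (t1/2 %.3g s), A_s=%.3f (t1/2 %.3g s), immobile=%.3f\n",
    x$model, x$A_f, x$t_half_fast, x$A_s,
    if (x$model == "two") x$t_half_slow else NA, x$immobile))
  invisible(x)
}

#' Bound-only recovery curve
#'
#' Subtracts the fitted fast (diffusing) component from the normalized
#' curve and renormalizes by `1 - A_f`, leaving the recovery of the
#' fork-bound pool; its half-time is `ln 2 / k_s`.
#'
#' @param curve a `frap_curve`.
#' @param fit a two-component `frap_fit`.
#' @return list with `t_post_s`, `value` (bound-normalized recovery) and
#'   `t_half_bound` (s).
#' @export
bound_recovery <- function(curve, fit) {
  stopifnot(inherits(curve, "frap_curve"), inherits(fit, "frap_fit"))
  if (fit$model != "two")
    stopf("bound_recovery needs a two-component fit")
  if (fit$A_f >= 1) stopf("A_f >= 1: no bound pool left after subtraction")
  post <- curve$t_post_s >= 0
  t <- curve$t_post_s[post]
  fast <- fit$A_f * (1 - exp(-fit$k_f * t))
  val <- (curve$value[post] - fast) / (1 - fit$A_f)
  list(t_post_s = t, value = val, t_half_bound = log(2) / fit$k_s)
}

#' Complexes exchanged within a time window after the bleach
#'
#' Multiplies the recovery gained over `[0, window]` seconds of the
#' (bound-normalized) curve by the number of complexes present at the
#' focus, and converts to an exchange rate per minute.
#'
#' @param recovery list with `t_post_s` and `value` (from
#'   [bound_recovery()], or a `frap_curve` for single-step channels).
#' @param n_bound complexes bound at the focus right before the bleach.
#' @param window window length, seconds (9 s suits fast RPA-like exchange,
#'   60 s slow PCNA-like exchange).
#' @return list with `complexes` exchanged in the window and
#'   `rate_per_min`.
#' @export
#' @examples
#' # 61.1 of ~81 bound complexes recovered in 9 s -> 407.5 per min
#' rec <- list(t_post_s = c(0, 9), value = c(0, 61.1 / 81))
#' exchange_rate(rec, n_bound = 81, window = 9)
exchange_rate <- function(recovery, n_bound, window) {
  stopifnot(n_bound > 0, window > 0)
  t <- if (!is.null(recovery$t_post_s)) recovery$t_post_s else recovery$times_s
  v <- recovery$value
  keep <- t >= 0
  t <- t[keep]; v <- v[keep]
  if (window > max(t)) stopf("window %.3g s beyond the data span %.3g s",
                             window, max(t))
  at <- function(tt) stats::approx(t, v, xout = tt, rule = 2)$y
  complexes <- n_bound * (at(window) - at(0))
  list(complexes = complexes, rate_per_min = complexes * 60 / window)
}
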