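# Piecewise-exponential kinetic schedules: the ground-truth bound-fraction
# trajectories followed by each channel of a synthetic stalling/restart movie.

#' Per-channel kinetic parameters
#'
#' Describes how the bound fraction of one channel (one tagged protein)
#' responds to nucleotide depletion and washout. Two channel types exist:
#' `"decay"` channels (PCNA-like: bound protein leaves foci when synthesis
#' stops) and `"rise"` channels (RPA-like: protein accumulates on the ssDNA
#' exposed at stalled forks).
#'
#' All trajectories are single exponentials parameterized by half-times, the
#' minimal form consistent with reported half-times and plateaus:
#' during stalling a decay channel follows
#' `f_res + (f0 - f_res) * 2^(-(t - t_HU)/t_half_stall)` and a rise channel
#' `f0 + (f_max - f0) * (1 - 2^(-(t - t_HU)/t_half_stall))`; after washout
#' each channel relaxes toward its restart plateau (`f0` for decay channels,
#' `f_post` for rise channels) with half-time `t_half_restart`.
#'
#' @param type `"decay"` or `"rise"`.
#' @param f0 baseline bound fraction (dimensionless, 0-1).
#' @param f_res residual bound fraction during stalling (decay channels;
#'   must not exceed `f0`).
#' @param f_max plateau bound fraction during stalling (rise channels).
#' @param t_half_stall stalling half-time, minutes.
#' @param t_half_restart restart half-time, minutes.
#' @param f_post post-restart residual bound fraction (rise channels; must
#'   not exceed `f_max`).
#' @return an object of class `channel_kinetics`.
#' @export
#' @examples
#' channel_kinetics("decay", f0 = 0.27, t_half_stall = 2.1)
channel_kinetics <- function(type = c("decay", "rise"), f0 = 0,
                             f_res = 0, f_max = 0, t_half_stall = 1,
                             t_half_restart = 1, f_post = 0) {
  type <- match.arg(type)
  for (v in c(f0 = f0, f_res = f_res, f_max = f_max, f_post = f_post)) {
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stopf("channel fractions must be single numbers in [0, 1]")
  }
  if (f_res > f0 + 1e-12)
    stopf("f_res (%.3g) must not exceed f0 (%.3g)", f_res, f0)
  if (f_post > max(f_max, f0) + 1e-12)
    stopf("f_post (%.3g) must not exceed the stalling plateau", f_post)
  if (!is_scalar_num(t_half_stall) || t_half_stall <= 0 ||
      !is_scalar_num(t_half_restart) || t_half_restart <= 0)
    stopf("half-times must be positive")
  structure(list(type = type, f0 = f0, f_res = f_res, f_max = f_max,
                 t_half_stall = t_half_stall,
                 t_half_restart = t_half_restart, f_post = f_post),
            class = "channel_kinetics")
}

#' Treatment schedule for a stalling/restart experiment
#'
#' Phase boundaries in minutes from the start of imaging: a drug-free
#' baseline, a treatment (stalling) phase starting at `t_treat`, and an
#' optional washout (restart) phase starting at `t_washout`. Defaults mirror
#' a 15 min baseline, 60 min hydroxyurea treatment and 45 min washout
#' acquisition.
#'
#' @param channels named list of [channel_kinetics()] objects.
#' @param t_treat treatment (drug addition) time, minutes.
#' @param t_washout washout time, minutes; `NA` for no washout phase.
#' @param t_end end of imaging, minutes.
#' @return an object of class `kinetic_schedule`.
#' @export
#' @examples
#' sched <- kinetic_schedule(
#'   channels = list(
#'     PCNA = channel_kinetics("decay", f0 = 0.27, t_half_stall = 2.1,
#'                             t_half_restart = 5.1),
#'     RPA1 = channel_kinetics("rise", f_max = 0.424, t_half_stall = 23.9,
#'                             t_half_restart = 2.5)))
#' evaluate_schedule(sched, c(0, 17.1, 75), "PCNA")
kinetic_schedule <- function(channels, t_treat = 15,
                             t_washout = t_treat + 60,
                             t_end = if (is.na(t_washout)) t_treat + 60
                                     else t_washout + 45) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stopf("`channels` must be a non-empty named list of channel_kinetics")
  if (!all(vapply(channels, inherits, logical(1), "channel_kinetics")))
    stopf("every channel must be a channel_kinetics object")
  bounds <- c(0, t_treat, if (!is.na(t_washout)) t_washout, t_end)
  if (any(diff(bounds) <= 0))
    stopf("phase boundaries must be strictly increasing (got %s)",
          paste(bounds, collapse = ", "))
  structure(list(channels = channels, t_treat = t_treat,
                 t_washout = t_washout, t_end = t_end),
            class = "kinetic_schedule")
}

#' Evaluate a kinetic schedule
#'
#' Closed-form ground-truth bound fraction of one channel at times `t`
#' (minutes from the start of imaging). Continuous across phase boundaries.
#'
#' @param schedule a [kinetic_schedule()].
#' @param t numeric vector of times in minutes; must lie in `[0, t_end]`.
#' @param channel channel name.
#' @return numeric vector of bound fractions in `[0, 1]`.
#' @export
evaluate_schedule <- function(schedule, t, channel) {
  stopifnot(inherits(schedule, "kinetic_schedule"))
  if (!channel %in% names(schedule$channels))
    stopf("unknown channel '%s' (have: %s)", channel,
          paste(names(schedule$channels), collapse = ", "))
  if (any(t < -1e-9 | t > schedule$t_end + 1e-9))
    stopf("t outside the movie span [0, %g] min", schedule$t_end)
  ch <- schedule$channels[[channel]]
  tH <- schedule$t_treat
  tW <- schedule$t_washout
  stall <- function(dt) {
    if (ch$type == "decay")
      ch$f_res + (ch$f0 - ch$f_res) * 2^(-dt / ch$t_half_stall)
    else
      ch$f0 + (ch$f_max - ch$f0) * (1 - 2^(-dt / ch$t_half_stall))
  }
  out <- rep(ch$f0, length(t))
  in_stall <- t >= tH & (is.na(tW) | t < tW)
  out[in_stall] <- stall(t[in_stall] - tH)
  if (!is.na(tW)) {
    post <- t >= tW
    if (any(post)) {
      v_w <- stall(tW - tH)
      target <- if (ch$type == "decay") ch$f0 else ch$f_post
      out[post] <- target + (v_w - target) * 2^(-(t[post] - tW) / ch$t_half_restart)
    }
  }
  out
}
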