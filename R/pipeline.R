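# End-to-end orchestration: canonical experimental conditions, batch
# simulation, the full quantification chain (registration -> ROI
# photometry -> stoichiometry -> kinetic fits), and config-driven
# commands with a reproducibility manifest.

#' Canonical channel kinetics for the standard conditions
#'
#' Parameter sets for hydroxyurea (HU) fork stalling with or without
#' checkpoint-kinase inhibition, expressed as [channel_kinetics()] for a
#' PCNA-like decay channel and an RPA1-like rise channel.
#'
#' Under HU alone the decay channel starts with 27% of the pool bound and
#' dissolves with a 2.1 min half-time; the rise channel accumulates with a
#' 23.9 min half-time toward an asymptote of 42.4% bound - the saturating
#' exponential that passes through 35% bound after 1 h of treatment and
#' levels off near 40% on longer treatments. Under ATR inhibition the rise
#' is four-fold faster (5.6 min) with a 70% plateau, and about 16% of the
#' peak persists after washout (52% under ATR+ATM co-inhibition).
#'
#' @param condition one of `"HU"`, `"HU+ATRi"`, `"HU+ATRi+ATMi"`.
#' @return named list of two [channel_kinetics()] (`PCNA`, `RPA1`).
#' @export
default_channels <- function(condition = c("HU", "HU+ATRi", "HU+ATRi+ATMi")) {
  condition <- match.arg(condition)
  pcna <- channel_kinetics("decay", f0 = 0.27, f_res = 0,
                           t_half_stall = 2.1, t_half_restart = 5.1)
  rpa <- switch(condition,
    "HU" = channel_kinetics("rise", f0 = 0, f_max = 0.424,
                            t_half_stall = 23.9, t_half_restart = 2.5,
                            f_post = 0),
    "HU+ATRi" = channel_kinetics("rise", f0 = 0, f_max = 0.70,
                                 t_half_stall = 5.6, t_half_restart = 2.5,
                                 f_post = 0.16 * 0.70),
    "HU+ATRi+ATMi" = channel_kinetics("rise", f0 = 0, f_max = 0.70,
                                      t_half_stall = 5.6,
                                      t_half_restart = 2.5,
                                      f_post = 0.52 * 0.70))
  list(PCNA = pcna, RPA1 = rpa)
}

#' Simulate a batch of single-cell stalling movies
#'
#' Renders `n_cells` movies that differ only in their noise / focus-layout
#' seeds (derived deterministically from `seed`).
#'
#' @param n_cells number of cells.
#' @param schedule a [kinetic_schedule()].
#' @param seed base seed; cell i uses `seed + i`.
#' @param dim image size.
#' @param n_foci foci per nucleus.
#' @param frame_interval_s frame interval, seconds.
#' @param optics_args extra arguments to [optics_noise()].
#' @param geometry_args extra arguments to [scene_geometry()].
#' @return list of `list(movie, truth)` per cell.
#' @export
simulate_batch <- function(n_cells, schedule, seed = 1L,
                           dim = c(128L, 128L), n_foci = 14L,
                           frame_interval_s = 30,
                           optics_args = list(), geometry_args = list()) {
  lapply(seq_len(n_cells), function(i) {
    geo <- do.call(scene_geometry,
                   c(list(dim = dim, n_foci = n_foci, seed = seed + i),
                     geometry_args))
    opt <- do.call(optics_noise,
                   c(list(seed = seed + 1000L + i), optics_args))
    render_movie(schedule, geo, opt, frame_interval_s = frame_interval_s)
  })
}

#' Quantify one cell movie end to end
#'
#' Registration (optional), raw ROI traces, bound traces per channel with
#' type-appropriate reference windows, stoichiometric conversion, and
#' kinetic fits over the treatment window (decay channels: [fit_decay()];
#' rise channels: [fit_rise()]).
#'
#' @param movie a `fork_movie`.
#' @param rois an [roi_set()].
#' @param channel_types named character vector mapping each channel to
#'   `"decay"` or `"rise"`.
#' @param constants a [stoich_constants()].
#' @param register estimate and correct drift first (default TRUE).
#' @param fit_window integer frame indices for the kinetic fit; `NULL`
#'   uses treatment to washout (or end).
#' @param reference_offsets decay-channel reference window, minutes after
#'   treatment.
#' @return list with `traces` (per-channel `bound_trace`), `fits`
#'   (per-channel `kinetic_fit`), `G` and `H` (complexes-per-fork and, for
#'   RPA-like channels, nt ssDNA per fork), `shifts`.
#' @export
quantify_movie <- function(movie, rois, channel_types,
                           constants = stoich_constants(),
                           register = TRUE, fit_window = NULL,
                           reference_offsets = c(10, 15)) {
  stopifnot(inherits(movie, "fork_movie"))
  missing_ch <- setdiff(movie$channels, names(channel_types))
  if (length(missing_ch))
    stopf("no channel type declared for: %s",
          paste(missing_ch, collapse = ", "))
  shifts <- NULL
  if (register) {
    reg <- register_movie(movie)
    movie <- reg$movie
    shifts <- reg$shifts
  }
  raw <- measure_raw(movie, rois)
  tf <- movie$t_treat_frame
  wf <- movie$t_washout_frame
  nt <- length(movie$times_min)
  if (is.null(fit_window))
    fit_window <- tf:(if (!is.na(wf)) wf - 1L else nt)
  traces <- list(); fits <- list(); G <- list(); H <- list()
  for (ch in movie$channels) {
    type <- match.arg(channel_types[[ch]], c("decay", "rise"))
    ref <- reference_frames(raw, type, offset_min = reference_offsets)
    tr <- bound_trace(raw, ch, ref)
    traces[[ch]] <- tr
    species <- if (type == "decay") "PCNA" else "RPA"
    G[[ch]] <- complexes_per_fork(pmax(tr$F, -0.05), constants, species)
    if (species == "RPA") H[[ch]] <- ssdna_per_fork(G[[ch]], constants)
    fits[[ch]] <- if (type == "decay")
      fit_decay(tr$times_min, tr$F, fit_window)
    else
      fit_rise(tr$times_min, tr$F, fit_window)
  }
  list(traces = traces, fits = fits, G = G, H = H, shifts = shifts)
}

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

schedule_from_config <- function(cfg) {
  chans <- lapply(cfg$channels, function(p) {
    do.call(channel_kinetics, p)
  })
  kinetic_schedule(chans,
                   t_treat = cfg$t_treat %||% 15,
                   t_washout = cfg$t_washout %||% NA,
                   t_end = cfg$t_end %||%
                     (if (is.na(cfg$t_washout %||% NA)) (cfg$t_treat %||% 15) + 60
                      else (cfg$t_washout) + 45))
}

write_manifest <- function(dir, command, config, seed) {
  manifest <- list(command = command,
                   run_id = format(Sys.time(), "%Y%m%d-%H%M%S"),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("replifork")),
                   config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Config-driven commands
#'
#' `run_simulate()` renders a batch of stalling movies and writes, per
#' cell, channel TIFFs, a ground-truth sidecar + CSV, and an ROI JSON
#' (foci-free regions chosen from the scene geometry); `run_quantify()`
#' reads them back, runs the full quantification, and writes a tidy trace
#' CSV plus a fit-summary JSON; `run_frap()` simulates (or reads) FRAP
#' records, fits them, and writes per-record fit JSON and normalized-curve
#' CSVs. Each writes a `manifest.json` with the seed and configuration.
#'
#' @param config a list, or path to a YAML/JSON file. Common fields:
#'   `out_dir`, `seed`, `n_cells`; `run_simulate()` also takes `schedule`
#'   (`t_treat`, `t_washout`, `t_end`, `channels`), `frame_interval_s`,
#'   `dim`, `n_foci`, `optics`; `run_quantify()` takes `in_dir`,
#'   `channel_types`; `run_frap()` takes `frap` parameters
#'   ([frap_kinetics()] fields), `n_records`.
#' @return `run_simulate()`: output dir (invisibly); `run_quantify()`:
#'   the summary list; `run_frap()`: list of fit records.
#' @name commands
#' @export
run_simulate <- function(config) {
  cfg <- read_config(config)
  out <- cfg$out_dir %||% stopf("config needs out_dir")
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out)
  seed <- cfg$seed %||% 1L
  sched <- if (!is.null(cfg$schedule)) schedule_from_config(cfg$schedule)
           else kinetic_schedule(default_channels("HU"))
  n <- cfg$n_cells %||% 1L
  batch <- simulate_batch(
    n, sched, seed = seed,
    dim = unlist(cfg$dim %||% c(96L, 96L)),
    n_foci = cfg$n_foci %||% 14L,
    frame_interval_s = cfg$frame_interval_s %||% 30,
    optics_args = cfg$optics %||% list())
  for (i in seq_len(n)) {
    prefix <- sprintf("cell%02d", i)
    write_movie(batch[[i]]$movie, out, prefix, truth = batch[[i]]$truth)
    rois <- roi_set_from_geometry(batch[[i]]$truth$geometry)
    write_roi_set(rois, file.path(out, sprintf("%s_rois.json", prefix)))
  }
  write_manifest(out, "simulate", cfg, seed)
  invisible(out)
}

#' @rdname commands
#' @export
run_quantify <- function(config) {
  cfg <- read_config(config)
  ind <- cfg$in_dir %||% stopf("config needs in_dir")
  out <- cfg$out_dir %||% ind
  sidecars <- sort(list.files(ind, pattern = "_sidecar\\.json$"))
  if (length(sidecars) == 0L) stopf("no movies found in '%s'", ind)
  prefixes <- sub("_sidecar\\.json$", "", sidecars)
  channel_types <- unlist(cfg$channel_types %||%
                            c(PCNA = "decay", RPA1 = "rise"))
  results <- list()
  for (p in prefixes) {
    movie <- read_movie(ind, p)
    roi_path <- file.path(ind, sprintf("%s_rois.json", p))
    if (!file.exists(roi_path)) stopf("missing ROI JSON for cell '%s'", p)
    rois <- read_roi_set(roi_path)
    results[[p]] <- quantify_movie(movie, rois, channel_types,
                                   register = cfg$register %||% TRUE)
  }
  tidy <- tidy_traces(lapply(results, `[[`, "traces"))
  utils::write.csv(tidy, file.path(out, "traces.csv"), row.names = FALSE)
  summary <- list()
  for (ch in names(channel_types)) {
    th <- vapply(results, function(r) r$fits[[ch]]$t_half, numeric(1))
    summary[[ch]] <- list(channel = ch, type = channel_types[[ch]],
                          n_cells = length(th),
                          t_half_mean = mean(th), t_half_sd = stats::sd(th))
  }
  jsonlite::write_json(summary, file.path(out, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out, "quantify", cfg, cfg$seed %||% NA)
  invisible(list(results = results, tidy = tidy, summary = summary))
}

#' @rdname commands
#' @export
run_frap <- function(config) {
  cfg <- read_config(config)
  out <- cfg$out_dir %||% stopf("config needs out_dir")
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out)
  seed <- cfg$seed %||% 1L
  n <- cfg$n_records %||% 10L
  frap <- do.call(frap_kinetics, cfg$frap %||% list())
  fits <- list()
  for (i in seq_len(n)) {
    geo <- scene_geometry(dim = unlist(cfg$dim %||% c(96L, 96L)),
                          n_foci = cfg$n_foci %||% 6L, seed = seed + i)
    opt <- do.call(optics_noise,
                   c(list(seed = seed + 2000L + i), cfg$optics %||% list()))
    sim <- render_frap_movie(frap, geo, opt)
    rec <- frap_traces(sim$movie, geo)
    curve <- normalize_frap(rec)
    fit <- fit_two_component(curve)
    prefix <- sprintf("frap%02d", i)
    write_frap_csv(rec, file.path(out, sprintf("%s_traces.csv", prefix)))
    utils::write.csv(data.frame(t_post_s = curve$t_post_s,
                                value = curve$value),
                     file.path(out, sprintf("%s_curve.csv", prefix)),
                     row.names = FALSE)
    rec_fit <- unclass(fit)
    if (fit$model == "two") {
      br <- bound_recovery(curve, fit)
      rec_fit$t_half_bound <- br$t_half_bound
    }
    jsonlite::write_json(rec_fit, file.path(out, sprintf("%s_fit.json", prefix)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    fits[[prefix]] <- fit
  }
  th <- vapply(fits, `[[`, numeric(1), "t_half_slow")
  imm <- vapply(fits, `[[`, numeric(1), "immobile")
  report <- list(n_records = n,
                 t_half_mean = mean(th), t_half_sd = stats::sd(th),
                 immobile_mean = mean(imm), immobile_sd = stats::sd(imm))
  jsonlite::write_json(report, file.path(out, "frap_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out, "frap", cfg, seed)
  invisible(fits)
}
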