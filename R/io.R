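# File I/O: multi-page TIFF movies with JSON sidecars, ROI JSON, tidy
# trace CSV, and FRAP record CSV. All outputs round-trip through the
# package's own readers.

#' Write a movie (and its ground truth) to disk
#'
#' One multi-page 32-bit float TIFF per channel plus a JSON sidecar with
#' the calibration (frame interval, treatment frames, per-channel
#' intensity scaling), the scene geometry and, when given, the full ground
#' truth; true per-frame bound fractions additionally go to a CSV.
#'
#' @param movie a `fork_movie`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param truth optional `fork_truth` / `frap_truth`.
#' @return (invisibly) the sidecar path.
#' @export
write_movie <- function(movie, dir, prefix = "movie", truth = NULL) {
  stopifnot(inherits(movie, "fork_movie"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", dir)
  scaling <- list()
  for (ch in movie$channels) {
    arr <- movie$data[[ch]]
    off <- min(0, min(arr))
    sc <- max(arr - off)
    if (sc <= 0) sc <- 1
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) (arr[, , k] - off) / sc)
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                    bits.per.sample = 32L)
    scaling[[ch]] <- list(offset = off, scale = sc)
  }
  na_null <- function(x) if (is.null(x) || is.na(x)) NULL else x
  sidecar <- list(
    channels = as.list(movie$channels),
    n_frames = length(movie$times_min),
    frame_interval_s = movie$frame_interval_s,
    t_treat_frame = na_null(movie$t_treat_frame),
    t_washout_frame = na_null(movie$t_washout_frame),
    bleach_frame = na_null(movie$bleach_frame),
    scaling = scaling)
  if (!is.null(truth)) {
    sidecar$seed <- truth$seed
    sidecar$geometry <- unclass(truth$geometry)
    if (inherits(truth, "fork_truth")) {
      sched <- truth$schedule
      sidecar$schedule <- list(
        t_treat = sched$t_treat, t_washout = sched$t_washout,
        t_end = sched$t_end,
        channels = lapply(sched$channels, unclass))
      utils::write.csv(
        data.frame(frame = seq_along(truth$times_min),
                   time_min = truth$times_min,
                   truth$fractions, check.names = FALSE),
        file.path(dir, sprintf("%s_truth.csv", prefix)), row.names = FALSE)
    } else if (inherits(truth, "frap_truth")) {
      sidecar$frap <- unclass(truth$frap)
    }
  }
  path <- file.path(dir, sprintf("%s_sidecar.json", prefix))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir directory holding the TIFFs and sidecar.
#' @param prefix file-name prefix used at writing.
#' @return a `fork_movie` with an extra `sidecar` field.
#' @export
read_movie <- function(dir, prefix = "movie") {
  path <- file.path(dir, sprintf("%s_sidecar.json", prefix))
  if (!file.exists(path)) stopf("no sidecar found at '%s'", path)
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  chans <- as.character(sc$channels)
  data <- list()
  for (ch in chans) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                            all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    s <- sc$scaling[[ch]]
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * s$scale + s$offset
    data[[ch]] <- arr
  }
  nt <- sc$n_frames
  times <- (seq_len(nt) - 1L) * sc$frame_interval_s / 60
  structure(list(data = data, channels = chans, times_min = times,
                 times_s = times * 60,
                 frame_interval_s = sc$frame_interval_s,
                 t_treat_frame = if (is.null(sc$t_treat_frame)) NA_integer_
                                 else sc$t_treat_frame,
                 t_washout_frame = if (is.null(sc$t_washout_frame))
                   NA_integer_ else sc$t_washout_frame,
                 bleach_frame = if (is.null(sc$bleach_frame)) NA_integer_
                                else sc$bleach_frame,
                 sidecar = sc),
            class = "fork_movie")
}

roi_to_list <- function(roi) unclass(roi)

list_to_roi <- function(x) {
  switch(x$type,
    ellipse = roi_ellipse(unlist(x$center), unlist(x$semiaxes)),
    rect = roi_rect(x$xmin, x$ymin, x$xmax, x$ymax),
    polygon = roi_polygon(matrix(unlist(x$vertices), ncol = 2)),
    annulus = roi_annulus(unlist(x$center), x$r_inner, x$r_outer),
    stopf("unknown roi type '%s'", x$type))
}

#' Write / read an ROI set as JSON
#'
#' Named regions with 0-based pixel coordinates.
#'
#' @param rois an [roi_set()].
#' @param path JSON file path.
#' @return `read_roi_set()` returns an [roi_set()]; `write_roi_set()` the
#'   path, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  obj <- list(A = roi_to_list(rois$A),
              B = lapply(rois$B, roi_to_list),
              C = roi_to_list(rois$C))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  roi_set(list_to_roi(x$A), lapply(x$B, list_to_roi), list_to_roi(x$C))
}

#' Write / read a FRAP record CSV
#'
#' Columns `time_s`, `bleached`, `unbleached`, `nucleus`, `background`;
#' the bleach frame index travels in the config (or is supplied on read).
#'
#' @param record a `frap_record`.
#' @param path CSV path.
#' @param bleach_frame bleach frame index (1-based) when reading.
#' @return `read_frap_csv()` returns a `frap_record`.
#' @export
write_frap_csv <- function(record, path) {
  utils::write.csv(
    data.frame(time_s = record$times_s, bleached = record$bleached,
               unbleached = record$unbleached,
               nucleus = record$nucleus %||% NA_real_,
               background = record$background),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path, bleach_frame) {
  df <- utils::read.csv(path)
  structure(list(times_s = df$time_s, bleached = df$bleached,
                 unbleached = df$unbleached, nucleus = df$nucleus,
                 background = df$background,
                 bleach_frame = as.integer(bleach_frame)),
            class = "frap_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
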