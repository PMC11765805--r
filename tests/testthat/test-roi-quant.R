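make_ellipse_image <- function(dim, centers, semiaxes = c(14, 10),
                               value = 1) {
  img <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    img[replifork:::ellipse_mask(dim, centers[i, ], semiaxes)] <- value
  }
  img
}

test_that("segment_nuclei labels bright nuclei and rejects degenerate input", {
  one <- make_ellipse_image(c(80, 80), rbind(c(40, 40)))
  lab1 <- segment_nuclei(one, min_area = 100)
  expect_equal(max(lab1), 1)
  expect_gt(sum(lab1 == 1 & one > 0) / sum(one > 0), 0.9)

  two <- make_ellipse_image(c(80, 120), rbind(c(30, 40), c(90, 40)))
  expect_equal(max(segment_nuclei(two, min_area = 100)), 2)

  expect_warning(lab0 <- segment_nuclei(matrix(5, 60, 60), min_area = 50),
                 "constant|no connected")
  expect_equal(max(lab0), 0)
})

test_that("registration recovers known drift to subpixel accuracy", {
  # static content: baseline-only movie drifting (1, 0.5) px/frame
  geo <- scene_geometry(dim = c(96L, 96L), n_foci = 8L, seed = 3L,
                        drift = c(1, 0.5))
  sched <- kinetic_schedule(
    list(P = channel_kinetics("decay", f0 = 0.27, t_half_stall = 2.1)),
    t_treat = 14, t_washout = NA, t_end = 15)
  sim <- render_movie(sched, geo, quiet_optics(), frame_interval_s = 60)
  reg <- register_translation(sim$movie$data$P)
  nt <- length(sim$movie$times_min)
  truth <- cbind(dx = (0:(nt - 1)) * 1, dy = (0:(nt - 1)) * 0.5)
  expect_lt(max(abs(reg$shifts[1:14, ] - truth[1:14, ])), 0.1)

  # identical frames: all shifts zero
  st <- array(rep(sim$movie$data$P[, , 1], 3), c(96, 96, 3))
  expect_equal(register_translation(st)$shifts,
               matrix(0, 3, 2, dimnames = list(NULL, c("dx", "dy"))))
  # single frame: no-op
  one <- array(sim$movie$data$P[, , 1], c(96, 96, 1))
  expect_identical(register_translation(one)$corrected, one)
  # flat frames: warning, zero shift
  flat <- array(1, c(32, 32, 2))
  expect_warning(r <- register_translation(flat), "ambiguous")
  expect_equal(r$shifts[2, ], c(dx = 0, dy = 0))
})

test_that("measure_raw reproduces region means and the background offset", {
  nf <- noise_free_sim()
  movie <- nf$sim$movie
  rois <- roi_set_from_geometry(nf$geometry)
  raw <- measure_raw(movie, rois)
  opt <- quiet_optics()
  # C tracks the camera offset exactly (noise-free)
  expect_equal(raw$traces$PCNA$C, rep(opt$background, length(raw$times_min)))
  # B tracks diffuse density + background
  mask <- replifork:::ellipse_mask(nf$geometry$dim, nf$geometry$center,
                                   nf$geometry$semiaxes)
  diffuse <- opt$budget * (1 - nf$sim$truth$fractions[, "PCNA"]) / sum(mask)
  expect_equal(rowMeans(raw$traces$PCNA$B), diffuse + opt$background,
               tolerance = 0.01)
  # uniform image: every ROI mean equals the pixel value
  uni <- movie
  for (ch in uni$channels) uni$data[[ch]][] <- 3.5
  raw_u <- measure_raw(uni, rois)
  expect_equal(unique(raw_u$traces$RPA1$A), 3.5)
  expect_equal(unique(as.vector(raw_u$traces$RPA1$B)), 3.5)
})

test_that("bound_trace implements the diffuse-pool formulas", {
  nf <- noise_free_sim()
  raw <- measure_raw(nf$sim$movie, roi_set_from_geometry(nf$geometry))
  trP <- bound_trace(raw, "PCNA", reference_frames(raw, "decay"))
  trR <- bound_trace(raw, "RPA1", reference_frames(raw, "rise"))
  # oracle equivalence on noise-free input: F_t within 1% absolute
  expect_lt(max(abs(trP$F - nf$sim$truth$fractions[, "PCNA"])), 0.01)
  expect_lt(max(abs(trR$F - nf$sim$truth$fractions[, "RPA1"])), 0.01)
  # algebraic closure: F_t * T_ref + D_t = T_ref
  expect_equal(trP$F * trP$T_ref + trP$D, rep(trP$T_ref, length(trP$D)))
  # E_t = T_ref - D_t
  expect_equal(trP$E, trP$T_ref - trP$D)
  # nE peaks at exactly 1 (plateau-shaped trace)
  expect_equal(max(trP$nE), 1)
  # pre-treatment and plateau levels
  tf <- nf$sim$movie$t_treat_frame
  expect_equal(mean(trP$F[1:(tf - 1)]), 0.27, tolerance = 0.02)
  expect_equal(mean(utils::tail(trR$F, 10)),
               mean(utils::tail(nf$sim$truth$fractions[, "RPA1"], 10)),
               tolerance = 0.01)
})

test_that("bound fraction is gain-invariant; nE is offset+gain invariant", {
  nf <- noise_free_sim()
  movie <- nf$sim$movie
  rois <- roi_set_from_geometry(nf$geometry)
  scaled <- movie
  for (ch in scaled$channels) scaled$data[[ch]] <- scaled$data[[ch]] * 3.7 + 11
  raw0 <- measure_raw(movie, rois)
  raw1 <- measure_raw(scaled, rois)
  tr0 <- bound_trace(raw0, "PCNA", reference_frames(raw0, "decay"))
  tr1 <- bound_trace(raw1, "PCNA", reference_frames(raw1, "decay"))
  expect_equal(tr1$F, tr0$F, tolerance = 1e-10)
  expect_equal(tr1$nE, tr0$nE, tolerance = 1e-10)
})

test_that("bound_trace and measure_raw reject invalid input", {
  nf <- noise_free_sim()
  raw <- measure_raw(nf$sim$movie, roi_set_from_geometry(nf$geometry))
  expect_error(bound_trace(raw, "PCNA", 1:2), "at least 3")
  expect_error(bound_trace(raw, "nope", 1:5), "unknown channel")
  # background >= signal: swap C and B levels via a doctored raw object
  bad <- raw
  bad$traces$PCNA$C <- bad$traces$PCNA$C + 1e6
  expect_error(bound_trace(bad, "PCNA", reference_frames(raw, "decay")),
               "background exceeds")
  # D_t constant => E = 0, F = 0
  flat <- raw
  flat$traces$PCNA$B[] <- 50
  flat$traces$PCNA$C[] <- 10
  trf <- bound_trace(flat, "PCNA", 1:10)
  expect_equal(unique(trf$E), 0)
  expect_equal(unique(trf$F), 0)
})

test_that("aggregate_cells aligns and averages traces", {
  nf <- noise_free_sim()
  raw <- measure_raw(nf$sim$movie, roi_set_from_geometry(nf$geometry))
  tr <- bound_trace(raw, "PCNA", reference_frames(raw, "decay"))
  one <- aggregate_cells(list(tr))
  expect_equal(one$mean, tr$F)
  expect_equal(unique(one$sd), 0)
  expect_equal(unique(one$n), 1)
  # mirrored traces average to zero
  tr2 <- tr
  tr2$F <- -tr$F
  two <- aggregate_cells(list(tr, tr2))
  expect_equal(two$mean, rep(0, nrow(two)))
  expect_equal(unique(two$n), 2)
  expect_error(aggregate_cells(list()), "no traces")
})
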