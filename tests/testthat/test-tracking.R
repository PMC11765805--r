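test_that("tracking locks onto stationary and drifting foci", {
  nf <- noise_free_sim()
  sp <- nf$geometry$foci[1, ]
  tk <- track_focus(nf$sim$movie, seed = sp + c(1, -1), channel = "PCNA")
  err <- sqrt(rowSums((tk$centers -
                         matrix(sp, nrow(tk$centers), 2, byrow = TRUE))^2))
  expect_lt(max(err[tk$valid]), 0.2)

  geo <- scene_geometry(dim = c(96L, 96L), n_foci = 3L, seed = 4L,
                        drift = c(0.5, 0.2))
  sched <- kinetic_schedule(
    list(P = channel_kinetics("decay", f0 = 0.27, t_half_stall = 2.1)),
    t_treat = 19, t_washout = NA, t_end = 20)
  sim <- render_movie(sched, geo, quiet_optics(), frame_interval_s = 60)
  tk2 <- track_focus(sim$movie, seed = geo$foci[1, ])
  nt <- nrow(tk2$centers)
  truth <- cbind(geo$foci[1, 1] + (0:(nt - 1)) * 0.5,
                 geo$foci[1, 2] + (0:(nt - 1)) * 0.2)
  expect_lt(max(sqrt(rowSums((tk2$centers - truth)^2))[tk2$valid]), 0.2)
  expect_error(track_focus(sim$movie, seed = c(500, 500)), "outside")
})

test_that("dissolving foci are flagged invalid once below the local noise", {
  geo <- small_geometry(n_foci = 6L, seed = 8L)
  sched <- kinetic_schedule(
    list(P = channel_kinetics("decay", f0 = 0.27, f_res = 0,
                              t_half_stall = 1)),
    t_treat = 3, t_washout = NA, t_end = 30)
  sim <- render_movie(sched, geo, noisy_optics(seed = 13),
                      frame_interval_s = 60)
  tk <- track_focus(sim$movie, seed = geo$foci[1, ])
  expect_true(all(tk$valid[1:3]))
  expect_false(any(tk$valid[25:31]))
  # track coasts at its last position
  last_valid <- max(which(tk$valid))
  expect_equal(tk$centers[31, ], tk$centers[last_valid, ])
})

test_that("kymograms are 7 px wide per frame and lossless in the interior", {
  nf <- noise_free_sim()
  tk <- track_focus(nf$sim$movie, seed = nf$geometry$foci[1, ],
                    channel = "PCNA")
  kym <- build_kymogram(nf$sim$movie, tk, channel = "PCNA")
  nt <- length(nf$sim$movie$times_min)
  expect_equal(dim(kym$strip), c(7L, 7L * nt))
  expect_false(any(kym$edge))
  # interior crops equal the corresponding movie pixels exactly
  k <- 5L
  cx <- round(tk$centers[k, 1]); cy <- round(tk$centers[k, 2])
  expect_identical(kym$crops[, , k],
                   nf$sim$movie$data$PCNA[(cy - 3):(cy + 3) + 1,
                                          (cx - 3):(cx + 3) + 1, k])
  # constant image: crops constant, Q identically zero
  flat <- nf$sim$movie
  flat$data$PCNA[] <- 4
  tkf <- suppressWarnings(track_focus(flat, seed = nf$geometry$foci[1, ],
                                      channel = "PCNA"))
  kf <- build_kymogram(flat, tkf, channel = "PCNA")
  expect_equal(unique(as.vector(kf$crops)), 4)
  expect_equal(unique(focus_trace(kf)$Q), 0)
})

test_that("single-focus photometry recapitulates the diffuse-pool kinetics", {
  nf <- noise_free_sim()
  movie <- nf$sim$movie
  tk <- track_focus(movie, seed = nf$geometry$foci[1, ], channel = "PCNA")
  kym <- build_kymogram(movie, tk, channel = "PCNA")
  ft <- focus_trace(kym)
  expect_equal(max(ft$nM), 1)
  # dissolution half-time read from one focus
  fit <- fit_decay(movie$times_min, ft$nM,
                   movie$t_treat_frame:length(ft$nM))
  expect_equal(fit$t_half, 2.1, tolerance = 0.05)
  # an explicit background region L overlapping the circle is rejected
  expect_error(
    build_kymogram(movie, tk, channel = "PCNA",
                   background = roi_annulus(nf$geometry$foci[1, ], 0, 3)),
    "overlaps")
})
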