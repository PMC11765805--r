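test_that("noise-free rendering conserves the nuclear pool", {
  nf <- noise_free_sim()
  opt <- quiet_optics()
  for (ch in c("PCNA", "RPA1")) {
    tot <- apply(nf$sim$movie$data[[ch]], 3, sum) -
      opt$background * prod(nf$geometry$dim)
    expect_lt(diff(range(tot)) / mean(tot), 1e-6)
  }
})

test_that("rendered focus mass equals its ground-truth bound amount", {
  # two separated foci whose +/-12 px windows stay inside the nucleus
  foci <- rbind(c(38, 48), c(58, 48))
  geo <- scene_geometry(dim = c(96L, 96L), n_foci = 2L, foci = foci)
  sim <- render_movie(hu_schedule(t_end = 16), geo, quiet_optics())
  opt <- quiet_optics()
  fr1 <- sim$movie$data$PCNA[, , 1]
  mask <- replifork:::ellipse_mask(geo$dim, geo$center, geo$semiaxes)
  diffuse_px <- (opt$budget * (1 - sim$truth$fractions[1, "PCNA"])) / sum(mask)
  for (i in 1:2) {
    ys <- (foci[i, 2] - 12):(foci[i, 2] + 12) + 1
    xs <- (foci[i, 1] - 12):(foci[i, 1] + 12) + 1
    win <- fr1[ys, xs]
    mass <- sum(win - opt$background - diffuse_px)
    expect_equal(mass, sim$truth$per_focus$PCNA[1, i], tolerance = 0.01)
  }
})

test_that("no foci and zero bound fraction give a flat nucleus", {
  geo <- scene_geometry(dim = c(64L, 64L), n_foci = 0L)
  sched <- kinetic_schedule(
    list(X = channel_kinetics("rise", f0 = 0, f_max = 0, t_half_stall = 5)),
    t_treat = 2, t_washout = NA, t_end = 3)
  opt <- quiet_optics(budget = 1e5, background = 7)
  sim <- render_movie(sched, geo, opt, frame_interval_s = 60)
  fr <- sim$movie$data$X[, , 1]
  mask <- replifork:::ellipse_mask(geo$dim, geo$center, geo$semiaxes)
  expect_equal(unique(fr[!mask]), 7)
  expect_equal(unique(fr[mask]), 7 + 1e5 / sum(mask))
})

test_that("rendering is deterministic under a fixed seed", {
  geo <- small_geometry()
  a <- render_movie(hu_schedule(t_end = 17), geo, noisy_optics(seed = 11),
                    frame_interval_s = 60)
  b <- render_movie(hu_schedule(t_end = 17), geo, noisy_optics(seed = 11),
                    frame_interval_s = 60)
  c <- render_movie(hu_schedule(t_end = 17), geo, noisy_optics(seed = 12),
                    frame_interval_s = 60)
  expect_identical(a$movie$data, b$movie$data)
  expect_gt(mean(a$movie$data$PCNA != c$movie$data$PCNA), 0.5)
})

test_that("FRAP movies follow the stated recovery law", {
  geo <- small_geometry(n_foci = 4L, seed = 7L)
  opt <- quiet_optics()
  # full mobility, fast only: recovery approaches pre-bleach level
  fr <- frap_kinetics(A_f = 1, k_f = log(2) / 5, A_s = 0, k_s = 1,
                      bleach_depth = 0, total_s = 120)
  sim <- render_frap_movie(fr, geo, opt)
  expect_equal(sim$truth$focus_factor[length(sim$truth$focus_factor)], 1,
               tolerance = 1e-6)
  expect_equal(sim$truth$bleach_frame, 7L)
  # immobile remainder caps the plateau: A_f = 0.7, immobile 0.3
  fr2 <- frap_kinetics(A_f = 0.7, k_f = log(2) / 5, A_s = 0, k_s = 1,
                       bleach_depth = 0, total_s = 600)
  sim2 <- render_frap_movie(fr2, geo, opt)
  expect_equal(sim2$truth$focus_factor[length(sim2$truth$focus_factor)],
               0.7, tolerance = 1e-6)
  # slow component at half its amplitude one slow half-life in
  fr3 <- frap_kinetics(A_f = 0.7, k_f = 50, A_s = 0.3, k_s = log(2) / 20,
                       bleach_depth = 0, total_s = 60)
  sim3 <- render_frap_movie(fr3, geo, opt)
  k20 <- sim3$truth$bleach_frame + 20L
  expect_equal(sim3$truth$focus_factor[k20], 0.7 + 0.3 / 2, tolerance = 1e-3)
  expect_error(frap_kinetics(A_f = 0.8, A_s = 0.4), "exceeds 1")
})
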