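frap_scene <- function(seed = 7L) small_geometry(n_foci = 4L, seed = seed)

make_frap_record <- function(frap, seed = 9L, noisy = FALSE) {
  geo <- frap_scene()
  opt <- if (noisy) noisy_optics(seed = seed) else quiet_optics(seed = seed)
  sim <- render_frap_movie(frap, geo, opt)
  list(rec = frap_traces(sim$movie, geo), sim = sim, geo = geo)
}

test_that("normalization pins the pre-bleach mean to 1 and the bleach frame to 0", {
  fr <- frap_kinetics(A_f = 0.5, k_f = log(2) / 2, A_s = 0.35,
                      k_s = log(2) / 149, bleach_depth = 0.4)
  x <- make_frap_record(fr)
  curve <- normalize_frap(x$rec)
  expect_equal(mean(curve$value[curve$pre_frames]), 1, tolerance = 1e-9)
  expect_identical(curve$value[curve$bleach_frame], 0)
  # noise-free: normalized curve equals the ground-truth recovery law
  post <- curve$t_post_s >= 0
  truth <- replifork:::frap_recovery_law(fr, curve$t_post_s[post])
  expect_equal(curve$value[post], truth, tolerance = 1e-10)
})

test_that("normalization is idempotent and cancels acquisition bleaching", {
  fr <- frap_kinetics()
  x <- make_frap_record(fr)
  curve <- normalize_frap(x$rec)
  # feed the normalized curve back in as a record
  rec2 <- structure(list(times_s = x$rec$times_s, bleached = curve$value,
                         unbleached = rep(1, length(curve$value)),
                         background = rep(0, length(curve$value)),
                         bleach_frame = curve$bleach_frame),
                    class = "frap_record")
  curve2 <- normalize_frap(rec2)
  expect_equal(curve2$value, curve$value, tolerance = 1e-12)
  # multiply both foci by a shared per-frame decay: curve unchanged
  g <- 0.995^(seq_along(x$rec$times_s) - 1)
  rec3 <- x$rec
  rec3$bleached <- (rec3$bleached - rec3$background) * g + rec3$background
  rec3$unbleached <- (rec3$unbleached - rec3$background) * g + rec3$background
  curve3 <- normalize_frap(rec3)
  expect_equal(curve3$value, curve$value, tolerance = 1e-9)
})

test_that("normalization rejects short pre-bleach spans and flags no-bleach input", {
  fr <- frap_kinetics(n_pre = 5)
  x <- make_frap_record(fr)
  expect_error(normalize_frap(x$rec), "6 pre-bleach")
  # identical bleached/unbleached traces: degenerate, flagged
  fr2 <- frap_kinetics()
  y <- make_frap_record(fr2)
  rec <- y$rec
  rec$bleached <- rec$unbleached
  expect_warning(curve <- normalize_frap(rec), "degenerate")
  expect_true(curve$degenerate)
})

test_that("two-component decomposition recovers exact parameters and falls back", {
  fr <- frap_kinetics(A_f = 0.5, k_f = 0.1, A_s = 0.35, k_s = 0.0047)
  x <- make_frap_record(fr)
  fit <- fit_two_component(normalize_frap(x$rec))
  expect_equal(fit$model, "two")
  expect_equal(fit$A_f, 0.5, tolerance = 1e-4)
  expect_equal(fit$k_f, 0.1, tolerance = 1e-4)
  expect_equal(fit$A_s, 0.35, tolerance = 1e-4)
  expect_equal(fit$k_s, 0.0047, tolerance = 1e-4)
  expect_equal(fit$immobile, 0.15, tolerance = 1e-4)
  # recovery plateau + immobile = 1 within fit tolerance
  expect_equal(fit$A_f + fit$A_s + fit$immobile, 1, tolerance = 1e-6)

  # pure single exponential: fallback branch with A_s = 0
  fr2 <- frap_kinetics(A_f = 1, k_f = log(2) / 5, A_s = 0, k_s = 1)
  y <- make_frap_record(fr2)
  fit2 <- fit_two_component(normalize_frap(y$rec))
  expect_equal(fit2$model, "single")
  expect_equal(fit2$A_s, 0)
  expect_equal(fit2$t_half_slow, 5, tolerance = 1e-4)
})

test_that("bound recovery isolates the slow component", {
  fr <- frap_kinetics(A_f = 0.5, k_f = 0.1, A_s = 0.35, k_s = log(2) / 149)
  x <- make_frap_record(fr)
  curve <- normalize_frap(x$rec)
  fit <- fit_two_component(curve)
  br <- bound_recovery(curve, fit)
  expect_equal(br$t_half_bound, 149, tolerance = 1e-3)
  # pointwise algebra: A_s/(1-A_f) (1 - exp(-k_s t))
  truth <- fit$A_s / (1 - fit$A_f) * (1 - exp(-fit$k_s * br$t_post_s))
  expect_equal(br$value, truth, tolerance = 1e-6)
  # untreated-like single-step path reports ln2/k directly
  fr2 <- frap_kinetics(A_f = 1, k_f = log(2) / 55, A_s = 0, k_s = 1)
  y <- make_frap_record(fr2)
  fit2 <- fit_two_component(normalize_frap(y$rec))
  expect_equal(fit2$t_half_slow, 55, tolerance = 1e-3)
  expect_error(bound_recovery(normalize_frap(y$rec), fit2), "two-component")
})

test_that("exchange-rate conversion reproduces the printed arithmetic", {
  rec <- list(t_post_s = c(0, 9), value = c(0, 61.1 / 81))
  ex <- exchange_rate(rec, n_bound = 81, window = 9)
  expect_equal(ex$complexes, 61.1, tolerance = 1e-6)
  expect_equal(round(ex$rate_per_min, 1), 407.3)
  ex2 <- exchange_rate(list(t_post_s = c(0, 60), value = c(0, 2.4 / 10.4)),
                       n_bound = 10.4, window = 60)
  expect_equal(ex2$complexes, 2.4, tolerance = 1e-6)
  expect_equal(ex2$rate_per_min, 2.4, tolerance = 1e-6)
  expect_equal(exchange_rate(list(t_post_s = c(0, 9), value = c(0, 0)),
                             10, 9)$complexes, 0)
  expect_error(exchange_rate(rec, 81, window = 20), "beyond")
})
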