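test_that("closed-form schedule evaluation matches half-life arithmetic", {
  sched <- kinetic_schedule(
    list(P = channel_kinetics("decay", f0 = 0.27, f_res = 0,
                              t_half_stall = 2.1),
         R = channel_kinetics("rise", f_max = 0.35, t_half_stall = 23.9)),
    t_treat = 15, t_washout = NA, t_end = 200)
  # one stalling half-life halves the decaying excess
  expect_equal(evaluate_schedule(sched, 15 + 2.1, "P"), 0.135)
  # plateau limit of the accumulation channel
  expect_equal(evaluate_schedule(sched, 200, "R"), 0.35, tolerance = 1e-2)
  # with a residual floor: f_res + (f0 - f_res)/2 at one half-life
  sched2 <- kinetic_schedule(
    list(P = channel_kinetics("decay", f0 = 0.27, f_res = 0.0475,
                              t_half_stall = 2.1)),
    t_treat = 15, t_washout = NA)
  expect_equal(evaluate_schedule(sched2, 15 + 2.1, "P"), 0.15875)
})

test_that("schedules are continuous at phase boundaries and stay in [0,1]", {
  sched <- kinetic_schedule(default_channels("HU"))
  eps <- 1e-9
  for (ch in c("PCNA", "RPA1")) {
    expect_equal(evaluate_schedule(sched, sched$t_treat - eps, ch),
                 evaluate_schedule(sched, sched$t_treat + eps, ch),
                 tolerance = 1e-6)
    expect_equal(evaluate_schedule(sched, sched$t_washout - eps, ch),
                 evaluate_schedule(sched, sched$t_washout + eps, ch),
                 tolerance = 1e-6)
    # treatment-time value equals the baseline value
    expect_equal(evaluate_schedule(sched, sched$t_treat, ch),
                 evaluate_schedule(sched, 0, ch))
  }
  # property sweep: random parameterizations remain within [0, 1]
  set.seed(42)
  for (i in 1:25) {
    f0 <- runif(1); fr <- runif(1, 0, f0); fm <- runif(1)
    ck <- channel_kinetics(sample(c("decay", "rise"), 1), f0 = f0,
                           f_res = fr, f_max = max(fm, f0),
                           t_half_stall = runif(1, 0.5, 30),
                           t_half_restart = runif(1, 0.5, 30),
                           f_post = runif(1, 0, min(fm, f0)))
    s <- kinetic_schedule(list(X = ck), t_treat = 10, t_washout = 40,
                          t_end = 80)
    v <- evaluate_schedule(s, seq(0, 80, by = 0.5), "X")
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
  }
})

test_that("invalid schedule parameters and out-of-span times are rejected", {
  expect_error(channel_kinetics("decay", f0 = 0.2, f_res = 0.3), "f_res")
  expect_error(channel_kinetics("decay", t_half_stall = 0), "positive")
  expect_error(kinetic_schedule(list(X = channel_kinetics("decay")),
                                t_treat = 20, t_washout = 10),
               "strictly increasing")
  sched <- kinetic_schedule(default_channels("HU"))
  expect_error(evaluate_schedule(sched, sched$t_end + 1, "PCNA"), "span")
  expect_error(evaluate_schedule(sched, 5, "nope"), "unknown channel")
})
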