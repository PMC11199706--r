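test_that("binding model: zero ligand, equilibrium and closed-form step response", {
  p <- quiet_params(k_on = 1e6, k_off = 0.029)
  t <- seq(0, 10, by = 0.001)

  # zero ligand: occupancy stays at 0, fluorescence at f0
  z <- simulate_binding_response(p, 0, t)
  expect_true(all(z$occupancy == 0))
  expect_true(all(z$fluorescence == p$f0))

  # ligand held at Kd to steady state: occupancy 0.5, dF/F r_max/2
  teq <- seq(0, 12 / (p$k_on * p$kd + p$k_off), by = 0.01)
  eq <- simulate_binding_response(p, p$kd, teq)
  expect_equal(tail(eq$occupancy, 1), 0.5, tolerance = 1e-4)
  expect_equal(tail(eq$fluorescence, 1) / p$f0 - 1, p$r_max / 2,
               tolerance = 1e-3)

  # step to 1 uM matches the analytic mono-exponential with rate k_on*L+k_off
  L <- 1e-6
  sim <- simulate_binding_response(p, L, t)
  r <- p$k_on * L + p$k_off
  closed <- (L / (L + p$kd)) * (1 - exp(-r * t))
  expect_lt(max(abs(sim$occupancy - closed)) / max(closed), 1e-6)

  expect_error(simulate_binding_response(p, -1e-9, t), "non-negative")
})

test_that("binding model agrees with an independent ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- quiet_params(k_on = 5e5, k_off = 0.1)
  t <- seq(0, 30, by = 0.01)
  lig <- rep(c(0, 2e-7, 5e-8, 1e-6),
             each = ceiling(length(t) / 4))[seq_along(t)]
  sim <- simulate_binding_response(p, lig, t)
  Lfun <- stats::approxfun(t, lig, method = "constant", rule = 2)
  ode <- deSolve::lsoda(c(B = 0), t, function(tt, y, parms)
    list(p$k_on * Lfun(tt) * (1 - y) - p$k_off * y),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sim$occupancy - ode[, "B"])), 1e-5)
})

test_that("equilibrium occupancy matches L/(L+Kd) for random positive parameters", {
  set.seed(42)
  for (i in 1:10) {
    kon <- 10^runif(1, 4, 7)
    koff <- 10^runif(1, -3, 0)
    L <- 10^runif(1, -9, -5)
    p <- quiet_params(k_on = kon, k_off = koff)
    r <- kon * L + koff
    t <- seq(0, 12 / r, length.out = 2000)
    sim <- simulate_binding_response(p, L, t)
    expect_equal(tail(sim$occupancy, 1), L / (L + p$kd), tolerance = 1e-4)
  }
})

test_that("photometry session: clean limit, default rate, shared artifact, reproducibility", {
  p <- quiet_params()
  sch <- event_schedule(data.frame(time_s = numeric(0),
                                   label = character(0),
                                   duration_s = numeric(0)),
                        session_length = 10, variant = "injection")
  rec <- simulate_photometry_session(p, sch, rate = 100)
  expect_true(all(rec$signal == p$f0))
  expect_true(all(rec$control == 0.5 * p$f0))

  recd <- simulate_photometry_session(p, sch)
  expect_equal(recd$rate, 1017.25)

  # motion artifact has identical waveform on both channels:
  # noise-free ratio of channels is constant despite the artifact
  pm <- sensor_params(motion_sd = 0.05, noise_sd = 0, seed = 9)
  recm <- simulate_photometry_session(pm, sch, rate = 200)
  expect_lt(diff(range(recm$signal / recm$control)), 1e-10)
  expect_gt(stats::sd(recm$signal), 0)

  # bit-reproducible under a fixed seed
  pz <- sensor_params(motion_sd = 0.02, noise_sd = 0.01, seed = 5)
  r1 <- simulate_photometry_session(pz, sch, rate = 100)
  r2 <- simulate_photometry_session(pz, sch, rate = 100)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$control, r2$control)
})

test_that("line-scan simulator: degenerate cases, tau round trip, dye latency gate", {
  p <- quiet_params()
  bg <- simulate_linescan(p, n_membrane = 0, n_background = 10,
                          duration = 2, seed = 1)
  expect_true(all(!bg$membrane_mask_truth))

  st <- simulate_linescan(p, n_membrane = 5, n_background = 0,
                          tau_true = 0.595, duration = 5, seed = 2)
  s <- pixelwise_tau_on(st, st$membrane_mask_truth,
                        onset_s = st$truth$onset_s)
  expect_equal(s$mean, 0.595, tolerance = 1e-4)

  # a 60 ms dye latency fails the 50 ms onset gate; 20 ms passes
  slow <- simulate_linescan(p, n_membrane = 1, n_background = 0,
                            dye_latency = 0.06, seed = 3)
  g <- onset_latency(slow$reference[1, ], slow$rate,
                     application_s = slow$truth$onset_s)
  expect_false(g$passed)
  expect_equal(g$latency, 0.06, tolerance = 0.005)
  fast <- simulate_linescan(p, n_membrane = 1, n_background = 0,
                            dye_latency = 0.02, seed = 3)
  gf <- onset_latency(fast$reference[1, ], fast$rate,
                      application_s = fast$truth$onset_s)
  expect_true(gf$passed)
})

test_that("dose-response simulator lies on the Hill curve at cv = 0", {
  tab <- simulate_dose_response(r_max = 2, ec50 = 1e-7, hill = 1.3, cv = 0)
  mu <- 2 * tab$concentration^1.3 / (1e-7^1.3 + tab$concentration^1.3)
  expect_equal(tab$response, mu, tolerance = 1e-12)

  at_ec50 <- simulate_dose_response(r_max = 3.88, ec50 = 1e-7,
                                    concentrations = 1e-7, cv = 0,
                                    replicates = 1)
  expect_equal(at_ec50$response, 3.88 / 2)

  # default ladder is the 8-point bath-application series 5 nM - 10 uM
  def <- simulate_dose_response(cv = 0)
  expect_equal(sort(unique(def$concentration)),
               c(5e-9, 1e-8, 5e-8, 1e-7, 5e-7, 1e-6, 5e-6, 1e-5))
  expect_equal(sum(def$concentration == 5e-9), 3)

  expect_error(simulate_dose_response(concentrations = numeric(0)),
               "non-empty")
  t1 <- simulate_dose_response(seed = 4)
  t2 <- simulate_dose_response(seed = 4)
  expect_identical(t1$response, t2$response)
})

test_that("progressive-ratio criteria follow the rounded geometric progression", {
  expect_identical(generate_pr_schedule(6), c(1L, 2L, 4L, 6L, 9L, 12L))
  expect_identical(generate_pr_schedule(0), integer(0))
  expect_equal(generate_pr_schedule(10)[10], 32)

  # brute-force check of the formula with round-half-away-from-zero, i = 1..50
  brute <- vapply(1:50, function(i) {
    x <- 5 * exp(i / 5) - 5
    as.integer(sign(x) * floor(abs(x) + 0.5))
  }, integer(1))
  got <- generate_pr_schedule(50)
  expect_identical(got, brute)
  expect_true(all(diff(got) >= 0))
})

test_that("event schedules reproduce the behavioral paradigms", {
  cs <- generate_event_schedule("cued_sucrose", seed = 1)
  tones <- cs$events[cs$events$label == "tone", ]
  expect_equal(nrow(tones), 15)
  expect_true(all(tones$duration_s == 5))
  sucs <- cs$events[cs$events$label == "sucrose", ]
  expect_equal(sucs$time_s, tones$time_s + 5)
  itis <- diff(tones$time_s) - 10
  expect_true(all(itis >= 45 & itis <= 75))
  expect_equal(tones$time_s[1], 300)

  tl <- generate_event_schedule("tail_lift", seed = 2)
  lifts <- tl$events[tl$events$label == "tail_lift", ]
  expect_equal(nrow(lifts), 4)
  expect_true(all(lifts$duration_s == 10))
  expect_true(all(diff(lifts$time_s) - 10 >= 120 &
                  diff(lifts$time_s) - 10 <= 300))
  expect_equal(tl$session_length,
               max(lifts$time_s) + 10 + 300)

  empty <- generate_event_schedule("cued_sucrose", n_trials = 0)
  expect_equal(nrow(empty$events), 0)
  expect_gt(empty$session_length, 0)

  expect_error(generate_event_schedule("unknown_variant"))

  s1 <- generate_event_schedule("tail_lift", seed = 7)
  s2 <- generate_event_schedule("tail_lift", seed = 7)
  expect_identical(s1$events, s2$events)
})
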