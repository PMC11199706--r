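test_that("LLS fit: exact cases and closed-form sampling error", {
  x <- c(1, 2, 3, 4, 5)
  f1 <- fit_lls(x, x)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)

  f2 <- fit_lls(x, 2 * x + 3)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 3)
  expect_equal(f2$fitted, 2 * x + 3)

  # noisy linear relation: estimate within 2 SE of truth (closed form:
  # SE(slope) = sigma / (sqrt(n) * sd(control)))
  set.seed(21)
  n <- 2000
  ctrl <- runif(n, 50, 60)
  sig <- 1.8 * ctrl + 4 + rnorm(n, 0, 0.5)
  f3 <- fit_lls(ctrl, sig)
  se <- 0.5 / (sqrt(n) * stats::sd(ctrl))
  expect_lt(abs(f3$slope - 1.8), 2 * se)

  expect_error(fit_lls(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_lls(1, 1), "2 samples")
})

test_that("power-like baseline: recovery, and median fallback on non-decaying traces", {
  t <- seq(0, 900, by = 1)
  y <- 100 * (t + 10)^(-0.3) + 50
  pf <- fit_powerlike_baseline(y, c(0, 600), t = t)
  expect_true(pf$success)
  expect_equal(unname(pf$coefficients[["a"]]), 100, tolerance = 0.05)
  expect_equal(unname(pf$coefficients[["b"]]), 0.3, tolerance = 0.05)
  expect_equal(unname(pf$coefficients[["c0"]]), 50, tolerance = 0.05)
  expect_lt(max(abs(pf$baseline - y)), 0.01)

  # flat trace: no decay, fallback to the baseline-window median
  set.seed(2)
  flat <- rnorm(200, 80, 0.2)
  pff <- fit_powerlike_baseline(flat, c(1, 200))
  expect_false(pff$success)
  expect_equal(pff$baseline, rep(median(flat), 200))

  # monotone increasing trace: no decay
  up <- 50 + 0.05 * seq(0, 400)
  expect_false(fit_powerlike_baseline(up, c(1, 401))$success)

  expect_error(fit_powerlike_baseline(flat, c(0, 10)), "30 samples")
})

test_that("power-like dF/F pipeline: 1 Hz output, artifact cancellation, rise recovery", {
  kd <- quiet_params()$kd
  # mild power-like bleach: a 5-min baseline constrains the F0(t) fit well
  # enough for extrapolation over the 10-min post-injection period
  p <- sensor_params(motion_sd = 0.04, noise_sd = 0,
                     bleach_model = "power_like",
                     bleach_params = list(a = 0.5, b = 0.3, t0 = 60,
                                          c = 0.8), seed = 6)
  rec <- tiny_injection_session(p, rate = 150, baseline_s = 300,
                                post_s = 600, seed = 6,
                                response_map = list(
                                  injection = list(shape = "sustained",
                                                   amplitude = 4 * kd,
                                                   tau = 30)))
  out <- preprocess_arc(rec)
  expect_equal(unique(round(diff(out$t), 9)), 1) # 1 Hz grid
  expect_equal(out$variant, "arc")

  # programmed post-injection rise: occupancy 0.8 at saturation of a
  # 4*Kd sustained ligand, so dF/F = r_max * 0.8 on the signal channel
  plateau <- mean(out$value[out$t >= 700 & out$t <= 850])
  expect_equal(plateau, p$r_max * 0.8, tolerance = 0.10)

  # shared multiplicative artifact with no ligand cancels out
  p0 <- sensor_params(motion_sd = 0.05, noise_sd = 0, seed = 7)
  sch <- event_schedule(data.frame(time_s = 60, label = "none",
                                   duration_s = 1),
                        session_length = 300, variant = "injection")
  rec0 <- simulate_photometry_session(p0, sch, rate = 150)
  out0 <- preprocess_arc(rec0, baseline_s = 60)
  expect_lt(max(abs(out0$value)), 0.01 * 0.05)

  expect_error(preprocess_arc(
    simulate_photometry_session(p0, event_schedule(
      data.frame(time_s = numeric(0), label = character(0),
                 duration_s = numeric(0)), 100, "injection"), rate = 50)),
    "baseline")
})

test_that("baseline-LLS correction removes a shared artifact almost entirely", {
  p <- sensor_params(motion_sd = 0.05, noise_sd = 0, seed = 13)
  rec <- tiny_injection_session(p, rate = 200, baseline_s = 120,
                                post_s = 300, seed = 13,
                                response_map = list(injection = list(
                                  shape = "sustained", amplitude = 0,
                                  tau = 1)))
  lls <- fit_lls(rec$control, rec$signal, window = c(0, 120), t = rec$t)
  resid <- rec$signal - lls$fitted
  artifact_var <- stats::var(p$f0 * rec$truth$motion)
  expect_gt(artifact_var, 0)
  expect_lt(stats::var(resid), 0.01 * artifact_var)
})

test_that("baseline-LLS pipeline: z-score definition and analytic plateau z", {
  kd <- quiet_params()$kd
  p <- sensor_params(noise_sd = 0.01, motion_sd = 0, seed = 1)
  rec <- tiny_injection_session(p, rate = 100, baseline_s = 900,
                                post_s = 600, seed = 1,
                                response_map = list(injection = list(
                                  shape = "sustained", amplitude = 4 * kd,
                                  tau = 30)))
  out <- preprocess_baseline_lls(rec)
  expect_equal(out$unit, "zscore")

  # z-scored baseline window has mean 0 and SD 1 by construction
  bidx <- which(out$t >= out$baseline_window[1] &
                out$t <= out$baseline_window[2])
  expect_equal(mean(out$value[bidx]), 0, tolerance = 1e-6)
  expect_equal(stats::sd(out$value[bidx]), 1, tolerance = 1e-6)

  # analytic plateau z from the generator's noise SD: additive noise
  # sigma = noise_sd * f0 per raw sample, reduced by block-mean
  # downsampling (x down) and the rolling smooth (x width); the baseline SD
  # estimate has limited effective degrees of freedom, so the observed z is
  # averaged over seeded replicate sessions
  down <- 300
  rate <- 50
  width <- round(10 * rate / down)
  if (width %% 2 == 0) width <- width + 1
  sigma_b <- (p$noise_sd * p$f0) / sqrt(down * width)
  z_pred <- p$f0 * p$r_max * 0.8 / sigma_b
  z_obs <- vapply(1:5, function(s) {
    ps <- sensor_params(noise_sd = 0.01, motion_sd = 0, seed = s)
    rs <- tiny_injection_session(ps, rate = rate, baseline_s = 1800,
                                 post_s = 600, seed = s,
                                 response_map = list(injection = list(
                                   shape = "sustained", amplitude = 4 * kd,
                                   tau = 30)))
    os <- preprocess_baseline_lls(rs, baseline_window = c(0, 1790),
                                  down = down)
    mean(os$value[os$t >= 2250 & os$t <= 2380])
  }, numeric(1))
  expect_equal(mean(z_obs), z_pred, tolerance = 0.10)
})

test_that("artifacts-only sessions carry no excursions beyond the noise floor", {
  # shared motion dominates the raw channels; after isosbestic correction
  # the z-trace must be indistinguishable from its baseline noise: no
  # artifact-driven excursions beyond the Gaussian envelope
  p <- sensor_params(motion_sd = 0.05, noise_sd = 0.002, seed = 17)
  rec <- tiny_injection_session(p, rate = 100, baseline_s = 300,
                                post_s = 600, seed = 17,
                                response_map = list(injection = list(
                                  shape = "sustained", amplitude = 0,
                                  tau = 1)))
  out <- preprocess_baseline_lls(rec, baseline_window = c(0, 295),
                                 down = 100)
  expect_lt(stats::quantile(abs(out$value), 0.95), 3)
})

test_that("session-LLS pipeline: constant limit and polynomial bleach removal", {
  p0 <- quiet_params()
  sch <- event_schedule(data.frame(time_s = 10, label = "none",
                                   duration_s = 1),
                        session_length = 400, variant = "injection")
  rec0 <- simulate_photometry_session(p0, sch, rate = 100)
  out0 <- preprocess_session_lls(rec0)
  expect_true(all(abs(out0$value - 1) < 1e-9))

  # degree-<=4 polynomial bleach is removed: residual linear trend tiny
  pb <- sensor_params(noise_sd = 0, motion_sd = 0,
                      bleach_model = "polynomial",
                      bleach_params = list(coef = c(-8e-4, 5e-7, 0, 0)))
  recb <- simulate_photometry_session(pb, sch, rate = 100)
  outb <- preprocess_session_lls(recb)
  sl <- stats::coef(stats::lm(outb$value ~ outb$t))[2]
  expect_lt(abs(sl), 1e-4)
})

test_that("all variants are invariant to a common positive channel rescaling", {
  p <- sensor_params(motion_sd = 0.02, noise_sd = 0.002,
                     bleach_model = "power_like", seed = 4)
  rec <- tiny_injection_session(p, rate = 120, baseline_s = 90,
                                post_s = 210, seed = 4)
  scaled <- two_channel_recording(rec$t, 7 * rec$signal, 7 * rec$control,
                                  rec$rate, events = rec$events)
  expect_equal(preprocess_arc(scaled)$value, preprocess_arc(rec)$value,
               tolerance = 1e-8)
  expect_equal(preprocess_baseline_lls(scaled)$value,
               preprocess_baseline_lls(rec)$value, tolerance = 1e-8)
  expect_equal(preprocess_session_lls(scaled)$value,
               preprocess_session_lls(rec)$value, tolerance = 1e-8)
})

test_that("downsampling preserves the mean and provenance replays bit-for-bit", {
  set.seed(5)
  x <- rnorm(3000)
  expect_equal(mean(downsample_block(x, 300)), mean(x), tolerance = 1e-9)
  expect_equal(rolling_mean(rep(2, 50), 11), rep(2, 50))

  p <- sensor_params(motion_sd = 0.03, noise_sd = 0.005,
                     bleach_model = "biexponential", seed = 2)
  rec <- tiny_injection_session(p, rate = 120, baseline_s = 60,
                                post_s = 180, seed = 2)
  for (fn in list(preprocess_arc, preprocess_baseline_lls,
                  preprocess_session_lls)) {
    out <- fn(rec)
    again <- replay_provenance(rec, out)
    expect_identical(out$value, again$value)
    expect_identical(out$t, again$t)
  }
})
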