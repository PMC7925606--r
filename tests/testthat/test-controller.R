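test_that("beat volume integral normalizes and signs correctly", {
  fs <- 250
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  # perfectly antisymmetric pulse: equal positive and negative half-waves
  anti <- sampled_signal(sin(2 * pi * 1 * t), fs = fs)
  expect_lt(abs(beat_volume_integral(anti, 1, 2)), 1e-10)
  # constant signal: the normalized integral is the constant
  cst <- sampled_signal(rep(0.37, length(t)), fs = fs)
  expect_equal(beat_volume_integral(cst, 0.5, 1.5), 0.37, tolerance = 1e-6)
  # fat pulse: negative half-wave area 0.6, positive 0.4, PI = 1 s
  fat <- ifelse(t %% 1 < 0.5, -1.2, 0.8)  # areas -0.6 and +0.4 per beat
  fat_sig <- sampled_signal(fat, fs = fs)
  expect_equal(beat_volume_integral(fat_sig, 1, 2), -0.2, tolerance = 0.01)
  expect_error(beat_volume_integral(anti, 2, 2), "interval")
  expect_error(beat_volume_integral(anti, 2.5, 4), "inside")
})

test_that("setpoint update implements the beat-based control law", {
  g <- controller_gains(c_BBI = 10, c_BBP = 5)
  st <- controller_state(P0 = 90)
  # all-zero integrals leave the setpoint at P0
  s0 <- st
  for (i in 1:5) s0 <- update_setpoint(s0, 0, g)
  expect_equal(s0$Pn, 90)
  # single fat beat: P1 = 90 - 10*(-0.2) - 5*(-0.2) = 93
  s1 <- update_setpoint(st, -0.2, g)
  expect_equal(s1$Pn, 93)
  # sequence (-0.1, -0.1, +0.2): P3 = 90 - 10*0 - 5*0.2 = 89
  s2 <- st
  for (v in c(-0.1, -0.1, 0.2)) s2 <- update_setpoint(s2, v, g)
  expect_equal(s2$Pn, 89)
  expect_equal(s2$sum_V, 0)
  expect_equal(s2$beat_count, 3L)
})

test_that("continuous PID terms accumulate per the control law", {
  g <- controller_gains(c_P = 50, c_D = 0, c_I = 0.1)
  st <- controller_state(90)
  # zero inputs keep both terms at zero
  s0 <- pid_rhythm(0, 0, st, g)
  expect_equal(s0$y_PD, 0)
  expect_equal(s0$y_I, 0)
  # constant v_Rhythm = 0.01 over 3 samples: y_PD = 0.5, y_I = 0.15
  s <- st
  for (i in 1:3) s <- pid_rhythm(0.01, 0, s, g)
  expect_equal(s$y_PD, 0.5)
  expect_equal(s$y_I, 0.15, tolerance = 1e-12)
  # frozen integral (anti-windup) leaves y_I unchanged
  s2 <- pid_rhythm(0.01, 0, s, g, freeze_integral = TRUE)
  expect_equal(s2$y_I, s$y_I)
})

test_that("discrete integrator lags the proportional term by ~90 degrees", {
  g <- controller_gains(c_P = 1, c_D = 0, c_I = 0.01)
  fs <- 250
  f <- 0.5
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  vr <- sin(2 * pi * f * t)
  st <- controller_state(90)
  ypd <- yi <- numeric(length(t))
  for (i in seq_along(t)) {
    st <- pid_rhythm(vr[i], 0, st, g)
    ypd[i] <- st$y_PD
    yi[i] <- st$y_I
  }
  keep <- t > 10
  phase_of <- function(y) atan2(-mean(y[keep] * cos(2 * pi * f * t[keep])),
                                mean(y[keep] * sin(2 * pi * f * t[keep])))
  dphi <- (phase_of(yi) - phase_of(ypd)) %% (2 * pi)
  expect_equal(min(dphi, 2 * pi - dphi), pi / 2, tolerance = 0.1)
})

test_that("contact pressure command combines terms and clamps", {
  st <- controller_state(90)
  expect_equal(contact_pressure_command(st)$command, 90)
  st$Pn <- 90
  st$y_I <- 2
  st$y_PD <- -1
  expect_equal(contact_pressure_command(st)$command, 89)
  st$Pn <- 10
  st$y_I <- 0
  st$y_PD <- 0
  cc <- contact_pressure_command(st, coupling_floor = 20)
  expect_equal(cc$command, 20)
  expect_true(cc$clamped)
})

test_that("waveform calibration reproduces the calibration pulse pressure", {
  # k = (120 - 80) / (-0.4 - 0.4) = -50
  cal <- calibration_state(120, 80, v_sys_ref = -0.4, v_dia_ref = 0.4)
  expect_equal(cal$k, -50)
  expect_equal(cal$k * (cal$v_sys_ref - cal$v_dia_ref), 120 - 80)
  fs <- 250
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  # 1.25 Hz places the exact extrema +/-0.4 on the sample grid
  vp <- sampled_signal(0.4 * sin(2 * pi * 1.25 * t), fs = fs)
  pc <- sampled_signal(rep(93, length(t)), fs = fs, unit = "mmHg")
  p2g <- calibrate_waveform(pc, vp, cal)
  expect_equal(range(p2g$values), c(73, 113), tolerance = 1e-9)
  expect_equal(max(p2g$values) - min(p2g$values), 40, tolerance = 1e-12)
  # zero pulse leaves the contact pressure untouched
  v0 <- sampled_signal(rep(0, length(t)), fs = fs)
  expect_equal(calibrate_waveform(pc, v0, cal)$values, pc$values)
  expect_error(calibration_state(120, 80, 0.2, 0.2), "degenerate")
})

test_that("hydrostatic heart-level correction", {
  expect_equal(hydrostatic_correct(95, heart_level_offset(0)), 95)
  expect_equal(hydrostatic_correct(95, heart_level_offset(10)), 95 - 7.8)
  expect_equal(hydrostatic_correct(95, heart_level_offset(-10)), 95 + 7.8)
  expect_error(heart_level_offset(150), "100")
})

test_that("operation modes follow the allowed transitions", {
  expect_equal(mode_step("start", "started"), "initial")
  expect_equal(mode_step("initial", "envelope_done"), "measure")
  expect_equal(mode_step("measure", "measure_timer_elapsed"), "interpolate")
  expect_equal(mode_step("interpolate", "interp_timer_elapsed"), "initial")
  expect_equal(mode_step("interpolate", "morphology_change"), "initial")
  expect_error(mode_step("start", "envelope_done"), "illegal")
  expect_error(mode_step("measure", "started"), "illegal")
})

test_that("interpolation estimator behaves like a least-squares model", {
  set.seed(9)
  feats <- data.frame(amplitude = rep(0.5, 60), baseline = rep(0.7, 60),
                      mBP = rep(90, 60))
  m <- fit_interpolation_model(feats)
  est <- interpolation_estimate(m, data.frame(amplitude = 0.5,
                                              baseline = 0.7))
  expect_equal(est$mBP, 90, tolerance = 1e-9)
  expect_equal(est$quality, "interpolated")
  # features at the training mean give the training-mean target
  feats2 <- data.frame(amplitude = runif(80, 0.3, 0.6),
                       baseline = runif(80, 0.6, 0.8))
  feats2$mBP <- 60 + 40 * feats2$amplitude + rnorm(80, 0, 2)
  m2 <- fit_interpolation_model(feats2)
  est2 <- interpolation_estimate(m2,
                                 data.frame(amplitude = mean(feats2$amplitude),
                                            baseline = mean(feats2$baseline)))
  expect_equal(est2$mBP, mean(feats2$mBP), tolerance = 1e-6)
  expect_error(interpolation_estimate(NULL, feats2), "untrained")
  expect_error(fit_interpolation_model(feats2[1:10, ]), "60 s")
})
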