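test_that("sampled_signal enforces its invariants and round-trips CSV", {
  s <- sampled_signal(sin(1:100), fs = 250, t0 = 2, label = "x")
  expect_equal(signal_time(s)[1], 2)
  expect_equal(signal_time(s)[100], 2 + 99 / 250)
  expect_error(sampled_signal(numeric(0)), "at least one")
  expect_error(sampled_signal(c(1, NA)), "finite")
  expect_error(sampled_signal(1, fs = 0), "fs")

  path <- file.path(tempdir(), "sig.csv")
  write_signal_csv(s, path)
  s2 <- read_signal_csv(path)
  expect_equal(s2$values, s$values)
  expect_equal(s2$fs, 250)
  expect_equal(s2$t0, 2)
  unlink(c(path, sub("csv$", "json", path)))
})

test_that("iir_stage follows the first-order recursion exactly", {
  # identity when UC = 1
  x <- rnorm(50)
  expect_equal(iir_stage(x, filter_stage(UC = 1)), x)
  # fixed point: constant input equal to the state stays put
  expect_equal(iir_stage(rep(3.5, 20), filter_stage(UC = 0.2), 3.5),
               rep(3.5, 20))
  # unit step, UC = 0.1: y_i = 1 - 0.9^(i+1) (0-based), y_9 ~ 0.6513
  y <- iir_stage(rep(1, 10), filter_stage(UC = 0.1), 0)
  expect_equal(y, 1 - 0.9^(1:10), tolerance = 1e-12)
  expect_equal(y[10], 0.6513216, tolerance = 1e-6)
  expect_error(iir_stage(c(1, Inf), filter_stage(0.1)), "finite")
  expect_error(iir_stage(numeric(0), filter_stage(0.1)), "empty")
})

test_that("decimated stages hold between block updates", {
  x <- rep(1, 20)
  y <- iir_stage(x, filter_stage(UC = 0.5, decimation = 5), 0)
  # first update at the end of block 1 (sample 5), held through sample 9
  expect_equal(y[1:4], rep(0, 4))
  expect_equal(y[5:9], rep(0.5, 5))
  expect_equal(y[10:14], rep(0.75, 5))
})

test_that("filter states seeded at v0 null all outputs for constant input", {
  cfg <- filter_bank_config()
  st <- init_filter_states(5, cfg)
  v <- sampled_signal(rep(5, 2500), fs = 250)
  out <- decompose(v, cfg, st)
  for (nm in c("v_Pulse", "v_Rhythm", "v_dRhythm", "v_VCT"))
    expect_lt(max(abs(out[[nm]]$values)), 1e-10)
  # a step away from the seed produces a positive v_VCT transient that decays
  v2 <- sampled_signal(rep(6, 250 * 120), fs = 250)
  out2 <- decompose(v2, cfg, init_filter_states(5, cfg))
  expect_gt(max(out2$v_VCT$values), 0.5)
  expect_lt(abs(out2$v_VCT$values[250 * 120]),
            0.2 * max(out2$v_VCT$values))
})

test_that("decompose separates pulse and rhythm bands", {
  # DC rejection after settling
  cfg <- filter_bank_config()
  v <- sampled_signal(rep(2, 250 * 400), fs = 250)
  out <- decompose(v, cfg)
  tail_idx <- (250 * 390):(250 * 400)
  for (nm in c("v_Pulse", "v_Rhythm", "v_dRhythm", "v_VCT"))
    expect_lt(max(abs(out[[nm]]$values[tail_idx])), 1e-3)
  # band gains measured on sinusoids (transfer-function oracle)
  expect_gte(measured_gain(1.2, "v_Pulse"), 0.9)
  expect_lte(measured_gain(1.2, "v_Rhythm"), 0.1)
  expect_gte(measured_gain(0.1, "v_Rhythm", settle_s = 300), 0.7)
  expect_lte(measured_gain(0.1, "v_Pulse"), 0.1)
  expect_error(decompose(sampled_signal(1, fs = 100), cfg), "fs")
})

test_that("decompose is linear in its input", {
  cfg <- filter_bank_config()
  set.seed(42)
  t <- seq(0, 20 - 1 / 250, by = 1 / 250)
  x <- sin(2 * pi * 1.1 * t)
  y <- sin(2 * pi * 0.2 * t) + 0.3 * rnorm(length(t))
  st0 <- init_filter_states(0, cfg)
  mix <- decompose(sampled_signal(2 * x - 3 * y, fs = 250), cfg, st0)
  dx <- decompose(sampled_signal(x, fs = 250), cfg, st0)
  dy <- decompose(sampled_signal(y, fs = 250), cfg, st0)
  for (nm in c("v_Pulse", "v_Rhythm", "v_dRhythm", "v_VCT"))
    expect_equal(mix[[nm]]$values,
                 2 * dx[[nm]]$values - 3 * dy[[nm]]$values,
                 tolerance = 1e-10)
})

test_that("stationary signal is approximated by trend + rhythm + pulse", {
  cfg <- filter_bank_config()
  t <- seq(0, 400 - 1 / 250, by = 1 / 250)
  x <- 0.5 + 0.2 * sin(2 * pi * 1 * t) + 0.1 * sin(2 * pi * 0.1 * t)
  out <- decompose(sampled_signal(x, fs = 250), cfg,
                   init_filter_states(0.5, cfg))
  keep <- t > 300
  trend <- x - out$v_VCT$values  # removed very-low-frequency content
  resid <- x[keep] - (trend[keep] + out$v_Rhythm$values[keep] +
                        out$v_Pulse$values[keep])
  # reconstruction error small against the 0.3 total oscillation amplitude
  expect_lt(sqrt(mean(resid^2)), 0.1)
})

test_that("every filter output is BIBO-bounded for unit-amplitude input", {
  cfg <- filter_bank_config()
  set.seed(7)
  x <- sign(rnorm(250 * 60))  # worst-ish bounded input
  out <- decompose(sampled_signal(x, fs = 250), cfg,
                   init_filter_states(0, cfg))
  expect_lt(max(abs(out$v_Pulse$values)), 4)
  expect_lt(max(abs(out$v_Rhythm$values)), 4)
  expect_lt(max(abs(out$v_VCT$values)), 4)
  expect_lt(max(abs(out$v_dRhythm$values)), 4 * pi * cfg$dRhythm_band[2] * 8)
})

test_that("frequency_response matches the gates and the measured gains", {
  cfg <- filter_bank_config()
  # rhythm output is dead near the Nyquist rate
  hr <- frequency_response(cfg, 120)
  expect_lt(Mod(hr$v_Rhythm), 0.01)
  # washout gain at the very-low-frequency cutoff is in the -3 dB region
  hv <- frequency_response(cfg, cfg$cutoff_vlf)
  expect_gt(Mod(hv$v_VCT), 0.3)
  expect_lt(Mod(hv$v_VCT), 0.7)
  # no unintended amplification (the derivative branch excepted)
  f <- c(0.005, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 5, 20, 80)
  H <- frequency_response(cfg, f)
  for (nm in c("v_Pulse", "v_Rhythm", "v_VCT"))
    expect_lt(max(Mod(H[[nm]])), 1.5)
  expect_error(frequency_response(cfg, 130), "fs/2")
  # analytic curve agrees with measured sinusoid gains
  expect_equal(Mod(frequency_response(cfg, 1.2)$v_Pulse),
               measured_gain(1.2, "v_Pulse"), tolerance = 0.02)
  expect_equal(Mod(frequency_response(cfg, 0.1)$v_Rhythm),
               measured_gain(0.1, "v_Rhythm", settle_s = 300),
               tolerance = 0.05)
})

test_that("beat detection counts, intervals and robustness", {
  # 1 Hz train over 60 s: 60 +/- 1 beats
  tr <- synth_pulse_train(1, 60)
  b <- detect_beats(tr$signal)
  expect_gte(nrow(b), 59)
  expect_lte(nrow(b), 61)
  # detection latency after the systolic extremum below 200 ms
  lat <- vapply(b$t_sys, function(ts) min(abs(tr$sys_t - ts)), 0)
  expect_lt(max(lat), 0.05)
  expect_lt(max(b$t_end - b$t_sys), 0.2)
  # 2 Hz train: pulse intervals 0.5 +/- 0.02 s
  tr2 <- synth_pulse_train(2, 30)
  b2 <- detect_beats(tr2$signal)
  expect_lt(max(abs(b2$PI[-1] - 0.5)), 0.02)
  # one 40% amplitude dropout: no double detection, count stays right
  sc <- rep(1, 30)
  sc[15] <- 0.4
  tr3 <- synth_pulse_train(1, 30, amp_scale = sc)
  b3 <- detect_beats(tr3$signal)
  expect_lte(nrow(b3), 30)
  expect_gte(nrow(b3), 29)
  expect_gt(min(b3$PI, na.rm = TRUE), 0.5)
  # flat signal: no beats, no error
  expect_equal(nrow(detect_beats(sampled_signal(rep(0.3, 5000), fs = 250))),
               0)
})

test_that("beat detector F1 on clean and noisy trains", {
  tr <- synth_pulse_train(1.2, 60)
  b <- detect_beats(tr$signal)
  expect_gte(beat_f1(b$t_sys, tr$sys_t), 0.99)
  # SNR 10 dB
  set.seed(11)
  amp_rms <- sd(tr$signal$values)
  noisy <- sampled_signal(tr$signal$values +
                            rnorm(length(tr$signal$values),
                                  0, amp_rms * 10^(-10 / 20)),
                          fs = 250)
  bn <- detect_beats(noisy)
  expect_gte(beat_f1(bn$t_sys, tr$sys_t), 0.95)
})

test_that("compiled loop cascade matches the reference decomposition", {
  # the per-sample compiled cascade and the vectorized one must agree
  cfg <- filter_bank_config()
  set.seed(3)
  n <- 250 * 20
  t <- (0:(n - 1)) / 250
  v_in <- 0.6 + 0.2 * sin(2 * pi * t) + 0.05 * sin(2 * pi * 0.1 * t) +
    0.01 * rnorm(n)
  # run the compiled path open-loop via a transparent pressure-volume map
  pv <- pv_model_config(v_high = 1, v_low0 = 0, tone_gain = 0, w = 1e6,
                        center_offset = 0)
  # with w enormous, v = 0.5 + (p_c - p_a) / (pi * w) ~ 0.5; instead feed
  # the signal through the noise channel on a constant carrier
  par <- vctbp:::loop_params(cfg, controller_gains(), actuator_config(),
                             pv, 250, 20,
                             beat_control = FALSE, pid_control = FALSE,
                             fixed_command = 50)
  st <- vctbp:::new_loop_state(v_in[1], 50, cfg, actuator_config(), 250,
                               p_applied = 50, amp_est = 0.2)
  out <- vctbp:::vct_chunk_cpp(rep(0, n), rep(0, n), v_in - 0.5, par, st)
  ref <- decompose(sampled_signal(out$v, fs = 250), cfg,
                   init_filter_states(v_in[1], cfg))
  expect_equal(out$v_Pulse, ref$v_Pulse$values, tolerance = 1e-10)
  expect_equal(out$v_Rhythm, ref$v_Rhythm$values, tolerance = 1e-10)
  expect_equal(out$v_dRhythm, ref$v_dRhythm$values, tolerance = 1e-10)
  expect_equal(out$v_VCT, ref$v_VCT$values, tolerance = 1e-10)
})
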