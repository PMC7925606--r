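test_that("arterial generator hits the mean-pressure identity per beat", {
  gen <- generate_arterial_bp(quiet_bp(duration = 120), seed = 4)
  tr <- head(gen$truth, -1)  # final beat may be truncated
  expect_true(all(abs(tr$mBP - (80 + 40 / 3)) < 0.1))
  expect_equal(nrow(tr), 119, tolerance = 2)
  # a +20 mmHg step moves the per-beat truth by exactly the step
  bp <- quiet_bp(duration = 120)
  bp$events <- list(list(type = "step", onset = 60, magnitude = 20))
  g2 <- generate_arterial_bp(bp, seed = 4)
  before <- g2$truth$mBP[g2$truth$t_onset < 55]
  after <- g2$truth$mBP[g2$truth$t_onset > 65 & g2$truth$t_onset < 115]
  expect_equal(mean(after) - mean(before), 20, tolerance = 0.1)
})

test_that("respiratory modulation appears at its frequency in beat means", {
  bp <- bp_trajectory_config(duration = 240, resp = list(freq = 0.25,
                                                         depth = 4),
                             mayer = list(freq = 0.1, depth = 0),
                             hr_jitter_sd = 0)
  gen <- generate_arterial_bp(bp, seed = 6)
  tr <- head(gen$truth, -1)
  # beat-mBP series resampled on a uniform grid, spectral peak at 0.25 Hz
  t_grid <- seq(5, 230, by = 0.25)
  m <- approx(tr$t_onset, tr$mBP - mean(tr$mBP), xout = t_grid)$y
  X <- Mod(fft(m))[1:(length(m) %/% 2)]
  f <- (seq_along(X) - 1) / (length(m) * 0.25)
  keep <- f > 0.03
  expect_equal(f[keep][which.max(X[keep])], 0.25, tolerance = 0.05)
})

test_that("arctangent transfer: asymptotes, midpoint, monotonicity, tone", {
  cfg0 <- pv_model_config(center_offset = 0)
  # far above systolic pressure all blood is squeezed out, any tone
  expect_equal(pv_transfer(90, 5000, 0, cfg0), cfg0$v_high,
               tolerance = 1e-3)
  expect_equal(pv_transfer(90, 5000, 1, cfg0), cfg0$v_high,
               tolerance = 1e-3)
  # symmetric configuration: p_c = p_a sits at the midpoint (inflection)
  v_low <- cfg0$v_low0 + cfg0$tone_gain * 0.3
  expect_equal(pv_transfer(90, 90, 0.3, cfg0),
               (v_low + cfg0$v_high) / 2, tolerance = 1e-12)
  # strictly increasing in contact pressure
  p <- seq(0, 250, by = 1)
  v <- pv_transfer(90, p, 0.3, pv_model_config())
  expect_true(all(diff(v) > 0))
  # vasoconstriction raises the light level at a fixed working point
  expect_gt(pv_transfer(120, 90, 0.8, pv_model_config()),
            pv_transfer(120, 90, 0.2, pv_model_config()))
  expect_error(pv_transfer(90, 90, 1.5, cfg0), "tone")
})

test_that("tone and pressure changes move the baseline in opposite ways", {
  pv <- pv_model_config()
  v_base <- balanced_v(pv)
  # vasoconstriction at constant pressure: light goes up
  expect_gt(balanced_v(pv, tone = 0.6), v_base)
  # a blood-pressure rise at fixed contact pressure: light goes down
  tpl <- pulse_template()
  pa_hi <- 90 + 40 * tpl$s  # dBP raised 10
  v_hi <- mean(pv_transfer(pa_hi, 80 + 40 / 3, 0.3, pv))
  expect_lt(v_hi, v_base)
})

test_that("beat volume balance vanishes at true mean pressure, signs flip", {
  pv <- pv_model_config()
  fb <- filter_bank_config()
  mBP <- 80 + 40 / 3
  v0 <- balanced_v(pv)
  res <- sapply(c(-15, 0, 15), function(off) {
    cl <- sim_clamped_v(mBP + off, quiet_bp(duration = 30), pv)
    dec <- decompose(cl$v, fb, init_filter_states(v0, fb))
    # early beats, before the washout absorbs the offset
    beats <- detect_beats(dec$v_Pulse)
    beats <- beats[beats$t_end > 3 & beats$t_end < 10, ]
    mean(vapply(seq_len(nrow(beats)), function(b)
      beat_volume_integral(dec$v_VCT, beats$t_onset[b], beats$t_end[b]), 0))
  })
  amp <- {
    cl <- sim_clamped_v(mBP, quiet_bp(duration = 30), pv)
    dec <- decompose(cl$v, fb, init_filter_states(v0, fb))
    max(dec$v_Pulse$values[1000:5000]) - min(dec$v_Pulse$values[1000:5000])
  }
  expect_lt(res[1], 0)                    # fat pulses below mBP
  expect_gt(res[3], 0)                    # spiky pulses above mBP
  expect_lt(abs(res[2]) / amp, 0.01)      # balanced at mBP
})

test_that("fat/spiky labels follow the pressure offset", {
  pv <- pv_model_config()
  tpl <- pulse_template()
  pa <- 80 + 40 * tpl$s
  mBP <- mean(pa)
  v_bal <- mean(pv_transfer(pa, mBP, 0.3, pv))
  lab_lo <- fat_spiky_check(pv_transfer(pa, mBP - 15, 0.3, pv), v_bal)
  lab_eq <- fat_spiky_check(pv_transfer(pa, mBP, 0.3, pv), v_bal)
  lab_hi <- fat_spiky_check(pv_transfer(pa, mBP + 15, 0.3, pv), v_bal)
  expect_equal(as.character(lab_lo), "fat")
  expect_lt(attr(lab_lo, "integral"), 0)
  expect_equal(as.character(lab_eq), "balanced")
  expect_equal(as.character(lab_hi), "spiky")
  expect_gt(attr(lab_hi, "integral"), 0)
})

test_that("actuator slews, holds and quantizes", {
  fs <- 250
  # unquantized: a +10 step at 30 mmHg/s completes in exactly 1/3 s
  act0 <- actuator_config(resolution = 0, delay = 0)
  cmd <- sampled_signal(c(rep(50, fs), rep(60, 2 * fs)), fs = fs,
                        unit = "mmHg")
  ap <- actuate(cmd, act0)
  reach <- which(ap$values >= 60 - 1e-9)[1]
  expect_equal((reach - fs) / fs, 1 / 3, tolerance = 0.02)
  # constant command: applied constant (zero motion duty cycle)
  hold <- actuate(sampled_signal(rep(80, fs), fs = fs, unit = "mmHg"),
                  actuator_config())
  expect_equal(diff(range(hold$values[10:fs])), 0)
  # sinusoid faster than the slew: output is slope-limited
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  fastcmd <- sampled_signal(100 + 50 * sin(2 * pi * 0.5 * t), fs = fs,
                            unit = "mmHg")
  apf <- actuate(fastcmd, act0)
  expect_lt(max(abs(diff(apf$values))) * fs, 30 + 1e-9)
  expect_gt(max(abs(diff(apf$values))) * fs, 29)  # actually slew-limited
  # quantized default: windowed rate never exceeds the configured maximum
  apq <- actuate(fastcmd, actuator_config())
  expect_lte(max_slew_rate(apq, 1), 30)
  expect_true(all(abs(apq$values / 0.1 -
                        round(apq$values / 0.1)) < 1e-9))
  expect_error(actuate(sampled_signal(rep(300, 10), fs = fs,
                                      unit = "mmHg"),
                       actuator_config()),
               "range")
})

test_that("noise injection hits the requested signal-to-noise ratio", {
  cl <- sim_clamped_v(90, quiet_bp(duration = 60))
  same <- add_noise_artifacts(cl$v, snr_db = Inf)
  expect_equal(same$values, cl$v$values)
  noisy <- add_noise_artifacts(cl$v, snr_db = 20, seed = 2)
  emp_snr <- 10 * log10(var(cl$v$values - mean(cl$v$values)) /
                          var(noisy$values - cl$v$values))
  expect_lt(abs(emp_snr - 20), 1)
  burst <- add_noise_artifacts(cl$v, artifact_rate = 3, seed = 2)
  expect_false(is.null(attr(burst, "artifact_windows")))
})

test_that("closed loop is bit-identical under the same seed", {
  scn <- scenario("det", duration = 250)
  r1 <- run_closed_loop(scn, seed = 11)
  r2 <- run_closed_loop(scn, seed = 11)
  expect_identical(r1$signals$p_c$values, r2$signals$p_c$values)
  expect_identical(r1$signals$v$values, r2$signals$v$values)
  expect_identical(r1$beats, r2$beats)
  r3 <- run_closed_loop(scn, seed = 12)
  expect_false(identical(r1$signals$p_c$values, r3$signals$p_c$values))
})
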