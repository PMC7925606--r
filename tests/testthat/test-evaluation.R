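test_that("window averaging counts and validity handling", {
  t <- seq(0, 2700 - 1, by = 1)  # 45 min at 1 Hz
  ser <- paired_series("s1", t, test = rnorm(length(t)) + 90,
                       ref = rnorm(length(t)) + 90)
  avg <- average_windows(ser, 10)
  expect_equal(nrow(avg), 270)
  # constant series stays constant
  serc <- paired_series("s1", seq(0, 99), rep(5, 100), rep(5, 100))
  avgc <- average_windows(serc, 10)
  expect_equal(nrow(avgc), floor(100 / 10))
  expect_true(all(avgc$test == 5))
  # one invalid minute drops its windows
  bad <- t >= 600 & t < 660
  ser2 <- paired_series("s1", t, ser$test, ser$ref, valid = !bad)
  avg2 <- average_windows(ser2, 10)
  expect_equal(nrow(avg2), 270 - 6)
})

test_that("simple Bland-Altman matches the textbook formulas exactly", {
  set.seed(31)
  d <- rnorm(200, 1.5, 3)
  ser <- paired_series("s", seq_along(d), test = 90 + d, ref = rep(90, 200))
  ba <- bland_altman(ser, repeated = FALSE)
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  # identity and pure-offset edge cases
  b0 <- bland_altman(paired_series("s", 1:50, 1:50, 1:50),
                     repeated = FALSE)
  expect_equal(b0$bias, 0)
  expect_equal(b0$sd, 0)
  b5 <- bland_altman(paired_series("s", 1:50, (1:50) + 5, 1:50),
                     repeated = FALSE)
  expect_equal(b5$bias, 5)
  expect_equal(b5$sd, 0)
  expect_equal(c(b5$loa_low, b5$loa_high), c(5, 5))
})

test_that("repeated-measures Bland-Altman recovers variance components", {
  # two subjects with fixed offsets +2 / -2 and within-subject noise sd 1.
  # For fixed effects o_i, E[MSB] = n * sum((o - mean(o))^2) / (k - 1) +
  # sigma_w^2, so the variance-component estimator targets
  # sigma_b^2 = sum(n (o - mean(o))^2) / ((k - 1) m0) = 8 here (the k - 1
  # divisor on two effects of +/-2), giving total sd sqrt(8 + 1) = 3.
  set.seed(17)
  n <- 400
  mk <- function(id, off) paired_series(id, seq_len(n),
                                        test = 90 + off + rnorm(n, 0, 1),
                                        ref = rep(90, n))
  ser <- rbind(mk("a", 2), mk("b", -2))
  ba <- bland_altman(structure(ser, class = c("paired_series",
                                              "data.frame")))
  expect_true(ba$repeated)
  analytic <- sqrt(8 + 1^2)
  expect_lt(abs(ba$sd - analytic) / analytic, 0.15)
  expect_equal(sort(names(ba$per_subject)), c("a", "b"))
  # single subject falls back with a warning
  expect_warning(bland_altman(mk("solo", 0)), "single subject")
})

test_that("pooled repeated=FALSE equals the simple method on grouped data", {
  set.seed(23)
  ser <- rbind(paired_series("a", 1:30, rnorm(30, 91), rnorm(30, 90)),
               paired_series("b", 1:30, rnorm(30, 89), rnorm(30, 90)))
  ser <- structure(ser, class = c("paired_series", "data.frame"))
  ba <- bland_altman(ser, repeated = FALSE)
  d <- ser$test - ser$ref
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd, sd(d), tolerance = 1e-12)
})

test_that("concordance of paired deltas", {
  # identical series agree everywhere
  x <- cumsum(rnorm(200))
  cc <- concordance_5min(x, x, step = 10, lag = 300)
  expect_equal(cc$concordance, 1)
  expect_equal(cc$n, length(x) - 30)
  # a pure sign flip of the deltas disagrees everywhere
  cf <- concordance_5min(-x, x, step = 10, lag = 300)
  expect_equal(cf$concordance, 0)
  # invariant to adding the same constant to both series
  c2 <- concordance_5min(x + 50, x + 50, step = 10, lag = 300)
  expect_equal(c2$concordance, 1)
  expect_error(concordance_5min(x[1:20], x[1:20]), "lag")
})

test_that("concordance matches the bivariate-normal orthant probability", {
  # reference deltas N(0, 5^2); test = reference + N(0, 2^2)
  set.seed(41)
  n <- 10000
  d_ref <- rnorm(n, 0, 5)
  d_test <- d_ref + rnorm(n, 0, 2)
  cc <- concordance_deltas(d_test, d_ref)
  rho <- 5 / sqrt(5^2 + 2^2)
  p_analytic <- 0.5 + asin(rho) / pi
  expect_equal(cc$concordance, p_analytic, tolerance = 0.02 / p_analytic)
  expect_equal(cc$n, n)
  # exclusion zone removes small deltas before counting
  cz <- concordance_deltas(d_test, d_ref, exclusion = 3)
  expect_lt(cz$n, n)
  expect_gt(cz$concordance, cc$concordance)
})

test_that("actuator speed statistics per beat and per second", {
  fs <- 250
  # constant pressure: all statistics zero
  pc <- sampled_signal(rep(90, fs * 20), fs = fs, unit = "mmHg")
  beats <- data.frame(t = seq(1, 19), PI = rep(1, 19))
  s0 <- actuator_speed_stats(pc, beats)
  expect_equal(s0$median_per_beat, 0)
  expect_equal(s0$max_per_s, 0)
  # +2 mmHg per 1-s beat: median = max = 2 mmHg/beat = 2 mmHg/s
  ramp <- sampled_signal(2 * seq(0, 20 - 1 / fs, by = 1 / fs), fs = fs,
                         unit = "mmHg")
  s2 <- actuator_speed_stats(ramp, beats)
  expect_equal(s2$median_per_beat, 2, tolerance = 1e-9)
  expect_equal(s2$max_per_beat, 2, tolerance = 1e-9)
  expect_equal(s2$median_per_s, 2, tolerance = 1e-9)
  expect_error(actuator_speed_stats(pc, beats[1, ]), ">= 2")
})

test_that("power budget totals", {
  pb <- power_budget()
  expect_equal(pb$total_mW, 58.7)
  expect_equal(pb$energy_24h_mWh, 1408.8)
  expect_equal(pb$energy_24h_mWh, pb$total_mW * 24)
  # empty component list
  p0 <- power_budget(setNames(numeric(0), character(0)))
  expect_equal(p0$total_mW, 0)
  # data-frame interface
  pdf <- power_budget(data.frame(name = c("a", "b"),
                                 power_mW = c(1.25, 2.5)))
  expect_equal(pdf$total_mW, 3.75)
  expect_error(power_budget(c(x = -1)), ">= 0")
})
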