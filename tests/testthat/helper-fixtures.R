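# Shared fixtures: all synthetic, built in code at test time.

# arterial trajectory with no rhythms and no beat-period jitter
quiet_bp <- function(duration = 60, sbp = 120, dbp = 80, hr = 60) {
  bp_trajectory_config(duration = duration, hr = hr, sbp = sbp, dbp = dbp,
                       resp = list(freq = 0.25, depth = 0),
                       mayer = list(freq = 0.1, depth = 0),
                       hr_jitter_sd = 0)
}

# open-loop light signal at a fixed (clamped) contact pressure
sim_clamped_v <- function(p_clamp, bp = quiet_bp(), pv = pv_model_config(),
                          tone = 0.3, fs = 250, noise_sd = 0, seed = 1) {
  gen <- generate_arterial_bp(bp, fs = fs, seed = seed)
  v <- pv_transfer(gen$p_a$values, p_clamp, tone, pv)
  if (noise_sd > 0) {
    set.seed(seed + 7L)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  list(v = sampled_signal(v, fs = fs, unit = "dimensionless", label = "v"),
       p_a = gen$p_a, truth = gen$truth)
}

# ground-truth balanced light level: beat-mean of v when p_c = mBP
balanced_v <- function(pv = pv_model_config(), sbp = 120, dbp = 80,
                       tone = 0.3, tpl = pulse_template()) {
  pa <- dbp + (sbp - dbp) * tpl$s
  mean(pv_transfer(pa, mean(pa), tone, pv))
}

# synthetic pulse train in the v_Pulse convention (systole = trough),
# returns the signal and the true systole times
synth_pulse_train <- function(rate_hz = 1, duration = 60, fs = 250,
                              amp = 0.5, amp_scale = NULL) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  period <- 1 / rate_hz
  phase <- (t %% period) / period
  shape <- -exp(-(phase - 0.25)^2 / (2 * 0.07^2)) +
    0.45 * exp(-(phase - 0.6)^2 / (2 * 0.12^2))
  beat_id <- floor(t / period)
  a <- if (is.null(amp_scale)) rep(amp, length(t)) else
    amp * amp_scale[pmin(beat_id + 1, length(amp_scale))]
  x <- a * shape
  x <- x - mean(x)
  sys_t <- (seq_len(floor(duration * rate_hz)) - 1) * period + 0.25 * period
  list(signal = sampled_signal(x, fs = fs, unit = "dimensionless",
                               label = "v_Pulse"),
       sys_t = sys_t)
}

# beat-detection F1 against true systole times
beat_f1 <- function(detected_t, true_t, tol = 0.15) {
  if (!length(detected_t)) return(0)
  tp <- sum(vapply(true_t, function(tt) any(abs(detected_t - tt) <= tol),
                   TRUE))
  prec <- tp / length(detected_t)
  rec <- tp / length(true_t)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# sinusoid gain of one decompose output, measured in steady state
measured_gain <- function(f, output, cfg = filter_bank_config(),
                          cycles = 10, settle_s = NULL) {
  fs <- cfg$fs
  if (is.null(settle_s)) settle_s <- max(60, 3 / f)
  dur <- settle_s + cycles / f
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  dec <- decompose(sampled_signal(x, fs = fs), cfg,
                   states = init_filter_states(0, cfg))
  y <- dec[[output]]$values
  keep <- t >= settle_s
  2 * sqrt(mean(y[keep] * sin(2 * pi * f * t[keep]))^2 +
             mean(y[keep] * cos(2 * pi * f * t[keep]))^2)
}
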