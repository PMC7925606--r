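# Synthetic finger hemodynamics: pulsatile arterial pressure with
# respiratory and Mayer-wave modulation, a vasomotor tone trajectory, an
# S-shaped arctangent pressure-volume/light transfer and a slew-rate-limited
# quantized actuator.

# ---- pulse template ---------------------------------------------------------

#' Arterial pulse template
#'
#' Normalized single-beat shape `s(phase)` on `[0, 1)` with `s` in `[0, 1]`
#' (0 = diastolic, 1 = systolic): a Gaussian systolic upstroke, an
#' exponential decay and a dicrotic bump. The decay time constant is solved
#' so that `mean(s) = 1/3` exactly, making the beat's time-averaged pressure
#' equal `dBP + (sBP - dBP) / 3`.
#'
#' @param n Number of phase points.
#' @param t_peak,sig_up Systolic peak position and upstroke width (phase).
#' @param a_dicrotic,t_dicrotic,sig_dicrotic Dicrotic bump amplitude,
#'   position and width.
#' @param mean_target Target dwell mean (default 1/3).
#' @return Object of class `pulse_template`: list with `phase`, `s` and the
#'   solved decay constant `tau`.
#' @export
pulse_template <- function(n = 1024, t_peak = 0.13, sig_up = 0.055,
                           a_dicrotic = 0.18, t_dicrotic = 0.42,
                           sig_dicrotic = 0.06, mean_target = 1 / 3) {
  u <- (seq_len(n) - 0.5) / n
  shape <- function(tau) {
    up <- exp(-(u - t_peak)^2 / (2 * sig_up^2))
    dec <- exp(-pmax(u - t_peak, 0) / tau) * (u > t_peak)
    s <- ifelse(u <= t_peak, up, dec) +
      a_dicrotic * exp(-(u - t_dicrotic)^2 / (2 * sig_dicrotic^2)) *
      (u > t_peak)
    (s - min(s)) / (max(s) - min(s))
  }
  tau <- uniroot(function(tt) mean(shape(tt)) - mean_target,
                 c(0.02, 3), tol = 1e-12)$root
  structure(list(phase = u, s = shape(tau), tau = tau), class = "pulse_template")
}

template_at <- function(tpl, phase) {
  # periodic linear interpolation of the template
  approx(c(tpl$phase, 1 + tpl$phase[1]), c(tpl$s, tpl$s[1]),
         xout = phase %% 1, rule = 2)$y
}

# ---- BP trajectory ----------------------------------------------------------

#' Blood-pressure trajectory configuration
#'
#' Describes a beat-to-beat arterial pressure scenario: baseline systolic
#' and diastolic pressures, a (piecewise-constant) heart-rate profile,
#' respiratory and Mayer-wave modulation and step / ramp / Valsalva-like
#' events. The per-beat mean pressure equals `dBP + (sBP - dBP) / 3` by
#' construction of the pulse template (checked within `mbp_tolerance`).
#'
#' @param duration Duration in seconds.
#' @param hr Heart rate in bpm: scalar or `data.frame(t, bpm)` piecewise
#'   profile.
#' @param sbp,dbp Baseline systolic / diastolic pressure (mmHg).
#' @param resp List `list(freq, depth)`: respiratory modulation, `freq` in
#'   Hz (0.15-0.4), `depth` = additive mBP excursion amplitude in mmHg.
#' @param mayer List `list(freq, depth)`: Mayer-wave modulation (~0.1 Hz).
#' @param events List of events, each
#'   `list(type = "step" | "ramp" | "valsalva", onset, magnitude, duration)`
#'   (`duration` for ramp / valsalva).
#' @param hr_jitter_sd Multiplicative beat-to-beat heart-period jitter SD.
#' @param mbp_tolerance Allowed deviation of per-beat mean pressure from
#'   `dBP + PP/3` (mmHg).
#' @param template A [pulse_template].
#' @return Object of class `bp_trajectory_config`.
#' @export
bp_trajectory_config <- function(duration = 300, hr = 60, sbp = 120,
                                 dbp = 80,
                                 resp = list(freq = 0.25, depth = 0),
                                 mayer = list(freq = 0.1, depth = 0),
                                 events = list(), hr_jitter_sd = 0.02,
                                 mbp_tolerance = 2,
                                 template = pulse_template()) {
  stopifnot(dbp < sbp, duration > 0)
  if (resp$depth > 0 && (resp$freq < 0.15 || resp$freq > 0.4))
    stop("respiratory frequency must be in [0.15, 0.4] Hz")
  structure(list(duration = duration, hr = hr, sbp = sbp, dbp = dbp,
                 resp = resp, mayer = mayer, events = events,
                 hr_jitter_sd = hr_jitter_sd,
                 mbp_tolerance = mbp_tolerance, template = template),
            class = "bp_trajectory_config")
}

event_offset <- function(events, t) {
  # summed additive mBP offset of all events at times t
  off <- numeric(length(t))
  for (ev in events) {
    m <- ev$magnitude
    if (ev$type == "step") {
      off <- off + m * (t >= ev$onset)
    } else if (ev$type == "ramp") {
      d <- ev$duration
      off <- off + m * pmin(pmax((t - ev$onset) / d, 0), 1)
    } else if (ev$type == "valsalva") {
      # four-phase excursion: brief rise, fall below baseline,
      # overshooting recovery, return to baseline
      d <- if (is.null(ev$duration)) 25 else ev$duration
      key_t <- ev$onset + d * c(0, 0.1, 0.2, 0.5, 0.65, 0.85, 1)
      key_v <- m * c(0, 0.6, 0.1, -1, 0.8, 0.2, 0)
      off <- off + ifelse(t < ev$onset | t > ev$onset + d, 0,
                          approx(key_t, key_v, xout = t, rule = 2)$y)
    } else stop("unknown event type: ", ev$type)
  }
  off
}

hr_at <- function(hr, t) {
  if (is.data.frame(hr)) {
    approx(hr$t, hr$bpm, xout = t, method = "constant", rule = 2)$y
  } else rep(hr, length(t))
}

#' Generate a pulsatile arterial pressure signal
#'
#' Builds the beat-by-beat waveform from the pulse template shaped by
#' per-beat systolic/diastolic values (baselines plus rhythm modulations
#' plus events), and returns the per-beat ground truth.
#'
#' @param cfg A [bp_trajectory_config].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the beat-period jitter and rhythm phases.
#' @return List with `p_a` (a mmHg [sampled_signal]) and `truth`, a data
#'   frame of per-beat `t_onset`, `t_end`, `PI`, `sBP`, `dBP`, `mBP`
#'   (actual time-average of the generated samples).
#' @export
generate_arterial_bp <- function(cfg, fs = 250, seed = 1) {
  stopifnot(inherits(cfg, "bp_trajectory_config"))
  set.seed(seed)
  ph_resp <- runif(1, 0, 2 * pi)
  ph_mayer <- runif(1, 0, 2 * pi)
  n_total <- round(cfg$duration * fs)
  # beat grid
  t <- 0
  onsets <- numeric(0)
  periods <- numeric(0)
  while (t < cfg$duration) {
    T_b <- 60 / hr_at(cfg$hr, t)
    if (cfg$hr_jitter_sd > 0)
      T_b <- T_b * exp(rnorm(1, 0, cfg$hr_jitter_sd))
    T_b <- max(T_b, 0.3)
    onsets <- c(onsets, t)
    periods <- c(periods, T_b)
    t <- t + T_b
  }
  nb <- length(onsets)
  mod <- function(tt)
    cfg$resp$depth * sin(2 * pi * cfg$resp$freq * tt + ph_resp) +
    cfg$mayer$depth * sin(2 * pi * cfg$mayer$freq * tt + ph_mayer) +
    event_offset(cfg$events, tt)
  off_b <- mod(onsets)
  sbp_b <- cfg$sbp + off_b
  dbp_b <- cfg$dbp + off_b
  i_on <- pmin(round(onsets * fs) + 1L, n_total)
  i_end <- c(i_on[-1] - 1L, n_total)
  vals <- vector("list", nb)
  mbp_b <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- i_on[b]:i_end[b]
    phase <- (idx - i_on[b]) / (fs * periods[b])
    s <- template_at(cfg$template, pmin(phase, 1))
    pb <- dbp_b[b] + (sbp_b[b] - dbp_b[b]) * s
    vals[[b]] <- pb
    mbp_b[b] <- mean(pb)
  }
  p_a <- sampled_signal(unlist(vals)[1:n_total], fs = fs, unit = "mmHg",
                        label = "p_a")
  truth <- data.frame(t_onset = (i_on - 1L) / fs, t_end = i_end / fs,
                      PI = periods, sBP = sbp_b, dBP = dbp_b, mBP = mbp_b)
  dev <- abs(truth$mBP - (truth$dBP + (truth$sBP - truth$dBP) / 3))
  dev <- dev[-length(dev)]  # final beat may be truncated by the duration
  if (length(dev) && any(dev > cfg$mbp_tolerance))
    warning("per-beat mBP deviates from dBP + PP/3 beyond tolerance")
  list(p_a = p_a, truth = truth)
}

# ---- pressure-volume / light transfer ---------------------------------------

#' Pressure-volume transfer configuration
#'
#' The transmitted-light signal follows an S-shaped arctangent of the
#' pressure difference between contact pressure and arterial pressure.
#' `v_high` is the upper light asymptote (all blood squeezed out,
#' independent of tone); the lower asymptote rises with vasoconstriction
#' (`v_low0 + tone_gain * tone`). `center_offset` shifts the arctangent
#' center along the transmural-pressure axis: compliance is maximal at a
#' slightly positive transmural pressure, which places the oscillometric
#' amplitude maximum at mean pressure (`dBP + PP/3`) rather than at the
#' systolic/diastolic midpoint; the default `-PP/6` for a 40 mmHg reference
#' pulse pressure is `-6.67` mmHg. Set it to 0 for a symmetric curve
#' centered at `p_c = p_a`.
#'
#' @param v_high Upper light asymptote (dimensionless).
#' @param v_low0 Lower asymptote at full dilation (tone 0).
#' @param tone_gain Increase of the lower asymptote per unit tone.
#' @param w Transition width in mmHg.
#' @param center_offset Arctangent center on the `p_c - p_a` axis (mmHg).
#' @param w_tone_narrowing Fractional narrowing of `w` at tone 1 (0 = no
#'   tone dependence of the width).
#' @return Object of class `pv_model_config`.
#' @export
pv_model_config <- function(v_high = 1, v_low0 = 0.10, tone_gain = 0.25,
                            w = 15, center_offset = -40 / 6,
                            w_tone_narrowing = 0) {
  stopifnot(v_low0 < v_high, v_low0 + tone_gain < v_high, w > 0,
            w_tone_narrowing >= 0, w_tone_narrowing < 1)
  structure(list(v_high = v_high, v_low0 = v_low0, tone_gain = tone_gain,
                 w = w, center_offset = center_offset,
                 w_tone_narrowing = w_tone_narrowing),
            class = "pv_model_config")
}

#' S-shaped pressure-to-light transfer
#'
#' @param p_a Arterial pressure sample(s), mmHg.
#' @param p_c Contact pressure sample(s), mmHg.
#' @param tone Vasomotor tone in `[0, 1]` (0 = max dilation).
#' @param cfg A [pv_model_config].
#' @return Dimensionless light value(s); strictly increasing in `p_c`,
#'   upper asymptote independent of tone.
#' @export
#' @examples
#' cfg <- pv_model_config(center_offset = 0)
#' pv_transfer(90, 90, 0.3, cfg)  # midpoint of (v_low, v_high)
pv_transfer <- function(p_a, p_c, tone, cfg = pv_model_config()) {
  if (any(tone < 0 | tone > 1)) stop("tone must be in [0, 1]")
  v_low <- cfg$v_low0 + cfg$tone_gain * tone
  w <- cfg$w * (1 - cfg$w_tone_narrowing * tone)
  v_low + (cfg$v_high - v_low) *
    (atan((p_c - p_a - cfg$center_offset) / w) + pi / 2) / pi
}

#' Classify a beat's pulse shape as fat, spiky or balanced
#'
#' A beat recorded with contact pressure below mean pressure is "fat" (the
#' negative half-wave relative to the balanced light level dominates, beat
#' integral < 0); above mean pressure it is "spiky" (integral > 0).
#'
#' @param v_beat Light samples over one beat (dimensionless).
#' @param v_balanced Balanced reference light level (beat-mean of `v` when
#'   contact pressure equals mean pressure).
#' @param tol_frac Fraction of the beat's pulse amplitude below which the
#'   integral counts as balanced.
#' @return One of `"fat"`, `"balanced"`, `"spiky"`, with the normalized
#'   beat integral attached as attribute `integral`.
#' @export
fat_spiky_check <- function(v_beat, v_balanced, tol_frac = 0.02) {
  amp <- max(v_beat) - min(v_beat)
  I <- mean(v_beat - v_balanced)
  lab <- if (abs(I) <= tol_frac * amp) "balanced"
         else if (I < 0) "fat" else "spiky"
  structure(lab, integral = I)
}

# ---- actuator ---------------------------------------------------------------

#' Actuator configuration
#'
#' @param max_rate Maximum pressure slew rate in mmHg/s (default 30).
#' @param resolution Step resolution in mmHg (default 0.1; 0 disables
#'   quantization).
#' @param delay Transport delay in seconds (default 0.02).
#' @param range Length-2 pressure range in mmHg.
#' @return Object of class `actuator_config`.
#' @export
actuator_config <- function(max_rate = 30, resolution = 0.1, delay = 0.02,
                            range = c(0, 250)) {
  stopifnot(max_rate > 0, resolution >= 0, delay >= 0, range[1] < range[2])
  structure(list(max_rate = max_rate, resolution = resolution,
                 delay = delay, range = range), class = "actuator_config")
}

#' Apply the actuator model to a pressure command
#'
#' Delays, slew-limits and quantizes the command. With quantization enabled
#' the internal continuous trajectory is slewed at `0.98 * max_rate` so
#' that the applied pressure change over any window of one beat or longer
#' stays within `max_rate`, quantization steps included.
#'
#' @param command A mmHg [sampled_signal] (or numeric vector with `fs`).
#' @param cfg An [actuator_config].
#' @param fs Sampling rate, taken from `command` if it is a signal.
#' @param init Initial applied pressure (defaults to the clamped first
#'   command sample).
#' @return Applied contact pressure as a [sampled_signal].
#' @export
actuate <- function(command, cfg = actuator_config(), fs = NULL,
                    init = NULL) {
  if (inherits(command, "sampled_signal")) {
    fs <- command$fs
    x <- command$values
    t0 <- command$t0
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(command)
    t0 <- 0
  }
  if (any(x < cfg$range[1] - 1e-9 | x > cfg$range[2] + 1e-9))
    stop("actuate: command outside actuator range")
  nd <- round(cfg$delay * fs)
  if (nd > 0) x <- c(rep(x[1], nd), x)[seq_along(x)]
  if (is.null(init)) init <- min(max(x[1], cfg$range[1]), cfg$range[2])
  rate <- if (cfg$resolution > 0) 0.98 * cfg$max_rate else cfg$max_rate
  y <- slew_quantize_cpp(x, init, rate / fs, cfg$resolution,
                         cfg$range[1], cfg$range[2])
  sampled_signal(y, fs = fs, t0 = t0, unit = "mmHg", label = "p_c")
}

# ---- noise and artifacts ----------------------------------------------------

#' Add measurement noise and motion artifacts to a light signal
#'
#' Adds white noise at a configured signal-to-noise ratio (relative to the
#' variance of the mean-removed signal) and optional short high-amplitude
#' motion-artifact bursts.
#'
#' @param v A dimensionless [sampled_signal].
#' @param snr_db Signal-to-noise ratio in dB; `Inf` adds nothing.
#' @param artifact_rate Expected artifact bursts per minute.
#' @param artifact_duration Length-2 range of burst durations in seconds.
#' @param artifact_gain Burst amplitude as a multiple of the signal SD.
#' @param seed Integer seed.
#' @return The noisy [sampled_signal]; artifact windows (start/end times)
#'   are attached as attribute `artifact_windows`.
#' @export
add_noise_artifacts <- function(v, snr_db = Inf, artifact_rate = 0,
                                artifact_duration = c(0.3, 1),
                                artifact_gain = 8, seed = 1) {
  stopifnot(inherits(v, "sampled_signal"))
  set.seed(seed)
  x <- v$values
  n <- length(x)
  sig_sd <- sd(x - mean(x))
  if (is.finite(snr_db)) {
    x <- x + rnorm(n, 0, sig_sd * 10^(-snr_db / 20))
  }
  windows <- NULL
  if (artifact_rate > 0) {
    k <- rpois(1, artifact_rate * n / v$fs / 60)
    if (k > 0) {
      starts <- sort(runif(k, 0, n / v$fs - max(artifact_duration)))
      durs <- runif(k, artifact_duration[1], artifact_duration[2])
      windows <- cbind(start = starts, end = starts + durs)
      for (i in seq_len(k)) {
        idx <- (round(starts[i] * v$fs) + 1):(round((starts[i] + durs[i]) * v$fs))
        idx <- idx[idx >= 1 & idx <= n]
        x[idx] <- x[idx] + rnorm(length(idx), 0, artifact_gain * sig_sd)
      }
    }
  }
  out <- sampled_signal(x, fs = v$fs, t0 = v$t0, unit = v$unit,
                        label = v$label)
  attr(out, "artifact_windows") <- windows
  out
}
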