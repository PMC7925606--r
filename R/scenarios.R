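# Seeded simulation scenarios: blood-pressure trajectory, vasomotor tone
# trajectory, pressure-volume model, noise and artifacts.

#' Simulation scenario
#'
#' Bundles everything [run_closed_loop()] needs: the arterial pressure
#' trajectory, the vasomotor tone trajectory (piecewise ramps smoothed by a
#' first-order lag), the pressure-volume model and the noise/artifact
#' settings.
#'
#' @param name Scenario name.
#' @param duration Duration in seconds.
#' @param hr Heart rate (bpm) scalar or `data.frame(t, bpm)`.
#' @param sbp,dbp Baseline pressures (mmHg).
#' @param resp,mayer Rhythm modulations, `list(freq, depth)` (depth in mmHg).
#' @param events BP events (see [bp_trajectory_config()]).
#' @param tone_base Baseline vasomotor tone in `[0, 1]`.
#' @param tone_events List of `list(onset, duration, target)` tone ramps.
#' @param tone_tau Tone first-order lag time constant (s).
#' @param pv A [pv_model_config()].
#' @param noise_sd Additive white-noise SD on the light signal.
#' @param artifact_rate Motion-artifact bursts per minute.
#' @param seed_offset Added to the run seed so each scenario in a suite has
#'   its own stream.
#' @return Object of class `vct_scenario`.
#' @export
scenario <- function(name = "scenario", duration = 1800, hr = 60,
                     sbp = 120, dbp = 80,
                     resp = list(freq = 0.25, depth = 2),
                     mayer = list(freq = 0.1, depth = 1),
                     events = list(), tone_base = 0.3,
                     tone_events = list(), tone_tau = 10,
                     pv = pv_model_config(), noise_sd = 0.002,
                     artifact_rate = 0, seed_offset = 0L) {
  stopifnot(tone_base >= 0, tone_base <= 1)
  structure(list(name = name, duration = duration, hr = hr, sbp = sbp,
                 dbp = dbp, resp = resp, mayer = mayer, events = events,
                 tone_base = tone_base, tone_events = tone_events,
                 tone_tau = tone_tau, pv = pv, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 seed_offset = as.integer(seed_offset)),
            class = "vct_scenario")
}

#' Vasomotor tone trajectory of a scenario
#'
#' Piecewise-linear commanded tone smoothed by a first-order lag.
#'
#' @param scn A [scenario()].
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of tone values in `[0, 1]`.
#' @export
tone_trajectory <- function(scn, n, fs = 250) {
  t <- (seq_len(n) - 1) / fs
  cmd <- rep(scn$tone_base, n)
  for (ev in scn$tone_events) {
    frac <- pmin(pmax((t - ev$onset) / max(ev$duration, 1 / fs), 0), 1)
    cmd <- cmd + (ev$target - scn$tone_base) * frac
  }
  cmd <- pmin(pmax(cmd, 0), 1)
  uc <- 1 - exp(-1 / (fs * scn$tone_tau))
  as.numeric(stats::filter(uc * cmd, 1 - uc, method = "recursive",
                           init = cmd[1]))
}

#' The standard scenario suite
#'
#' Ten seeded 30-min scenarios spanning the conditions the controller must
#' handle: constant pressure, +/-20 mmHg steps, slow drift,
#' respiratory-heavy and Mayer-heavy rhythms, a pure vasomotor tone ramp,
#' combined tone and pressure changes (with a Valsalva-like excursion),
#' motion artifacts, tachycardia at 120 bpm and a hypotensive range
#' (mean pressure ~55 mmHg).
#'
#' @param duration Scenario duration in seconds (default 1800).
#' @return Named list of 10 [scenario()] objects.
#' @export
standard_scenarios <- function(duration = 1800) {
  list(
    constant = scenario("constant", duration, seed_offset = 1L),
    steps = scenario("steps", duration, seed_offset = 2L,
                     events = list(
                       list(type = "step", onset = 400, magnitude = 20),
                       list(type = "step", onset = 800, magnitude = -20),
                       list(type = "step", onset = 1200, magnitude = -20),
                       list(type = "step", onset = 1500, magnitude = 20))),
    drift = scenario("drift", duration, seed_offset = 3L,
                     events = list(
                       list(type = "ramp", onset = 300, duration = 1000,
                            magnitude = 15),
                       list(type = "ramp", onset = 1400, duration = 300,
                            magnitude = -10))),
    respiratory = scenario("respiratory", duration, seed_offset = 4L,
                           resp = list(freq = 0.25, depth = 6)),
    mayer = scenario("mayer", duration, seed_offset = 5L,
                     mayer = list(freq = 0.1, depth = 5)),
    tone_ramp = scenario("tone_ramp", duration, seed_offset = 6L,
                         tone_events = list(
                           list(onset = 600, duration = 60, target = 0.7)),
                         events = list()),
    tone_bp = scenario("tone_bp", duration, seed_offset = 7L,
                       tone_events = list(
                         list(onset = 500, duration = 120, target = 0.6)),
                       events = list(
                         list(type = "step", onset = 900, magnitude = 15),
                         list(type = "valsalva", onset = 1300,
                              magnitude = 15, duration = 30))),
    artifact = scenario("artifact", duration, seed_offset = 8L,
                        noise_sd = 0.004, artifact_rate = 1),
    tachycardia = scenario("tachycardia", duration, seed_offset = 9L,
                           hr = 120, sbp = 125, dbp = 85),
    hypotension = scenario("hypotension", duration, seed_offset = 10L,
                           sbp = 75, dbp = 45)
  )
}
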