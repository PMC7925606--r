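# Closed-loop volume-control core: beat-based setpoint control, continuous
# rhythm PID, calibration of the contact pressure to a pulsatile waveform,
# hydrostatic correction and the operation-mode state machine.
#
# Feedback signs: rising blood pressure increases finger blood volume and
# DECREASES transmitted light. A fall of the beat volume integral (fat
# pulses, contact pressure below mean pressure) must RAISE the setpoint:
#   P_n = P_0 - c_BBI * sum(Vbar) - c_BBP * Vbar .
# The continuous branch keeps the rhythm-band light content near zero:
#   y_PD = c_P * v_Rhythm + c_D * v_dRhythm ;  y_I = c_I * sum(y_PD) ;
#   p_C  = P_n - y_I - y_PD .

#' Controller gains
#'
#' Beat-based and continuous control constants. All gains are >= 0; the
#' feedback signs are fixed in the control law so that a blood-pressure
#' rise (light decrease) raises the contact pressure. The defaults were
#' tuned once on the standard scenario suite and frozen (see
#' `scripts/tune_gains.R` in the source repository).
#'
#' @param c_BBI,c_BBP Beat-based integral and proportional constants
#'   (mmHg per dimensionless volume unit).
#' @param c_P,c_D Continuous proportional and differential constants.
#' @param c_I Continuous integral constant (per sample).
#' @param y_I_tau Forgetting time constant of the continuous integral in
#'   seconds (`Inf` disables the leak). The leak confines `y_I` to the
#'   rhythm band so it cannot wind up against the beat-based integral,
#'   which alone owns the long-term memory.
#' @param c_SA Shape-anchor integral constant (mmHg per unit of summed
#'   shape deviation, 0 disables). The fat/spiky shape statistic -- the
#'   beat mean of the raw light relative to the beat's extremes -- is
#'   invariant to vasomotor shifts of the lower asymptote and to amplitude
#'   scaling, and anchors the setpoint absolutely against slow drift.
#' @return Object of class `vct_gains`.
#' @export
controller_gains <- function(c_BBI = 60, c_BBP = 20, c_P = 25,
                             c_D = 1.2, c_I = 4e-4, y_I_tau = 60,
                             c_SA = 8) {
  g <- list(c_BBI = c_BBI, c_BBP = c_BBP, c_P = c_P, c_D = c_D, c_I = c_I,
            y_I_tau = y_I_tau, c_SA = c_SA)
  if (any(unlist(g) < 0)) stop("controller gains must be >= 0")
  structure(g, class = "vct_gains")
}

#' Controller state
#'
#' @param P0 Initial setpoint (mmHg), normally the oscillometric `P0`.
#' @param mode Initial operation mode.
#' @return Object of class `vct_state` with the running sums zeroed.
#' @export
controller_state <- function(P0, mode = "start") {
  stopifnot(is.finite(P0))
  structure(list(P0 = P0, Pn = P0, sum_V = 0, y_PD = 0, y_I = 0,
                 beat_count = 0L, mode = mode), class = "vct_state")
}

#' Beat volume integral
#'
#' Time-normalized integral of the volume-control signal over one beat,
#' `Vbar = (1 / PI) * integral of v_VCT dt` (trapezoidal rule on the sample
#' grid). Zero for a balanced pulse; negative for fat pulses (contact
#' pressure below mean pressure), positive for spiky ones.
#'
#' @param v_VCT The volume-control component ([sampled_signal]).
#' @param t_start,t_end Beat interval in seconds (detection to detection);
#'   `t_end - t_start` is the pulse interval and must be positive.
#' @return `Vbar`, dimensionless.
#' @export
beat_volume_integral <- function(v_VCT, t_start, t_end) {
  stopifnot(inherits(v_VCT, "sampled_signal"))
  PI_s <- t_end - t_start
  if (!is.finite(PI_s) || PI_s <= 0) stop("pulse interval must be > 0")
  fs <- v_VCT$fs
  i0 <- floor((t_start - v_VCT$t0) * fs) + 1L
  i1 <- ceiling((t_end - v_VCT$t0) * fs) + 1L
  if (i0 < 1L || i1 > length(v_VCT$values))
    stop("beat not fully inside signal")
  x <- v_VCT$values[i0:i1]
  dt <- 1 / fs
  sum((x[-1] + x[-length(x)]) / 2) * dt / PI_s
}

#' Beat-based setpoint update
#'
#' Accumulates the beat volume integral and recomputes the setpoint
#' `P_n = P_0 - c_BBI * sum(Vbar) - c_BBP * Vbar`. A negative `Vbar` (fat
#' pulse) increases the setpoint.
#'
#' @param state A `vct_state`.
#' @param Vbar Beat volume integral from [beat_volume_integral()].
#' @param gains A [controller_gains()].
#' @return Updated state.
#' @export
update_setpoint <- function(state, Vbar, gains) {
  stopifnot(inherits(state, "vct_state"), is.finite(Vbar))
  state$sum_V <- state$sum_V + Vbar
  state$Pn <- state$P0 - gains$c_BBI * state$sum_V - gains$c_BBP * Vbar
  state$beat_count <- state$beat_count + 1L
  state
}

#' Continuous rhythm PID step
#'
#' Per-sample update of the continuous terms:
#' `y_PD = c_P * v_Rhythm + c_D * v_dRhythm` and
#' `y_I = y_I + c_I * y_PD`.
#'
#' @param v_Rhythm,v_dRhythm Current samples of the rhythm components.
#' @param state A `vct_state`.
#' @param gains A [controller_gains()].
#' @param freeze_integral Logical; when `TRUE` (anti-windup while the
#'   actuator command is clamped) `y_I` is not accumulated.
#' @return Updated state with fields `y_PD`, `y_I`.
#' @export
pid_rhythm <- function(v_Rhythm, v_dRhythm, state, gains,
                       freeze_integral = FALSE) {
  state$y_PD <- gains$c_P * v_Rhythm + gains$c_D * v_dRhythm
  if (!freeze_integral) state$y_I <- state$y_I + gains$c_I * state$y_PD
  state
}

#' Contact pressure command
#'
#' `p_C = P_n - y_I - y_PD`, optionally passed through the antiresonance
#' notch and clamped to the light-coupling floor and the actuator ceiling.
#'
#' @param state A `vct_state`.
#' @param coupling_floor Minimum contact pressure for light coupling (mmHg).
#' @param ceiling Upper clamp (mmHg).
#' @return List with `command` (mmHg) and `clamped` (logical).
#' @export
contact_pressure_command <- function(state, coupling_floor = 20,
                                     ceiling = 250) {
  raw <- state$Pn - state$y_I - state$y_PD
  cmd <- min(max(raw, coupling_floor), ceiling)
  list(command = cmd, clamped = !isTRUE(all.equal(cmd, raw)))
}

# ---- calibration to a pulsatile waveform ------------------------------------

#' Calibration state
#'
#' Stores the calibration pressures and reference pulse extrema and derives
#' the scale `k = (sBP_init - dBP_init) / (v_sys - v_dia)`. Under the
#' inverse light-volume convention `v_sys < v_dia`, so `k` is negative and
#' systole maps to a pressure maximum.
#'
#' @param sBP_init,dBP_init Calibration pressures (mmHg).
#' @param v_sys_ref,v_dia_ref Reference extrema of `v_Pulse` during the
#'   initial phase (dimensionless; systolic minimum and diastolic maximum
#'   of the light pulse).
#' @return Object of class `vct_calibration` with field `k`.
#' @export
calibration_state <- function(sBP_init, dBP_init, v_sys_ref, v_dia_ref) {
  stopifnot(sBP_init > dBP_init)
  if (v_sys_ref == v_dia_ref) stop("degenerate pulse: v_sys equals v_dia")
  k <- (sBP_init - dBP_init) / (v_sys_ref - v_dia_ref)
  structure(list(sBP_init = sBP_init, dBP_init = dBP_init,
                 v_sys_ref = v_sys_ref, v_dia_ref = v_dia_ref, k = k),
            class = "vct_calibration")
}

#' Superimpose the pulsatile waveform on the contact pressure
#'
#' `p_C2G(t) = p_c(t) + k * v_Pulse(t)`. During the calibration beat the
#' reconstructed pulse pressure equals `sBP_init - dBP_init` exactly.
#'
#' @param p_c Contact pressure ([sampled_signal], mmHg).
#' @param v_Pulse Pulsatile light component ([sampled_signal]).
#' @param calib A [calibration_state()].
#' @return `p_C2G` as a mmHg [sampled_signal].
#' @export
calibrate_waveform <- function(p_c, v_Pulse, calib) {
  stopifnot(inherits(calib, "vct_calibration"),
            length(p_c$values) == length(v_Pulse$values))
  sampled_signal(p_c$values + calib$k * v_Pulse$values, fs = p_c$fs,
                 t0 = p_c$t0, unit = "mmHg", label = "p_C2G")
}

# ---- hydrostatic (heart level) correction -----------------------------------

#' Heart-level offset
#'
#' @param d_v Vertical finger-minus-heart distance in cm, positive when the
#'   finger is below the heart; `|d_v| <= 100`.
#' @param rho_g Blood-column pressure per length (mmHg/cm, default 0.78).
#' @return Object of class `heart_level_offset`.
#' @export
heart_level_offset <- function(d_v = 0, rho_g = 0.78) {
  stopifnot(abs(d_v) <= 100, rho_g > 0)
  structure(list(d_v = d_v, rho_g = rho_g), class = "heart_level_offset")
}

#' Hydrostatic correction
#'
#' Subtracts the blood-column pressure between finger and heart:
#' `p - d_v * rho_g`.
#'
#' @param p Pressure value(s) in mmHg.
#' @param offset A [heart_level_offset()].
#' @return Corrected pressure(s), mmHg.
#' @export
hydrostatic_correct <- function(p, offset = heart_level_offset()) {
  p - offset$d_v * offset$rho_g
}

# ---- operation-mode state machine -------------------------------------------

#' Operation-mode transition
#'
#' Modes: `start` -> `initial` (open-loop oscillometry) -> `measure`
#' (closed-loop tracking) -> `interpolate` (low-pressure estimation from
#' the trained model) -> back to `initial` on the interpolation timer or on
#' a pulse-morphology change.
#'
#' @param mode Current mode string.
#' @param event One of `"started"`, `"envelope_done"`,
#'   `"measure_timer_elapsed"`, `"interp_timer_elapsed"`,
#'   `"morphology_change"`.
#' @return The new mode string.
#' @export
#' @examples
#' mode_step("start", "started")
mode_step <- function(mode, event) {
  transitions <- list(
    start = c(started = "initial"),
    initial = c(envelope_done = "measure"),
    measure = c(measure_timer_elapsed = "interpolate"),
    interpolate = c(interp_timer_elapsed = "initial",
                    morphology_change = "initial"))
  legal <- transitions[[mode]]
  if (is.null(legal) || !(event %in% names(legal)))
    stop(sprintf("illegal mode transition: event '%s' in mode '%s'",
                 event, mode))
  unname(legal[[event]])
}

#' Mode schedule durations
#'
#' @param measure_s Duration of the measurement (VCT) phase in seconds
#'   (default 120).
#' @param interpolate_s Duration of the low-power interpolation phase
#'   (default 780, i.e. 13 min).
#' @return List of durations.
#' @export
mode_schedule <- function(measure_s = 120, interpolate_s = 780) {
  stopifnot(measure_s > 0, interpolate_s > 0)
  list(measure_s = measure_s, interpolate_s = interpolate_s)
}

# ---- interpolation-mode estimator -------------------------------------------

#' Train the interpolation-mode estimator
#'
#' A deliberately simple per-session linear model (a stand-in for a device
#' model the method leaves open): tracked mean pressure regressed on
#' per-beat pulse amplitude and baseline light level collected during
#' measure mode.
#'
#' @param features Data frame with columns `amplitude`, `baseline`
#'   (per-beat) and `mBP` (tracked mean pressure, mmHg); >= 60 s of beats.
#' @return Object of class `interp_model`.
#' @export
fit_interpolation_model <- function(features) {
  stopifnot(all(c("amplitude", "baseline", "mBP") %in% names(features)))
  ok <- is.finite(features$amplitude) & is.finite(features$baseline) &
    is.finite(features$mBP)
  features <- features[ok, , drop = FALSE]
  if (nrow(features) < 40)
    stop("interpolation model needs >= 60 s of measure-mode beats")
  keep_amp <- sd(features$amplitude) > 1e-12
  keep_base <- sd(features$baseline) > 1e-12
  form <- if (keep_amp && keep_base) mBP ~ amplitude + baseline
          else if (keep_amp) mBP ~ amplitude
          else if (keep_base) mBP ~ baseline
          else mBP ~ 1
  structure(list(fit = lm(form, data = features),
                 n = nrow(features)), class = "interp_model")
}

#' Interpolation-mode mean-pressure estimate
#'
#' @param model An `interp_model` from [fit_interpolation_model()]; an
#'   untrained model (`NULL`) is an error directing back to measure mode.
#' @param features Data frame with per-beat `amplitude` and `baseline`.
#' @return Data frame with `mBP` estimates and `quality = "interpolated"`.
#' @export
interpolation_estimate <- function(model, features) {
  if (is.null(model) || !inherits(model, "interp_model"))
    stop("interpolation model untrained: run measure mode first")
  data.frame(mBP = as.numeric(predict(model$fit, newdata = features)),
             quality = "interpolated")
}
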