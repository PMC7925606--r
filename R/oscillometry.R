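# Open-loop oscillometric initialization: a slow contact-pressure ramp,
# beat-wise pulse-amplitude extraction, Gaussian envelope fit, mean pressure
# by the maximum-oscillation rule, optional ratio-derived systolic/diastolic
# estimates, and the initial setpoint (P0, v0).

#' Pressure ramp command
#'
#' Monotone non-decreasing contact-pressure command from `start` to `stop`
#' mmHg at `rate` mmHg/s (defaults 0 to 200 at 2 mmHg/s).
#'
#' @param start,stop Ramp limits in mmHg, `0 <= start < stop <= 300`
#'   (`start == stop` yields an empty ramp).
#' @param rate Ramp rate in mmHg/s, in `[0.5, 10]`.
#' @param fs Sampling rate in Hz.
#' @param max_rate Actuator slew limit; `rate` above it is rejected.
#' @return A mmHg [sampled_signal] (length 0 values are not allowed, so an
#'   empty ramp returns a single sample at `start`).
#' @export
ramp_protocol <- function(start = 0, stop = 200, rate = 2, fs = 250,
                          max_rate = 30) {
  stopifnot(start >= 0, stop <= 300, start <= stop,
            rate >= 0.5, rate <= 10)
  if (rate > max_rate) stop("ramp rate exceeds actuator slew limit")
  if (stop == start)
    return(sampled_signal(start, fs = fs, unit = "mmHg", label = "ramp"))
  n <- ceiling((stop - start) / rate * fs)
  p <- pmin(start + (1:n) / fs * rate, stop)
  sampled_signal(p, fs = fs, unit = "mmHg", label = "ramp")
}

#' Extract per-beat oscillometric amplitude points
#'
#' One point per beat: the beat's mean contact pressure and the
#' peak-to-trough excursion of `v_Pulse` within the beat. Beats not fully
#' inside the signals are skipped.
#'
#' @param v_Pulse Pulsatile light component ([sampled_signal]).
#' @param p_c Contact pressure ([sampled_signal], same grid).
#' @param beats A `beat_table` from [detect_beats()].
#' @return Data frame with columns `pressure` (mmHg), `amplitude`
#'   (dimensionless, >= 0) and `t` (beat time).
#' @export
extract_amplitudes <- function(v_Pulse, p_c, beats) {
  stopifnot(inherits(v_Pulse, "sampled_signal"),
            inherits(p_c, "sampled_signal"))
  fs <- v_Pulse$fs
  n <- length(v_Pulse$values)
  rows <- lapply(seq_len(nrow(beats)), function(b) {
    i0 <- floor((beats$t_onset[b] - v_Pulse$t0) * fs) + 1L
    i1 <- ceiling((beats$t_end[b] - v_Pulse$t0) * fs) + 1L
    if (i0 < 1L || i1 > n || i1 <= i0) return(NULL)
    seg <- v_Pulse$values[i0:i1]
    data.frame(pressure = mean(p_c$values[i0:i1]),
               amplitude = max(seg) - min(seg),
               t = beats$t_end[b])
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Fit the oscillometric envelope
#'
#' Unweighted least-squares fit of a Gaussian
#' `A * exp(-(p - mu)^2 / (2 sigma^2))` to amplitude-versus-pressure
#' points. The envelope peak `mu` is the mean-pressure estimate by the
#' maximum-oscillation rule and the initial setpoint `P0`. Points below the
#' light-coupling pressure floor are excluded, as are points below
#' `fit_floor` of the maximum amplitude (the asymptotic tails carry no
#' envelope information).
#'
#' @param points Data frame with `pressure` and `amplitude` columns
#'   (>= 8 points spanning >= 40 mmHg, with an interior maximum).
#' @param coupling_floor Minimum contact pressure for valid light coupling
#'   (mmHg, default 20).
#' @param fit_floor Amplitude fraction below which points are excluded from
#'   the fit (default 0.25).
#' @param v Optional raw light signal; if given together with `p_c`, the
#'   companion value `v0` (beat-mean light at the beat nearest `mu`) is
#'   computed.
#' @param p_c Optional contact pressure signal matching `v`.
#' @param beats Optional `beat_table` matching `v`.
#' @return Object of class `osc_envelope`: `A`, `mu`, `sigma`, `mBP`
#'   (= `mu`), `P0` (= `mu`), `v0`, `fit_rmse`, `points`.
#' @export
fit_envelope <- function(points, coupling_floor = 20, fit_floor = 0.25,
                         v = NULL, p_c = NULL, beats = NULL) {
  pts <- points[points$pressure >= coupling_floor, , drop = FALSE]
  if (nrow(pts) < 8) stop("envelope fit needs >= 8 points above the floor")
  if (diff(range(pts$pressure)) < 40)
    stop("envelope fit needs >= 40 mmHg of pressure span")
  i_max <- which.max(pts$amplitude)
  rng <- range(pts$pressure)
  if (pts$pressure[i_max] <= rng[1] + 0.05 * diff(rng) ||
      pts$pressure[i_max] >= rng[2] - 0.05 * diff(rng))
    stop("envelope not domed: amplitude maximum on the boundary")
  a_max <- pts$amplitude[i_max]
  fitpts <- pts[pts$amplitude >= fit_floor * a_max, , drop = FALSE]
  start <- list(A = a_max, mu = pts$pressure[i_max], sigma = 20)
  fit <- minpack.lm::nlsLM(
    amplitude ~ A * exp(-(pressure - mu)^2 / (2 * sigma^2)),
    data = fitpts, start = start,
    lower = c(A = 0, mu = rng[1], sigma = 1),
    upper = c(A = 10 * a_max, mu = rng[2], sigma = 200),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (!all(is.finite(cf))) stop("envelope fit diverged")
  rmse <- sqrt(mean(residuals(fit)^2))
  v0 <- NA_real_
  if (!is.null(v) && !is.null(p_c) && !is.null(beats) && nrow(beats) > 0) {
    bp <- extract_amplitudes(v, p_c, beats)  # reuse alignment for means
    # beat-mean light value of the beat whose mean pressure is nearest mu
    fs <- v$fs
    means <- vapply(seq_len(nrow(beats)), function(b) {
      i0 <- max(1L, floor((beats$t_onset[b] - v$t0) * fs) + 1L)
      i1 <- min(length(v$values),
                ceiling((beats$t_end[b] - v$t0) * fs) + 1L)
      c(mean(p_c$values[i0:i1]), mean(v$values[i0:i1]))
    }, numeric(2))
    v0 <- means[2, which.min(abs(means[1, ] - cf[["mu"]]))]
  }
  structure(list(A = cf[["A"]], mu = cf[["mu"]], sigma = cf[["sigma"]],
                 mBP = cf[["mu"]], P0 = cf[["mu"]], v0 = v0,
                 fit_rmse = rmse, points = pts),
            class = "osc_envelope")
}

#' @export
print.osc_envelope <- function(x, ...) {
  cat(sprintf(paste0("<osc_envelope> A = %.4g, mu (mBP, P0) = %.1f mmHg, ",
                     "sigma = %.1f mmHg, rmse = %.3g (%d points)\n"),
              x$A, x$mu, x$sigma, x$fit_rmse, nrow(x$points)))
  if (!is.null(x$sBP)) cat(sprintf("  sBP = %.1f, dBP = %.1f mmHg\n",
                                   x$sBP, x$dBP))
  invisible(x)
}

#' @export
plot.osc_envelope <- function(x, ...) {
  plot(x$points$pressure, x$points$amplitude, xlab = "contact pressure (mmHg)",
       ylab = "pulse amplitude", pch = 16, cex = 0.6, ...)
  p <- seq(min(x$points$pressure), max(x$points$pressure), length.out = 200)
  lines(p, x$A * exp(-(p - x$mu)^2 / (2 * x$sigma^2)), lwd = 2)
  abline(v = x$mu, lty = 2)
  invisible(x)
}

#' Ratio-derived systolic and diastolic pressures
#'
#' The systolic pressure is where the fitted envelope falls to
#' `r_sys * A` above the peak and the diastolic where it falls to
#' `r_dia * A` below it:
#' `sBP = mu + sigma * sqrt(-2 log r_sys)`,
#' `dBP = mu - sigma * sqrt(-2 log r_dia)`.
#' The default ratios are taken from the oscillometric literature and are
#' UNVALIDATED for this sensor geometry; treat the results as calibration
#' placeholders.
#'
#' @param env An `osc_envelope`.
#' @param r_sys,r_dia Amplitude ratios in (0, 1].
#' @return The envelope with `sBP` and `dBP` fields added.
#' @export
estimate_sbp_dbp <- function(env, r_sys = 0.55, r_dia = 0.85) {
  stopifnot(inherits(env, "osc_envelope"))
  if (r_sys <= 0 || r_sys > 1 || r_dia <= 0 || r_dia > 1)
    stop("amplitude ratios must be in (0, 1]")
  env$sBP <- env$mu + env$sigma * sqrt(-2 * log(r_sys))
  env$dBP <- env$mu - env$sigma * sqrt(-2 * log(r_dia))
  env
}

#' Run an open-loop oscillometric initialization against the simulator
#'
#' Applies a pressure ramp to the simulated finger, decomposes the light
#' signal, detects beats, extracts amplitudes and fits the envelope.
#'
#' @param bp A [bp_trajectory_config] (its duration must cover the ramp).
#' @param pv A [pv_model_config].
#' @param tone Constant vasomotor tone during the ramp.
#' @param ramp Ramp command from [ramp_protocol()].
#' @param act An [actuator_config].
#' @param fb A [filter_bank_config].
#' @param noise_sd Additive white-noise SD on the light signal.
#' @param seed Integer seed.
#' @param ... Passed to [fit_envelope()].
#' @return The fitted `osc_envelope`, with the simulation signals attached
#'   as attribute `signals`.
#' @export
run_oscillometry <- function(bp, pv = pv_model_config(), tone = 0.3,
                             ramp = ramp_protocol(), act = actuator_config(),
                             fb = filter_bank_config(), noise_sd = 0,
                             seed = 1, ...) {
  fs <- ramp$fs
  gen <- generate_arterial_bp(bp, fs = fs, seed = seed)
  n <- min(length(gen$p_a$values), length(ramp$values))
  p_cmd <- sampled_signal(ramp$values[1:n], fs = fs, unit = "mmHg")
  p_c <- actuate(p_cmd, act)
  v_vals <- pv_transfer(gen$p_a$values[1:n], p_c$values, tone, pv)
  if (noise_sd > 0) {
    set.seed(seed + 1L)
    v_vals <- v_vals + rnorm(n, 0, noise_sd)
  }
  v <- sampled_signal(v_vals, fs = fs, unit = "dimensionless", label = "v")
  dec <- decompose(v, fb)
  beats <- detect_beats(dec$v_Pulse)
  pts <- extract_amplitudes(dec$v_Pulse, p_c, beats)
  env <- fit_envelope(pts, v = v, p_c = p_c, beats = beats, ...)
  attr(env, "signals") <- list(v = v, p_c = p_c, p_a = gen$p_a,
                               beats = beats, truth = gen$truth)
  env
}
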