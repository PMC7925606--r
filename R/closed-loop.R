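# Closed-loop harness: oscillometric initialization followed by the
# volume-control loop against the synthetic finger, with antiresonance
# supervision and (optionally) the measure/interpolate duty cycle.

stage_order <- c("pulse1", "pulse2", "vct1", "rhy_hp1", "rhy_hp2",
                 "rhy_lp1", "rhy_lp2", "rhy_lp3", "rhy_lp4",
                 "drh_lp1", "drh_lp2")

fb_par_vectors <- function(fb) {
  list(uc = vapply(stage_order, function(s) fb$stages[[s]]$UC, 0),
       dec = vapply(stage_order, function(s) fb$stages[[s]]$decimation, 0L))
}

new_loop_state <- function(v0, P0, fb, act, fs, p_applied, amp_est) {
  fstates <- init_filter_states(v0, fb)
  nd <- max(0L, as.integer(round(act$delay * fs)))
  list(filt = unname(unlist(fstates[stage_order])),
       filt_acc = rep(0, length(stage_order)), drh_prev = 0,
       drh_hold = 0,
       P0 = P0, Pn = P0, sum_V = 0, y_I = 0, PI_est = 1,
       notch_on = FALSE, notch_b = c(1, 0, 0), notch_a = c(1, 0, 0),
       nx1 = 0, nx2 = 0, ny1 = 0, ny2 = 0,
       z_act = p_applied, p_applied = p_applied,
       delay_line = rep(P0, nd), dpos = 0L,
       amp_est = amp_est, cur_min = 0, cur_max = 0,
       last_beat = 0, g = 0, vct_acc = 0, vct_n = 0, clamped = FALSE,
       armed = FALSE, vbuf = rep(0, 1024), anchor_sum = 0)
}

loop_params <- function(fb, gains, act, pv, fs, coupling_floor,
                        beat_control = TRUE, pid_control = TRUE,
                        fixed_command = NA_real_) {
  fv <- fb_par_vectors(fb)
  rate <- if (act$resolution > 0) 0.98 * act$max_rate else act$max_rate
  list(fs = fs, uc = fv$uc, dec = as.integer(fv$dec),
       c_BBI = gains$c_BBI, c_BBP = gains$c_BBP, c_P = gains$c_P,
       c_D = gains$c_D, c_I = gains$c_I,
       y_I_leak = if (is.finite(gains$y_I_tau) && gains$y_I_tau > 0)
         1 / (gains$y_I_tau * fs) else 0,
       c_SA = gains$c_SA, S0 = NA_real_,
       clamp_lo = coupling_floor, clamp_hi = act$range[2],
       beat_control = beat_control, pid_control = pid_control,
       vbar_pulse_free = TRUE,
       fixed_command = fixed_command,
       v_high = pv$v_high, v_low0 = pv$v_low0, tone_gain = pv$tone_gain,
       w = pv$w, center_offset = pv$center_offset,
       w_narrow = pv$w_tone_narrowing,
       act_step = rate / fs, act_res = act$resolution,
       act_lo = act$range[1], act_hi = act$range[2],
       refract = as.integer(0.25 * fs), confirm = 0.25, min_amp = 1e-4)
}

# open-loop oscillometric initialization on a segment of the scenario
oscillometric_init <- function(p_a_seg, tone_seg, noise_seg, fs, act, fb,
                               coupling_floor, ramp_start = 0,
                               ramp_stop = 200, ramp_rate = 2) {
  ramp <- ramp_protocol(ramp_start, ramp_stop, ramp_rate, fs,
                        max_rate = act$max_rate)
  n <- min(length(ramp$values), length(p_a_seg))
  p_c <- actuate(sampled_signal(ramp$values[1:n], fs = fs, unit = "mmHg"),
                 act, init = ramp_start)
  pv_cfg <- attr(p_a_seg, "pv")
  v_vals <- pv_transfer(p_a_seg[1:n], p_c$values, tone_seg[1:n], pv_cfg) +
    noise_seg[1:n]
  v <- sampled_signal(v_vals, fs = fs, unit = "dimensionless", label = "v")
  dec <- decompose(v, fb)
  beats <- detect_beats(dec$v_Pulse)
  pts <- extract_amplitudes(dec$v_Pulse, p_c, beats)
  env <- fit_envelope(pts, coupling_floor = coupling_floor,
                      v = v, p_c = p_c, beats = beats)
  env <- estimate_sbp_dbp(env)
  # reference pulse extrema of the initial phase: beats near the setpoint
  near <- which(abs(pts$pressure - env$mu) <= 15)
  if (!length(near)) near <- which.min(abs(pts$pressure - env$mu))
  idx <- match(pts$t[near], beats$t_end)
  v_sys_ref <- mean(beats$v_sys[idx])
  v_dia_ref <- mean(beats$v_dia[idx])
  list(env = env, n_used = n, p_c = p_c, v = v, beats = beats,
       v_sys_ref = v_sys_ref, v_dia_ref = v_dia_ref)
}

#' Run the full closed loop on a scenario
#'
#' Executes the open-loop oscillometric initialization (pressure ramp,
#' envelope fit, setpoint \code{P0} and companion \code{v0}), seeds the
#' filter cascade, then runs the volume-control loop: beat-based setpoint
#' updates, continuous rhythm PID, antiresonance supervision (a spectral
#' resonance detector tuning a latched notch in the command path) and the
#' slew-limited actuator. Deterministic given \code{seed}.
#'
#' @param scn A [scenario()].
#' @param gains A [controller_gains()].
#' @param act An [actuator_config()].
#' @param fb A [filter_bank_config()].
#' @param seed Integer seed; the scenario's `seed_offset` is added.
#' @param coupling_floor Minimum contact pressure (mmHg).
#' @param settle_s Hold time at `P0` between re-seeding the filter states
#'   with `v0` and loop closure (s). Kept short so the washout trend does
#'   not forget the oscillometric anchor before the loop closes.
#' @param chunk_s Chunk length for the compiled loop (s).
#' @param antiresonance Enable the resonance detector + notch.
#' @param antires_bandwidth Notch bandwidth in Hz.
#' @param antires_threshold Detector amplitude threshold in mmHg.
#' @param schedule `NULL` for continuous measurement, or a
#'   [mode_schedule()] for the measure/interpolate duty cycle.
#' @param heart_offset A [heart_level_offset()]; its hydrostatic correction
#'   is applied to the tracked pressure.
#' @param fs Sampling rate (Hz, default 250).
#' @return Object of class `vct_result`: signals (`p_a`, `p_c`, `v`,
#'   `p_C2G`), per-beat records (`beats`), the fitted envelope, the
#'   calibration state, the event log, and a `failed` flag (set when the
#'   contact pressure stays pinned at a range limit for more than 10 s).
#' @export
run_closed_loop <- function(scn, gains = controller_gains(),
                            act = actuator_config(),
                            fb = filter_bank_config(), seed = 1,
                            coupling_floor = 20, settle_s = 6,
                            chunk_s = 5, antiresonance = TRUE,
                            antires_bandwidth = 0.05,
                            antires_threshold = 2, schedule = NULL,
                            heart_offset = heart_level_offset(),
                            fs = 250) {
  stopifnot(inherits(scn, "vct_scenario"))
  seed_i <- as.integer(seed) + scn$seed_offset
  n <- round(scn$duration * fs)

  bp_cfg <- bp_trajectory_config(duration = scn$duration, hr = scn$hr,
                                 sbp = scn$sbp, dbp = scn$dbp,
                                 resp = scn$resp, mayer = scn$mayer,
                                 events = scn$events)
  gen <- generate_arterial_bp(bp_cfg, fs = fs, seed = seed_i)
  p_a <- gen$p_a$values
  attr(p_a, "pv") <- scn$pv
  tone <- tone_trajectory(scn, n, fs)

  set.seed(seed_i + 101L)
  noise <- rnorm(n, 0, scn$noise_sd)
  artifact_windows <- NULL
  if (scn$artifact_rate > 0) {
    k <- rpois(1, scn$artifact_rate * scn$duration / 60)
    if (k > 0) {
      starts <- sort(runif(k, 120, scn$duration - 2))
      durs <- runif(k, 0.3, 1)
      artifact_windows <- cbind(start = starts, end = starts + durs)
      amp_burst <- 0.5  # large against typical pulse amplitudes
      for (i in seq_len(k)) {
        idx <- (round(starts[i] * fs) + 1):min(round((starts[i] + durs[i]) * fs), n)
        noise[idx] <- noise[idx] + rnorm(length(idx), 0, amp_burst)
      }
    }
  }

  events <- data.frame(t = numeric(0), event = character(0),
                       detail = character(0))
  log_event <- function(t, ev, detail = "") {
    events <<- rbind(events, data.frame(t = t, event = ev, detail = detail))
  }

  # ---- phase A: oscillometric initialization --------------------------------
  init <- oscillometric_init(p_a, tone, noise, fs, act, fb, coupling_floor)
  env <- init$env
  log_event(init$n_used / fs, "envelope_done",
            sprintf("P0=%.1f v0=%.4f", env$P0, env$v0))
  calib <- calibration_state(env$sBP, env$dBP, init$v_sys_ref,
                             init$v_dia_ref)
  mode <- mode_step(mode_step("start", "started"), "envelope_done")

  par_measure <- loop_params(fb, gains, act, scn$pv, fs, coupling_floor)
  par_settle <- modifyList(par_measure,
                           list(beat_control = FALSE, pid_control = FALSE,
                                fixed_command = env$P0))
  par_interp <- modifyList(par_measure,
                           list(beat_control = FALSE, pid_control = FALSE,
                                fixed_command = coupling_floor))

  st <- new_loop_state(env$v0, env$P0, fb, act, fs,
                       p_applied = init$p_c$values[init$n_used],
                       amp_est = env$A)

  n_chunk <- round(chunk_s * fs)
  i_cur <- init$n_used + 1L
  t_origin <- init$n_used / fs  # time of the sample where the loop counter g = 0
  # output accumulators
  vs <- list(init$v$values)
  pcs <- list(init$p_c$values)
  vps <- list(rep(0, init$n_used))  # keeps the accumulators index-aligned
  beat_rows <- list()
  pc_hist <- numeric(0)      # 10 Hz decimated contact pressure
  notch_freq <- NA_real_
  backoff <- 1               # rhythm-gain backoff while resonance persists

  # descent from the ramp top to P0 before the filter states are seeded:
  # the saturated light level during the descent must not enter the washout
  descent_s <- abs(init$p_c$values[init$n_used] - env$P0) /
    (0.98 * act$max_rate) + 0.5
  descent_end <- min(n, i_cur + round(descent_s * fs) - 1L)
  settle_end <- min(n, descent_end + round(settle_s * fs))
  phase_end_measure <- if (is.null(schedule)) n else NA_integer_
  mode_t0 <- settle_end / fs

  run_chunk <- function(i0, i1, par) {
    idx <- i0:i1
    out <- vct_chunk_cpp(p_a[idx], tone[idx], noise[idx], par, st)
    st <<- out$state
    out
  }

  reseed_states <- function(v0, amp) {
    fresh <- init_filter_states(v0, fb)
    st$filt <<- unname(unlist(fresh[stage_order]))
    st$filt_acc <<- rep(0, length(stage_order))
    st$drh_prev <<- 0
    st$drh_hold <<- 0
    st$vct_acc <<- 0
    st$vct_n <<- 0
    st$cur_min <<- 0
    st$cur_max <<- 0
    st$armed <<- FALSE
    st$amp_est <<- amp
    st$last_beat <<- st$g
    st$anchor_sum <<- 0
  }

  # ---- phase B: descend to P0, re-seed the cascade at v0, settle ------------
  run_fixed <- function(to) {
    sb <- numeric(0)
    while (i_cur <= to) {
      i1 <- min(i_cur + n_chunk - 1L, to)
      out <- run_chunk(i_cur, i1, par_settle)
      vs[[length(vs) + 1L]] <<- out$v
      pcs[[length(pcs) + 1L]] <<- out$p_c
      vps[[length(vps) + 1L]] <<- out$v_Pulse
      sb <- c(sb, out$beat_S)
      i_cur <<- i1 + 1L
    }
    sb
  }
  run_fixed(descent_end)
  reseed_states(env$v0, env$A)
  settle_S <- run_fixed(settle_end)
  loop_start_t <- (i_cur - 1L) / fs

  # The balanced value S0 of the fat/spiky shape statistic is calibrated
  # on the first beats of the closed loop itself (running conditions,
  # including controller ripple), during which the anchor stays disabled.
  anchor_calib_end <- min(n, i_cur + round(20 * fs) - 1L)
  par_calib <- par_measure
  par_calib$c_SA <- 0
  calib_S <- numeric(0)

  # ---- phase C: closed loop (with optional duty cycle) ----------------------
  if (!is.null(schedule)) phase_end_measure <-
      min(n, i_cur + round(schedule$measure_s * fs) - 1L)
  measure_feat <- NULL   # per-beat features of the current measure phase
  interp_model <- NULL
  while (i_cur <= n) {
    if (mode == "measure") {
      i1 <- min(i_cur + n_chunk - 1L, n,
                if (is.na(phase_end_measure)) n else phase_end_measure)
      calibrating <- i_cur <= anchor_calib_end
      if (calibrating) i1 <- min(i1, anchor_calib_end)
      out <- run_chunk(i_cur, i1, if (calibrating) par_calib else par_measure)
      if (calibrating) {
        calib_S <- c(calib_S, out$beat_S)
        if (i1 >= anchor_calib_end) {
          sS <- calib_S[is.finite(calib_S)]
          if (length(sS) > 4) sS <- sS[-(1:2)]
          if (length(sS) >= 3) par_measure$S0 <- mean(sS)
          else par_measure$c_SA <- 0
        }
      }
      vs[[length(vs) + 1L]] <- out$v
      pcs[[length(pcs) + 1L]] <- out$p_c
      vps[[length(vps) + 1L]] <- out$v_Pulse
      if (length(out$beat_t)) {
        beat_rows[[length(beat_rows) + 1L]] <-
          data.frame(t = t_origin + out$beat_t, PI = out$beat_PI,
                     Pn = out$beat_Pn, Vbar = out$beat_V,
                     clamped = out$beat_clamped == 1, mode = "measure")
      }
      # antiresonance supervision on the decimated pressure history: a
      # persistent oscillation tunes the notch onto its frequency and, on
      # every (re)tune, backs the rhythm gains off, since a notch alone
      # only moves a broadband instability to a neighbouring frequency
      pc_hist <- c(pc_hist, out$p_c[seq(1, length(out$p_c), by = fs / 10)])
      if (antiresonance && length(pc_hist) >= 320) {
        win <- tail(pc_hist, 300)
        det <- detect_resonance(sampled_signal(win, fs = 10, unit = "mmHg"),
                                amp_threshold = antires_threshold)
        if (!is.null(det) &&
            (!isTRUE(st$notch_on) ||
             abs(det$freq - notch_freq) > antires_bandwidth / 2)) {
          co <- notch_coefficients(det$freq, antires_bandwidth, fs)
          st$notch_on <- TRUE
          st$notch_b <- co$b
          st$notch_a <- co$a
          notch_freq <- det$freq
          backoff <- max(0.25, backoff * 0.6)
          for (nm in c("c_P", "c_D", "c_I")) {
            par_measure[[nm]] <- gains[[nm]] * backoff
            par_calib[[nm]] <- gains[[nm]] * backoff
          }
          log_event(i1 / fs, "notch_tuned",
                    sprintf("f=%.3f Hz amp=%.1f mmHg backoff=%.2f",
                            det$freq, det$amplitude, backoff))
        }
      }
      i_cur <- i1 + 1L
      if (!is.na(phase_end_measure) && i_cur > phase_end_measure &&
          i_cur <= n) {
        # train the interpolation model on this measure phase
        bt <- do.call(rbind, beat_rows)
        bt <- bt[bt$mode == "measure" & bt$t >= mode_t0, , drop = FALSE]
        feats <- beat_features(bt, vs, vps, pcs, fs)
        if (!is.null(feats) && nrow(feats) >= 40)
          interp_model <- fit_interpolation_model(feats)
        mode <- mode_step(mode, "measure_timer_elapsed")
        log_event(i_cur / fs, "mode", "measure -> interpolate")
        mode_t0 <- (i_cur - 1L) / fs
        phase_end_interp <- min(n, i_cur + round(schedule$interpolate_s * fs) - 1L)
      }
    } else if (mode == "interpolate") {
      i1 <- min(i_cur + n_chunk - 1L, n, phase_end_interp)
      out <- run_chunk(i_cur, i1, par_interp)
      vs[[length(vs) + 1L]] <- out$v
      pcs[[length(pcs) + 1L]] <- out$p_c
      vps[[length(vps) + 1L]] <- out$v_Pulse
      if (length(out$beat_t)) {
        beat_rows[[length(beat_rows) + 1L]] <-
          data.frame(t = t_origin + out$beat_t, PI = out$beat_PI,
                     Pn = out$beat_Pn, Vbar = out$beat_V,
                     clamped = out$beat_clamped == 1, mode = "interpolate")
      }
      i_cur <- i1 + 1L
      if (i_cur > phase_end_interp && i_cur <= n) {
        mode <- mode_step(mode, "interp_timer_elapsed")   # -> initial
        log_event(i_cur / fs, "mode", "interpolate -> initial")
        # re-initialization: fresh ramp on the upcoming segment
        seg <- i_cur:n
        p_seg <- p_a[seg]
        attr(p_seg, "pv") <- scn$pv
        init2 <- tryCatch(
          oscillometric_init(p_seg, tone[seg], noise[seg], fs, act, fb,
                             coupling_floor),
          error = function(e) NULL)
        if (is.null(init2)) {
          mode <- "measure"  # not enough signal left; resume tracking
          phase_end_measure <- n
        } else {
          env2 <- init2$env
          vs[[length(vs) + 1L]] <- init2$v$values
          pcs[[length(pcs) + 1L]] <- init2$p_c$values
          vps[[length(vps) + 1L]] <- rep(0, init2$n_used)
          st_new <- new_loop_state(env2$v0, env2$P0, fb, act, fs,
                                   p_applied =
                                     init2$p_c$values[init2$n_used],
                                   amp_est = env2$A)
          st_new$g <- st$g + init2$n_used
          st_new$last_beat <- st_new$g
          st <- st_new
          pc_hist <- numeric(0)  # the re-init transient is not resonance
          i_cur <- i_cur + init2$n_used
          mode <- mode_step("initial", "envelope_done")
          log_event(i_cur / fs, "mode", "initial -> measure")
          mode_t0 <- (i_cur - 1L) / fs
          phase_end_measure <- min(n, i_cur + round(schedule$measure_s * fs) - 1L)
        }
      }
    }
  }

  # ---- assemble -------------------------------------------------------------
  v_all <- unlist(vs)[1:n]
  pc_all <- unlist(pcs)[1:n]
  v_sig <- sampled_signal(v_all, fs = fs, unit = "dimensionless",
                          label = "v")
  pc_sig <- sampled_signal(pc_all, fs = fs, unit = "mmHg", label = "p_c")
  dec_full <- decompose(v_sig, fb)
  p_c2g <- calibrate_waveform(pc_sig, dec_full$v_Pulse, calib)

  beats <- if (length(beat_rows)) do.call(rbind, beat_rows) else
    data.frame(t = numeric(0), PI = numeric(0), Pn = numeric(0),
               Vbar = numeric(0), clamped = logical(0), mode = character(0))
  if (nrow(beats)) {
    i_end <- pmin(round(beats$t * fs) + 1L, n)
    i_start <- pmax(1L, i_end - pmax(1L, round(beats$PI * fs)))
    beats$tracked_mBP <- hydrostatic_correct(
      vapply(seq_len(nrow(beats)),
             function(b) mean(pc_all[i_start[b]:i_end[b]]), 0),
      heart_offset)
    beats$true_mBP <- vapply(seq_len(nrow(beats)),
                             function(b) mean(p_a[i_start[b]:i_end[b]]), 0)
    # interpolation-mode estimates replace the (floor) contact pressure
    if (any(beats$mode == "interpolate") && !is.null(interp_model)) {
      ii <- beats$mode == "interpolate"
      feats <- beat_features(beats[ii, , drop = FALSE], list(v_all),
                             list(dec_full$v_Pulse$values), list(pc_all), fs)
      if (!is.null(feats))
        beats$tracked_mBP[ii] <- interpolation_estimate(interp_model,
                                                        feats)$mBP
    }
    beats$quality <- ifelse(
      beats$clamped | beats$PI < 0.3 | beats$PI > 2.5, "invalid",
      ifelse(beats$mode == "interpolate", "interpolated", "valid"))
    if (!is.null(artifact_windows)) {
      for (i in seq_len(nrow(artifact_windows)))
        beats$quality[beats$t >= artifact_windows[i, 1] - 1 &
                        beats$t <= artifact_windows[i, 2] + 3] <- "invalid"
    }
  }

  # divergence check: pinned at a range limit for > 10 s
  pinned <- pc_all >= act$range[2] - 1e-6 | pc_all <= act$range[1] + 1e-6
  failed <- FALSE
  if (any(pinned)) {
    r <- rle(pinned)
    failed <- any(r$lengths[r$values] > 10 * fs)
  }

  structure(list(
    signals = list(p_a = gen$p_a, p_c = pc_sig, v = v_sig, p_C2G = p_c2g,
                   v_Pulse = dec_full$v_Pulse),
    beats = beats, truth = gen$truth, envelope = env, calib = calib,
    events = events, artifact_windows = artifact_windows,
    loop_start = loop_start_t, scenario = scn, gains = gains, seed = seed,
    failed = failed), class = "vct_result")
}

# per-beat features for the interpolation estimator
beat_features <- function(beats, vs, vps, pcs, fs) {
  if (!nrow(beats)) return(NULL)
  v_all <- unlist(vs)
  vp_all <- unlist(vps)
  pc_all <- unlist(pcs)
  n <- length(v_all)
  i_end <- pmin(round(beats$t * fs) + 1L, n)
  i_start <- pmax(1L, i_end - pmax(1L, round(beats$PI * fs)))
  amp <- vapply(seq_len(nrow(beats)), function(b) {
    seg <- vp_all[i_start[b]:i_end[b]]
    max(seg) - min(seg)
  }, 0)
  base <- vapply(seq_len(nrow(beats)),
                 function(b) mean(v_all[i_start[b]:i_end[b]]), 0)
  out <- data.frame(amplitude = amp, baseline = base)
  if (!is.null(beats$tracked_mBP)) out$mBP <- beats$tracked_mBP
  else if (!is.null(pc_all)) out$mBP <- vapply(
    seq_len(nrow(beats)), function(b) mean(pc_all[i_start[b]:i_end[b]]), 0)
  out
}

#' @export
print.vct_result <- function(x, ...) {
  vb <- x$beats[x$beats$quality == "valid", , drop = FALSE]
  cat(sprintf("<vct_result> scenario '%s', %d beats (%d valid)%s\n",
              x$scenario$name, nrow(x$beats), nrow(vb),
              if (x$failed) " [FAILED: pressure pinned]" else ""))
  if (nrow(vb)) {
    d <- vb$tracked_mBP - vb$true_mBP
    cat(sprintf("  tracked - true mBP: %.2f +/- %.2f mmHg (valid beats)\n",
                mean(d), sd(d)))
  }
  cat(sprintf("  envelope: P0 = %.1f mmHg, A = %.3g, sigma = %.1f\n",
              x$envelope$P0, x$envelope$A, x$envelope$sigma))
  invisible(x)
}

#' @export
plot.vct_result <- function(x, ...) {
  b <- x$beats
  plot(x$truth$t_onset, x$truth$mBP, type = "l", col = "grey50",
       xlab = "time (s)", ylab = "mBP (mmHg)", ...)
  ok <- b$quality == "valid"
  points(b$t[ok], b$tracked_mBP[ok], pch = 16, cex = 0.3, col = "steelblue")
  legend("topright", c("true mBP", "tracked"), lty = c(1, NA),
         pch = c(NA, 16), col = c("grey50", "steelblue"), bty = "n")
  invisible(x)
}

#' Ten-second tracked/true pressure pairs of a closed-loop run
#'
#' Averages the per-beat tracked and true mean pressures over non-overlapping
#' 10-s windows of the closed-loop phase; windows with less than half their
#' span covered by valid beats are dropped.
#'
#' @param result A `vct_result`.
#' @param window Window length in seconds (default 10).
#' @param warmup Seconds after loop closure to discard (default 60).
#' @return Data frame with `t`, `tracked`, `truth` (mmHg).
#' @export
tracked_pairs <- function(result, window = 10, warmup = 60) {
  b <- result$beats
  b <- b[b$quality %in% c("valid", "interpolated") &
           b$t >= result$loop_start + warmup, , drop = FALSE]
  if (!nrow(b)) return(data.frame(t = numeric(0), tracked = numeric(0),
                                  truth = numeric(0)))
  win <- floor(b$t / window)
  cov <- tapply(b$PI, win, sum)
  tr <- tapply(b$tracked_mBP, win, mean)
  th <- tapply(b$true_mBP, win, mean)
  keep <- cov >= window / 2
  data.frame(t = (as.numeric(names(tr)) + 0.5) * window,
             tracked = as.numeric(tr), truth = as.numeric(th))[keep, ]
}
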