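# Digital filter cascade decomposing the raw PPG light signal v(t) into the
# four control components:
#   v_Pulse   -- pulsatile content above the pulse split (high-pass),
#   v_Rhythm  -- respiratory / Mayer-wave band (band-pass),
#   v_dRhythm -- band-limited derivative of v_Rhythm (non-pulsatile),
#   v_VCT     -- v(t) with the unreliable very-low-frequency (< 0.01 Hz)
#                content removed but the pulses retained; its beat integral
#                is the volume-balance control signal.
#
# Every stage is a first-order IIR low-pass y_i = (1 - UC) y_{i-1} + UC x_i.
# Stages with very low cutoffs run decimated (the recursion advances every
# `decimation`-th input sample and the output is held in between), which
# keeps the update coefficients in a numerically comfortable range.
# High-pass blocks are formed as input minus low-pass.

#' Single filter stage configuration
#'
#' @param UC Update coefficient in (0, 1].
#' @param decimation Positive integer down-sampling factor applied before
#'   the recursion; the output is sample-and-hold reconstructed.
#' @return An object of class `filter_stage`.
#' @export
filter_stage <- function(UC, decimation = 1L) {
  if (!is.finite(UC) || UC <= 0 || UC > 1)
    stop("filter_stage: UC must be in (0, 1]")
  decimation <- as.integer(decimation)
  if (decimation < 1L) stop("filter_stage: decimation must be >= 1")
  structure(list(UC = UC, decimation = decimation), class = "filter_stage")
}

#' Update coefficient realizing a -3 dB cutoff
#'
#' For a first-order IIR low-pass running at `fs / decimation`, returns the
#' update coefficient whose pole matches the analog time constant
#' `1 / (2 pi fc)`.
#'
#' @param fc Cutoff frequency in Hz.
#' @param fs Sampling frequency in Hz.
#' @param decimation Stage decimation factor.
#' @return Update coefficient in (0, 1].
#' @export
uc_for_cutoff <- function(fc, fs, decimation = 1L) {
  stopifnot(fc > 0, fs > 0, fc < fs / (2 * decimation))
  1 - exp(-2 * pi * fc * decimation / fs)
}

#' Filter bank configuration
#'
#' Builds the stage cascade realizing the frequency split of the control
#' signals at sampling rate `fs`. The defaults place the very-low-frequency
#' cut at 0.01 Hz (vasomotor-dominated content, removed from all control
#' signals) and the pulse split at 0.5 Hz. Stage cutoffs are derived from
#' the band edges: the two-stage pulse high-pass uses stage cutoff
#' `cutoff_pulse / 1.554` so its composite -3 dB point sits at
#' `cutoff_pulse`; the rhythm low-pass uses four stages at the band top.
#'
#' @param fs Design sampling rate in Hz (default 250).
#' @param cutoff_vlf Very-low-frequency cutoff in Hz (default 0.01).
#' @param cutoff_pulse Pulse high-pass cutoff in Hz (default 0.5).
#' @param rhythm_band Length-2 numeric, rhythm band in Hz (default
#'   `c(0.01, 0.5)`).
#' @param dRhythm_band Length-2 numeric, derivative-branch band in Hz
#'   (default `c(0.05, 0.5)`).
#' @param vlf_decimation Decimation of the very-low-frequency stages.
#' @param rhythm_decimation Decimation of the rhythm stages.
#' @return An object of class `filter_bank_config` with a `stages` list and
#'   the band assignments.
#' @export
filter_bank_config <- function(fs = 250, cutoff_vlf = 0.01,
                               cutoff_pulse = 0.5,
                               rhythm_band = c(cutoff_vlf, 0.5),
                               dRhythm_band = c(0.05, 0.5),
                               vlf_decimation = 25L,
                               rhythm_decimation = 5L) {
  if (!(cutoff_vlf < rhythm_band[2] && rhythm_band[2] <= cutoff_pulse * 1.001))
    stop("filter_bank_config: need cutoff_vlf < rhythm_band[2] <= cutoff_pulse")
  fc_pulse_stage <- cutoff_pulse / 1.554  # two-block HP composite -3 dB
  stages <- list(
    pulse1  = filter_stage(uc_for_cutoff(fc_pulse_stage, fs), 1L),
    pulse2  = filter_stage(uc_for_cutoff(fc_pulse_stage, fs), 1L),
    # single-stage washout: its beat-integral summation must retain the
    # step-response area (first-order memory); stage cutoff 1.2x the VLF
    # cut keeps the gain at cutoff_vlf near -4 dB
    vct1    = filter_stage(uc_for_cutoff(1.2 * cutoff_vlf, fs,
                                         vlf_decimation),
                           vlf_decimation),
    rhy_hp1 = filter_stage(uc_for_cutoff(cutoff_vlf, fs, vlf_decimation),
                           vlf_decimation),
    rhy_hp2 = filter_stage(uc_for_cutoff(cutoff_vlf, fs, vlf_decimation),
                           vlf_decimation),
    rhy_lp1 = filter_stage(uc_for_cutoff(rhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation),
    rhy_lp2 = filter_stage(uc_for_cutoff(rhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation),
    rhy_lp3 = filter_stage(uc_for_cutoff(rhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation),
    rhy_lp4 = filter_stage(uc_for_cutoff(rhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation),
    drh_lp1 = filter_stage(uc_for_cutoff(dRhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation),
    drh_lp2 = filter_stage(uc_for_cutoff(dRhythm_band[2], fs,
                                         rhythm_decimation),
                           rhythm_decimation)
  )
  structure(list(fs = fs, cutoff_vlf = cutoff_vlf,
                 cutoff_pulse = cutoff_pulse, rhythm_band = rhythm_band,
                 dRhythm_band = dRhythm_band, stages = stages),
            class = "filter_bank_config")
}

# one low-pass stage; returns the output and the final stage memory
lp_run <- function(x, UC, d, init) {
  n <- length(x)
  if (d == 1L) {
    y <- as.numeric(stats::filter(UC * x, 1 - UC, method = "recursive",
                                  init = init))
    return(list(out = y, state = y[n]))
  }
  nfull <- n %/% d
  if (nfull == 0L) return(list(out = rep(init, n), state = init))
  m <- .colMeans(x[seq_len(nfull * d)], d, nfull)
  y <- as.numeric(stats::filter(UC * m, 1 - UC, method = "recursive",
                                init = init))
  out <- c(rep(init, d - 1L), rep(y, each = d))[seq_len(n)]
  list(out = out, state = y[nfull])
}

#' Run one first-order IIR low-pass stage
#'
#' Implements `y_i = (1 - UC) y_{i-1} + UC x_i`, seeded with
#' `initial_state` as `y_0`. With `decimation > 1` the recursion advances
#' once per block of `decimation` input samples, using the block mean as
#' its input (an anti-aliased decimator: the boxcar pre-average has nulls
#' at all multiples of the decimated rate, so pulse harmonics cannot fold
#' into a very-low-frequency trend), and the output is held between
#' updates.
#'
#' @param x Numeric sample vector (finite, non-empty).
#' @param cfg A [filter_stage].
#' @param initial_state Seed value `y_0`.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' iir_stage(rep(1, 10), filter_stage(UC = 0.1), 0)  # 1 - 0.9^(1:10)
iir_stage <- function(x, cfg, initial_state = 0) {
  stopifnot(inherits(cfg, "filter_stage"))
  if (length(x) == 0L) stop("iir_stage: empty input")
  if (!all(is.finite(x))) stop("iir_stage: non-finite input sample")
  if (!is.finite(initial_state)) stop("iir_stage: non-finite initial state")
  if (cfg$UC == 1 && cfg$decimation == 1L) return(as.numeric(x))
  lp_run(x, cfg$UC, cfg$decimation, initial_state)$out
}

#' Initialize filter-bank states
#'
#' Seeds every cascade memory so that a subsequent constant input `v0`
#' produces zero in all band-limited outputs from the first sample: stages
#' whose input is the raw signal are set to `v0`, stages operating on
#' already high-passed (zero-mean) branches are set to 0.
#'
#' @param v0 Light value at the operating point (dimensionless, finite).
#' @param cfg A [filter_bank_config].
#' @return Named list of per-stage memories (plus the derivative-branch
#'   previous-value slot `drh_prev`).
#' @export
init_filter_states <- function(v0, cfg) {
  stopifnot(is.finite(v0))
  st <- list(pulse1 = v0, pulse2 = 0, vct1 = v0,
             rhy_hp1 = v0, rhy_hp2 = 0,
             rhy_lp1 = 0, rhy_lp2 = 0, rhy_lp3 = 0, rhy_lp4 = 0,
             drh_lp1 = 0, drh_lp2 = 0, drh_prev = 0)
  st
}

#' Decompose a PPG signal into the four control components
#'
#' Applies the filter cascade to a dimensionless light signal, producing
#' `v_Pulse` (content above the pulse cutoff), `v_Rhythm` (rhythm band),
#' `v_dRhythm` (band-limited derivative of the rhythm component) and
#' `v_VCT` (very-low-frequency content removed, pulses retained).
#'
#' @param v A dimensionless [sampled_signal] whose `fs` matches the
#'   configuration design rate.
#' @param cfg A [filter_bank_config].
#' @param states Stage memories from [init_filter_states()]; defaults to
#'   seeding with the first sample.
#' @return An object of class `filter_bank_output`: list with the four
#'   component [sampled_signal]s and the updated `states`.
#' @export
decompose <- function(v, cfg = filter_bank_config(), states = NULL) {
  stopifnot(inherits(v, "sampled_signal"))
  if (v$unit != "dimensionless")
    stop("decompose: v must be dimensionless")
  if (abs(v$fs - cfg$fs) > 1e-9)
    stop("decompose: signal fs does not match filter design rate")
  x <- v$values
  if (length(x) == 0L) stop("decompose: empty signal")
  if (is.null(states)) states <- init_filter_states(x[1], cfg)
  s <- cfg$stages
  new_states <- states
  run <- function(name, input) {
    r <- lp_run(input, s[[name]]$UC, s[[name]]$decimation, states[[name]])
    new_states[[name]] <<- r$state
    r$out
  }

  # pulse branch: two cascaded high-pass blocks (input minus low-pass)
  u1 <- x - run("pulse1", x)
  v_pulse <- u1 - run("pulse2", u1)

  # VCT branch: first-order washout of the < cutoff_vlf trend, pulses kept
  v_vct <- x - run("vct1", x)

  # rhythm branch: VLF high-pass then 4-stage low-pass at the band top
  r1 <- x - run("rhy_hp1", x)
  r2 <- r1 - run("rhy_hp2", r1)
  v_rhythm <- run("rhy_lp4", run("rhy_lp3", run("rhy_lp2",
                                                run("rhy_lp1", r2))))

  # derivative branch: first difference of v_Rhythm at the decimated rate,
  # scaled to per-second units, then smoothed
  d <- s$drh_lp1$decimation
  fs_d <- cfg$fs / d
  nfull <- length(x) %/% d
  if (nfull > 0) {
    rd <- v_rhythm[seq_len(nfull) * d]   # values at block ends
    dr <- c(rd[1] - states$drh_prev, diff(rd)) * fs_d
    dr_full <- c(rep(0, d - 1L), rep(dr, each = d))[seq_along(x)]
    new_states$drh_prev <- rd[nfull]
  } else {
    dr_full <- rep(0, length(x))
  }
  d1 <- run("drh_lp1", dr_full)
  v_drhythm <- run("drh_lp2", d1)
  mk <- function(vals, lab) sampled_signal(vals, fs = v$fs, t0 = v$t0,
                                           unit = "dimensionless",
                                           label = lab)
  structure(list(v_Pulse = mk(v_pulse, "v_Pulse"),
                 v_Rhythm = mk(v_rhythm, "v_Rhythm"),
                 v_dRhythm = mk(v_drhythm, "v_dRhythm"),
                 v_VCT = mk(v_vct, "v_VCT"),
                 states = new_states),
            class = "filter_bank_output")
}

#' Frequency response of the filter bank
#'
#' Evaluates the complex transfer function of each of the four outputs on a
#' frequency grid. Decimated stages are evaluated at their decimated rate
#' with a zero-order-hold reconstruction factor (first-harmonic
#' approximation, accurate well below the decimated Nyquist rate).
#'
#' @param cfg A [filter_bank_config].
#' @param f Numeric vector of frequencies in Hz, all in `(0, fs / 2)`.
#' @return Data frame with columns `f`, and complex gains `v_Pulse`,
#'   `v_Rhythm`, `v_dRhythm`, `v_VCT`.
#' @export
frequency_response <- function(cfg, f) {
  if (any(f <= 0 | f >= cfg$fs / 2))
    stop("frequency_response: f must be in (0, fs/2)")
  fs <- cfg$fs
  H_lp <- function(stage, f) {
    d <- stage$decimation
    z <- exp(-2i * pi * f * d / fs)
    h <- stage$UC / (1 - (1 - stage$UC) * z)
    if (d > 1L) {
      zoh <- vapply(f, function(ff)
        mean(exp(-2i * pi * ff * (0:(d - 1)) / fs)), complex(1))
      h <- h * zoh
    }
    h
  }
  s <- cfg$stages
  hp2 <- function(a, b) (1 - H_lp(s[[a]], f)) * (1 - H_lp(s[[b]], f))
  H_pulse <- hp2("pulse1", "pulse2")
  H_vct <- 1 - H_lp(s$vct1, f)
  H_rhy <- hp2("rhy_hp1", "rhy_hp2") *
    H_lp(s$rhy_lp1, f) * H_lp(s$rhy_lp2, f) *
    H_lp(s$rhy_lp3, f) * H_lp(s$rhy_lp4, f)
  d <- s$drh_lp1$decimation
  fs_d <- fs / d
  H_diff <- (1 - exp(-2i * pi * f / fs_d)) * fs_d
  H_drh <- H_rhy * H_diff * H_lp(s$drh_lp1, f) * H_lp(s$drh_lp2, f)
  data.frame(f = f, v_Pulse = H_pulse, v_Rhythm = H_rhy,
             v_dRhythm = H_drh, v_VCT = H_vct)
}
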