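# Beat detection on the pulsatile light component. Under the transmission
# PPG convention used throughout (rising arterial volume absorbs more light),
# systole is a local MINIMUM of v_Pulse.

#' Detect heartbeats in a pulsatile light signal
#'
#' Finds one beat per cardiac cycle on the high-pass filtered pulse
#' component. Systolic troughs are located with an adaptive amplitude
#' threshold (fraction of a running peak-to-trough estimate) and a 250 ms
#' refractory period. A beat is time-stamped (`t_end`) when the signal has
#' risen by a confirmation fraction of the running amplitude above the
#' trough, emulating a detector that fires shortly after the systolic
#' extremum.
#'
#' @param v_Pulse A dimensionless [sampled_signal], normally the `v_Pulse`
#'   output of [decompose()].
#' @param min_amplitude Absolute minimum trough depth to consider
#'   (dimensionless); troughs smaller than this are ignored. On a flat
#'   signal the result is an empty table.
#' @param threshold Fraction of the running amplitude a trough must reach
#'   (default 0.35).
#' @param confirm Fraction of the running amplitude the signal must rise
#'   above the trough before the beat is declared (default 0.2).
#' @param refractory Minimum spacing between systoles in seconds
#'   (default 0.25).
#' @return A data frame of class `beat_table` with columns `t_onset`,
#'   `t_sys`, `t_end`, `PI` (pulse interval between consecutive detections,
#'   `NA` for the first beat), `v_sys`, `v_dia`.
#' @export
detect_beats <- function(v_Pulse, min_amplitude = 1e-4, threshold = 0.35,
                         confirm = 0.2, refractory = 0.25) {
  stopifnot(inherits(v_Pulse, "sampled_signal"))
  x <- v_Pulse$values
  fs <- v_Pulse$fs
  n <- length(x)
  empty <- structure(
    data.frame(t_onset = numeric(0), t_sys = numeric(0),
               t_end = numeric(0), PI = numeric(0),
               v_sys = numeric(0), v_dia = numeric(0)),
    class = c("beat_table", "data.frame"))
  if (n < 5L) return(empty)

  # candidate troughs: strict local minima of x
  dm <- diff(x)
  cand <- which(dm[-1] > 0 & dm[-length(dm)] <= 0) + 1L
  if (!length(cand)) return(empty)

  # running amplitude: peak-to-trough over a sliding 2 s window, floored
  win <- max(3L, as.integer(2 * fs))
  k <- ceiling(n / win)
  hi <- rep(vapply(seq_len(k), function(i)
    max(x[((i - 1) * win + 1):min(i * win, n)]), 0), each = win)[1:n]
  lo <- rep(vapply(seq_len(k), function(i)
    min(x[((i - 1) * win + 1):min(i * win, n)]), 0), each = win)[1:n]
  amp <- pmax(hi - lo, min_amplitude)

  depth <- (lo[cand] + hi[cand]) / 2 - x[cand]  # trough depth below local mid
  cand <- cand[depth > threshold * amp[cand] / 2 &
                 (amp[cand] > 2 * min_amplitude)]
  if (!length(cand)) return(empty)

  # greedy refractory pass, keep deepest trough inside each refractory span
  refr <- as.integer(refractory * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (x[i] < x[keep[length(keep)]]) {
      keep[length(keep)] <- i                 # deeper trough wins
      last <- i
    }
  }

  # confirmation time: first sample after the trough where x has risen by
  # confirm * amplitude above the trough value
  t_end <- vapply(keep, function(i) {
    rise <- confirm * amp[i]
    j <- i
    while (j < n && x[j] - x[i] < rise) j <- j + 1L
    signal_time(v_Pulse)[j]
  }, 0)
  t_sys <- signal_time(v_Pulse)[keep]
  v_sys <- x[keep]
  v_dia <- vapply(seq_along(keep), function(b) {
    i0 <- if (b == 1L) max(1L, keep[b] - as.integer(fs)) else keep[b - 1L]
    max(x[i0:keep[b]])
  }, 0)
  pi_s <- c(NA, diff(t_end))
  onset <- c(t_end[1] - ifelse(is.na(pi_s[2]), 1, pi_s[2]),
             t_end[-length(t_end)])
  out <- data.frame(t_onset = onset, t_sys = t_sys, t_end = t_end,
                    PI = pi_s, v_sys = v_sys, v_dia = v_dia)
  structure(out, class = c("beat_table", "data.frame"))
}
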