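# Antiresonance: the deliberately slow actuator places a pole near the unit
# circle and the loop tends to oscillate at 0.1-1 Hz (typically when the
# breathing rhythm appears in the pressure signal). A spectral resonance
# detector tunes a high-Q IIR notch in the command path.

#' Detect a resonance oscillation in the contact pressure
#'
#' Looks for a dominant, persistent spectral peak of the contact pressure
#' in the resonance band. The window is linearly detrended, the
#' periodogram peak amplitude is estimated as `2 |X_k| / n`, and a
#' detection is reported only when the peak exceeds the amplitude
#' threshold, covers at least `min_cycles` cycles in the window, and is
#' prominent against the median band power.
#'
#' @param p_c Contact pressure window, a mmHg [sampled_signal] of at least
#'   30 s.
#' @param band Resonance band in Hz (default `c(0.1, 1)`).
#' @param amp_threshold Minimum oscillation amplitude in mmHg (default 2).
#' @param min_cycles Minimum number of cycles inside the window.
#' @param prominence Minimum ratio of peak amplitude to the median band
#'   amplitude.
#' @return `NULL` when no resonance is present, otherwise a list with
#'   `freq` (Hz) and `amplitude` (mmHg).
#' @export
detect_resonance <- function(p_c, band = c(0.1, 1), amp_threshold = 2,
                             min_cycles = 3, prominence = 4) {
  stopifnot(inherits(p_c, "sampled_signal"))
  x <- p_c$values
  n <- length(x)
  fs <- p_c$fs
  if (n / fs < 30) stop("resonance detection needs a window of >= 30 s")
  tt <- seq_len(n)
  x <- x - (coef(lm(x ~ tt))[1] + coef(lm(x ~ tt))[2] * tt)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  amp <- 2 * Mod(X) / n
  in_band <- f >= band[1] & f <= band[2] & f >= min_cycles * fs / n
  if (!any(in_band)) return(NULL)
  k <- which(in_band)[which.max(amp[in_band])]
  if (amp[k] < amp_threshold) return(NULL)
  if (amp[k] < prominence * median(amp[in_band])) return(NULL)
  list(freq = f[k], amplitude = amp[k])
}

#' Second-order IIR notch coefficients
#'
#' Constrained biquad with zeros exactly on the unit circle at the notch
#' frequency and poles at radius `1 - pi * bandwidth / fs`, normalized to
#' unity DC gain.
#'
#' @param freq Notch center frequency in Hz, `0 < freq < fs / 2`.
#' @param bandwidth Approximate -3 dB bandwidth in Hz.
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` (length 3) and denominator `a`
#'   (length 3, `a[1] = 1`).
#' @export
notch_coefficients <- function(freq, bandwidth, fs) {
  if (freq <= 0 || freq >= fs / 2) stop("notch frequency must be in (0, fs/2)")
  stopifnot(bandwidth > 0)
  w0 <- 2 * pi * freq / fs
  R <- max(1 - pi * bandwidth / fs, 0)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * R * cos(w0), R^2)
  g <- sum(a) / sum(b)  # unity gain at DC
  list(b = g * b, a = a)
}

#' Apply a notch filter to a sample sequence
#'
#' Gain at the notch frequency is (numerically) zero, DC gain is unity, and
#' the gain recovers to within 1 dB outside `freq +/- 2 * bandwidth`.
#' Start-up is referenced to the first sample (assumed pre-existing DC
#' level) to avoid an initialization transient.
#'
#' @param x Numeric sample vector or [sampled_signal].
#' @param freq Notch center frequency in Hz.
#' @param bandwidth Notch bandwidth in Hz.
#' @param fs Sampling rate (taken from `x` if it is a signal).
#' @return Filtered samples, same type as `x`.
#' @export
notch_filter <- function(x, freq, bandwidth, fs = NULL) {
  sig <- NULL
  if (inherits(x, "sampled_signal")) {
    sig <- x
    fs <- x$fs
    x <- x$values
  }
  stopifnot(!is.null(fs))
  co <- notch_coefficients(freq, bandwidth, fs)
  x0 <- x[1]
  u <- x - x0
  n <- length(u)
  u1 <- c(0, u[-n])
  u2 <- if (n >= 2) c(0, 0, u[-c(n - 1, n)]) else 0
  num <- co$b[1] * u + co$b[2] * u1 + co$b[3] * u2
  y <- as.numeric(stats::filter(num, -co$a[-1], method = "recursive")) + x0
  if (!is.null(sig)) sampled_signal(y, fs = fs, t0 = sig$t0,
                                    unit = sig$unit, label = sig$label)
  else y
}
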