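# Uniformly sampled time series with unit metadata. Carrier for the light
# signal v(t) (dimensionless), contact pressure p_c(t), arterial pressure
# p_a(t) and the calibrated waveform p_C2G(t) (all mmHg).

#' Uniformly sampled signal
#'
#' Container for a uniformly sampled real-valued time series. The time of
#' sample `i` (1-based) is `t0 + (i - 1) / fs`.
#'
#' @param values Numeric vector of samples; must be finite and non-empty.
#' @param fs Sampling frequency in Hz (default 250).
#' @param t0 Start time in seconds.
#' @param unit Unit of the samples, `"mmHg"` or `"dimensionless"`.
#' @param label Free-text label.
#'
#' @return An object of class `sampled_signal`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' length(s$values)
sampled_signal <- function(values, fs = 250, t0 = 0,
                           unit = c("dimensionless", "mmHg"),
                           label = "") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("sampled_signal: need at least one sample")
  if (!all(is.finite(values))) stop("sampled_signal: all samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("sampled_signal: fs must be > 0")
  structure(list(values = values, fs = fs, t0 = t0, unit = unit,
                 label = label),
            class = "sampled_signal")
}

#' Sample times of a signal
#'
#' @param x A [sampled_signal].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz, %.1f s, unit %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, length(x$values) / x$fs, x$unit))
  invisible(x)
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(time_s = signal_time(x), value = x$values)
}

#' Write a signal to CSV with a JSON sidecar
#'
#' Writes a two-column CSV (`time_s,value`) plus a sidecar JSON file
#' (same path with extension `.json`) holding `fs`, `unit`, `label`, `t0`.
#'
#' @param x A [sampled_signal].
#' @param path Path of the CSV file to write.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "sampled_signal"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    list(fs = x$fs, unit = x$unit, label = x$label, t0 = x$t0),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal from CSV (with optional JSON sidecar)
#'
#' Reads a `time_s,value` CSV; lines starting with `#` are ignored. If a
#' sidecar JSON is present its metadata is used, otherwise `fs` is inferred
#' from the time column.
#'
#' @param path Path of the CSV file.
#' @return A [sampled_signal].
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "value") %in% names(df)))
    stop("signal CSV must have columns time_s,value")
  side <- paste0(sub("\\.csv$", "", path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    sampled_signal(df$value, fs = meta$fs, t0 = meta$t0,
                   unit = meta$unit, label = meta$label)
  } else {
    dt <- median(diff(df$time_s))
    sampled_signal(df$value, fs = 1 / dt, t0 = df$time_s[1])
  }
}
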