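# Method-comparison statistics and engineering diagnostics: 10-s window
# averaging, Bland-Altman limits of agreement accounting for multiple
# measurements per subject, direction-of-change (concordance) analysis at a
# 5-min lag, actuator-speed statistics, and the power-budget calculator.

#' Paired test/reference series
#'
#' @param subject Subject (or scenario) identifier, recycled.
#' @param t Time in seconds.
#' @param test,ref Test and reference values (mmHg), time-synchronized.
#' @param valid Logical validity flags (default all `TRUE`).
#' @return Data frame of class `paired_series`.
#' @export
paired_series <- function(subject, t, test, ref, valid = TRUE) {
  df <- data.frame(subject = as.character(subject), t = t, test = test,
                   ref = ref, valid = valid)
  structure(df, class = c("paired_series", "data.frame"))
}

#' Average paired series over non-overlapping windows
#'
#' Window means per subject; windows with fewer than half of their expected
#' samples valid are dropped.
#'
#' @param series A [paired_series()].
#' @param window Window length in seconds (default 10).
#' @return A [paired_series()] of window means (`t` = window midpoints).
#' @export
average_windows <- function(series, window = 10) {
  stopifnot(window > 0)
  out <- lapply(split(series, series$subject), function(df) {
    dt <- median(diff(sort(unique(df$t))))
    expected <- max(1, round(window / dt))
    win <- floor(df$t / window)
    ok <- df$valid
    agg <- lapply(split(seq_len(nrow(df)), win), function(ix) {
      ix <- ix[ok[ix]]
      if (length(ix) < expected / 2) return(NULL)
      data.frame(subject = df$subject[1],
                 t = (win[ix[1]] + 0.5) * window,
                 test = mean(df$test[ix]), ref = mean(df$ref[ix]),
                 valid = TRUE)
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("paired_series", "data.frame"))
}

#' Bland-Altman agreement with repeated measures
#'
#' Bias is the mean of the paired differences. With `repeated = TRUE` the
#' standard deviation used for the 95% limits of agreement partitions the
#' difference variance into between- and within-subject components by
#' one-way analysis of variance on the differences with subject as the
#' factor: `sd^2 = sigma_b^2 + sigma_w^2` where
#' `sigma_w^2 = MSW` and `sigma_b^2 = (MSB - MSW) / m0`,
#' `m0 = (N - sum(n_i^2) / N) / (k - 1)` (the variance-component estimator
#' for unbalanced one-way designs). With a single subject (or
#' `repeated = FALSE`) the simple pooled standard deviation is used.
#'
#' @param series A [paired_series()] (normally after [average_windows()]).
#' @param repeated Account for multiple measurements per subject.
#' @return Object of class `ba_agreement`: `bias`, `sd`, `loa_low`,
#'   `loa_high` (bias +/- 1.96 sd), `n_pairs`, `per_subject` biases.
#' @export
bland_altman <- function(series, repeated = TRUE) {
  d <- series$test - series$ref
  subj <- factor(series$subject)
  n <- length(d)
  bias <- mean(d)
  per_subject <- tapply(d, subj, mean)
  k <- nlevels(subj)
  if (repeated && k < 2) {
    warning("single subject: falling back to simple Bland-Altman")
    repeated <- FALSE
  }
  if (repeated) {
    ni <- as.numeric(table(subj))
    gm <- bias
    ssb <- sum(ni * (per_subject - gm)^2)
    ssw <- sum((d - per_subject[subj])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    m0 <- (n - sum(ni^2) / n) / (k - 1)
    sig_b2 <- max(0, (msb - msw) / m0)
    s <- sqrt(sig_b2 + msw)
  } else {
    s <- sd(d)
  }
  structure(list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n_pairs = n,
                 per_subject = per_subject, repeated = repeated),
            class = "ba_agreement")
}

#' @export
print.ba_agreement <- function(x, ...) {
  cat(sprintf(paste0("<ba_agreement> bias %.2f +/- %.2f mmHg ",
                     "(95%% LoA %.2f to %.2f), n = %d%s\n"),
              x$bias, x$sd, x$loa_low, x$loa_high, x$n_pairs,
              if (x$repeated) ", repeated-measures" else ""))
  invisible(x)
}

#' Sign concordance of paired changes
#'
#' Fraction of delta pairs with the same sign. Pairs with either delta
#' inside the exclusion zone are removed before counting.
#'
#' @param d_test,d_ref Paired changes (mmHg).
#' @param exclusion Exclusion-zone half-width in mmHg (default 0: no
#'   exclusion; zero deltas count as agreeing).
#' @return List with `concordance` and `n`.
#' @export
concordance_deltas <- function(d_test, d_ref, exclusion = 0) {
  stopifnot(length(d_test) == length(d_ref))
  if (exclusion > 0) {
    keep <- abs(d_test) >= exclusion & abs(d_ref) >= exclusion
    d_test <- d_test[keep]
    d_ref <- d_ref[keep]
  }
  list(concordance = mean(sign(d_test) == sign(d_ref)),
       n = length(d_test))
}

#' Concordance of changes over a 5-min lag
#'
#' Forms overlapping delta pairs at `lag` seconds on the averaged grid
#' (stride = one grid step) and counts sign agreement.
#'
#' @param test,ref Aligned series (e.g. 10-s averaged mBP, mmHg).
#' @param step Grid step of the series in seconds (default 10).
#' @param lag Delta lag in seconds (default 300); the series must be at
#'   least twice the lag long.
#' @param exclusion Exclusion zone in mmHg.
#' @return List with `concordance`, `n`, and the delta pairs.
#' @export
concordance_5min <- function(test, ref, step = 10, lag = 300,
                             exclusion = 0) {
  stopifnot(length(test) == length(ref))
  k <- round(lag / step)
  if (length(test) < 2 * k)
    stop("series shorter than twice the delta lag")
  n <- length(test)
  d_test <- test[(k + 1):n] - test[1:(n - k)]
  d_ref <- ref[(k + 1):n] - ref[1:(n - k)]
  c(concordance_deltas(d_test, d_ref, exclusion),
    list(d_test = d_test, d_ref = d_ref))
}

#' Actuator speed statistics
#'
#' Median and maximum of the absolute change of beat-mean contact pressure,
#' per beat and per second (normalized by the pulse interval).
#'
#' @param p_c Contact pressure ([sampled_signal], mmHg).
#' @param beats Data frame with beat times `t` and pulse intervals `PI`
#'   (e.g. the `beats` element of a `vct_result`).
#' @return List with `median_per_beat`, `max_per_beat`, `median_per_s`,
#'   `max_per_s` (mmHg/beat and mmHg/s) and `n_beats`.
#' @export
actuator_speed_stats <- function(p_c, beats) {
  stopifnot(inherits(p_c, "sampled_signal"))
  if (nrow(beats) < 2) stop("actuator speed statistics need >= 2 beats")
  fs <- p_c$fs
  n <- length(p_c$values)
  i_end <- pmin(pmax(round((beats$t - p_c$t0) * fs) + 1L, 1L), n)
  i_start <- pmax(1L, i_end - pmax(1L, round(beats$PI * fs)))
  bm <- vapply(seq_len(nrow(beats)),
               function(b) mean(p_c$values[i_start[b]:i_end[b]]), 0)
  dpb <- abs(diff(bm))
  dps <- dpb / beats$PI[-1]
  list(median_per_beat = median(dpb), max_per_beat = max(dpb),
       median_per_s = median(dps), max_per_s = max(dps),
       n_beats = nrow(beats))
}

#' Maximum windowed slew rate of a pressure signal
#'
#' Largest absolute change of the applied pressure over any window of
#' `window` seconds, expressed in mmHg/s.
#'
#' @param p_c A mmHg [sampled_signal].
#' @param window Window length in seconds (default 1).
#' @return Maximum rate in mmHg/s.
#' @export
max_slew_rate <- function(p_c, window = 1) {
  stopifnot(inherits(p_c, "sampled_signal"))
  k <- round(window * p_c$fs)
  x <- p_c$values
  if (length(x) <= k) return(0)
  max(abs(x[(k + 1):length(x)] - x[1:(length(x) - k)])) / window
}

#' Power budget
#'
#' Sums component powers and converts to 24-h energy. The default
#' component set is the wearable sensor's: actuator 45.19 mW, PPG system
#' 5.64 mW, low-power bluetooth microcontroller 1.66 mW, motion sensor
#' 6.21 mW.
#'
#' @param components Data frame with `name` and `power_mW` columns, or a
#'   named numeric vector of average powers in mW (>= 0).
#' @param duty Optional free-text duty-cycle description.
#' @return Object of class `power_budget`: `components`, `total_mW`,
#'   `energy_24h_mWh` (= total x 24).
#' @export
#' @examples
#' power_budget()$total_mW  # 58.7
power_budget <- function(components = c(actuator = 45.19, ppg = 5.64,
                                        mcu = 1.66, motion = 6.21),
                         duty = "45 s initial + 2 min VCT + 13 min interpolation") {
  if (is.data.frame(components)) {
    comp <- setNames(components$power_mW, components$name)
  } else comp <- components
  if (any(comp < 0)) stop("component powers must be >= 0")
  total <- sum(comp)
  structure(list(components = comp, duty = duty, total_mW = total,
                 energy_24h_mWh = total * 24), class = "power_budget")
}

#' @export
print.power_budget <- function(x, ...) {
  cat("<power_budget>\n")
  for (nm in names(x$components))
    cat(sprintf("  %-10s %7.2f mW\n", nm, x$components[[nm]]))
  cat(sprintf("  total      %7.2f mW, %.1f mWh / 24 h\n",
              x$total_mW, x$energy_24h_mWh))
  invisible(x)
}
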