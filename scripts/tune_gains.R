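#!/usr/bin/env Rscript
# One-time tuning of the default controller gains on the standard scenario
# suite. The chosen defaults are frozen in controller_gains(); re-running
# this script reproduces the selection table. Usage:
#   Rscript scripts/tune_gains.R [duration_s]
suppressPackageStartupMessages(library(vctbp))

args <- commandArgs(trailingOnly = TRUE)
dur <- if (length(args) >= 1) as.numeric(args[1]) else 1800

suite_stats <- function(gains, duration, seed = 1) {
  suite <- standard_scenarios(duration)
  pairs <- lapply(names(suite), function(nm) {
    pr <- tracked_pairs(run_closed_loop(suite[[nm]], gains = gains,
                                        seed = seed))
    paired_series(nm, pr$t, pr$tracked, pr$truth)
  })
  ser <- do.call(rbind, pairs)
  ba <- bland_altman(structure(ser, class = c("paired_series",
                                              "data.frame")))
  c(bias = ba$bias, sd = ba$sd, n = ba$n_pairs)
}

grid <- expand.grid(c_BBI = c(30, 45, 60), c_BBP = c(20, 40),
                    c_P = c(15, 25, 40))
cat("grid search over beat and rhythm gains",
    sprintf("(%d combinations, %.0f-s scenarios)\n", nrow(grid), dur))
for (i in seq_len(nrow(grid))) {
  g <- controller_gains(grid$c_BBI[i], grid$c_BBP[i], grid$c_P[i])
  s <- suite_stats(g, dur)
  cat(sprintf("c_BBI=%2d c_BBP=%2d c_P=%2d -> bias %+5.2f sd %5.2f (n=%d)\n",
              grid$c_BBI[i], grid$c_BBP[i], grid$c_P[i],
              s["bias"], s["sd"], s["n"]))
}

cat("\nfrozen defaults:\n")
print(unclass(controller_gains()))
s <- suite_stats(controller_gains(), dur)
cat(sprintf("frozen defaults -> bias %+5.2f sd %5.2f (n=%d)\n",
            s["bias"], s["sd"], s["n"]))
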