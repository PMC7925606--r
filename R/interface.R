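# Configuration and command-line binding: YAML run configuration, output
# writing and a small subcommand dispatcher (exposed to the shell through
# the inst/cli/vctbp script).

#' Read a run configuration
#'
#' YAML with optional sections `filter_bank`, `controller`, `actuator`,
#' `scenario`, `evaluation`, plus `seed` and `out`.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Materialize configuration objects from a run configuration
#'
#' @param cfg List from [read_run_config()] (may be empty).
#' @return List with `fb`, `gains`, `act`, `scn` (may be `NULL`), `seed`.
#' @export
resolve_run_config <- function(cfg = list()) {
  mk <- function(f, args) do.call(f, args[names(args) %in% names(formals(f))])
  list(
    fb = mk(filter_bank_config, cfg$filter_bank %||% list()),
    gains = mk(controller_gains, cfg$controller %||% list()),
    act = mk(actuator_config, cfg$actuator %||% list()),
    scn = if (!is.null(cfg$scenario)) {
      if (is.character(cfg$scenario)) pick_scenario(cfg$scenario)
      else mk(scenario, cfg$scenario)
    },
    seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pick_scenario <- function(name, duration = 1800) {
  suite <- standard_scenarios(duration)
  if (grepl("^standard-[0-9]+$", name)) {
    i <- as.integer(sub("standard-", "", name))
    if (i < 1 || i > length(suite)) stop("unknown scenario: ", name)
    return(suite[[i]])
  }
  if (!name %in% names(suite)) stop("unknown scenario: ", name)
  suite[[name]]
}

parse_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[[i + 1]], "--")) {
        out[[key]] <- args[[i + 1]]
        i <- i + 2
      } else {
        out[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1
    }
  }
  out
}

write_log <- function(dir, lines) {
  con <- file(file.path(dir, "run.log"), open = "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     lines), con)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a scenario's signals and ground truth),
#' `run-loop` (full closed-loop run), `oscillometry` (open-loop ramp and
#' envelope), `evaluate` (agreement report for two signal files),
#' `power-budget`, `scenarios` (list the standard suite). Every run writes
#' its resolved configuration and seed next to its outputs so it can be
#' reproduced bit-identically.
#'
#' @param args Character vector of command-line arguments (first element:
#'   the subcommand).
#' @return Integer exit code (0 on success, 2 on usage errors), invisibly.
#' @export
vct_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vctbp <subcommand> [options]",
    "  scenarios",
    "  simulate    --scenario <name> [--seed N] [--duration S] --out DIR",
    "  run-loop    --scenario <name> [--seed N] [--duration S] --out DIR",
    "  oscillometry [--ramp start,stop,rate] [--mbP 90] [--seed N] --out FILE",
    "  evaluate    --test a.csv --ref b.csv --report FILE",
    "  power-budget [--config FILE] [--out FILE]", sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[[1]]
  opt <- parse_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  ok <- switch(
    cmd,
    scenarios = {
      cat(sprintf("standard-%02d  %s\n", seq_along(standard_scenarios(60)),
                  names(standard_scenarios(60))))
      TRUE
    },
    simulate = {
      if (is.null(opt$scenario) || is.null(opt$out)) {
        message(usage)
        return(invisible(2L))
      }
      dur <- as.numeric(opt$duration %||% 1800)
      scn <- pick_scenario(opt$scenario, dur)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      cfg <- bp_trajectory_config(duration = scn$duration, hr = scn$hr,
                                  sbp = scn$sbp, dbp = scn$dbp,
                                  resp = scn$resp, mayer = scn$mayer,
                                  events = scn$events)
      gen <- generate_arterial_bp(cfg, seed = seed + scn$seed_offset)
      tone <- tone_trajectory(scn, length(gen$p_a$values))
      write_signal_csv(gen$p_a, file.path(opt$out, "p_a.csv"))
      truth <- gen$truth
      truth$tone <- tone[pmin(round(truth$t_onset * 250) + 1,
                              length(tone))]
      write.csv(truth[, c("t_onset", "sBP", "dBP", "mBP", "tone")],
                file.path(opt$out, "truth.csv"), row.names = FALSE)
      jsonlite::write_json(list(scenario = scn$name, seed = seed),
                           file.path(opt$out, "config.json"),
                           auto_unbox = TRUE)
      write_log(opt$out, sprintf("simulate %s seed=%d", scn$name, seed))
      TRUE
    },
    `run-loop` = {
      if (is.null(opt$scenario) || is.null(opt$out)) {
        message(usage)
        return(invisible(2L))
      }
      dur <- as.numeric(opt$duration %||% 1800)
      scn <- pick_scenario(opt$scenario, dur)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      res <- run_closed_loop(scn, seed = seed)
      write_signal_csv(res$signals$p_c, file.path(opt$out, "p_c.csv"))
      write_signal_csv(res$signals$p_C2G, file.path(opt$out, "p_c2g.csv"))
      b <- res$beats
      out <- data.frame(t_beat = b$t, PI_s = b$PI, Pn_mmHg = b$Pn,
                        Vbar = b$Vbar, mBP_mmHg = b$tracked_mBP,
                        quality = b$quality)
      write.csv(out, file.path(opt$out, "beats.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(scenario = scn$name, seed = seed, duration = dur,
             gains = unclass(controller_gains()),
             failed = res$failed),
        file.path(opt$out, "config.json"), auto_unbox = TRUE, digits = NA)
      write_log(opt$out, sprintf("run-loop %s seed=%d failed=%s",
                                 scn$name, seed, res$failed))
      TRUE
    },
    oscillometry = {
      if (is.null(opt$out)) {
        message(usage)
        return(invisible(2L))
      }
      rp <- as.numeric(strsplit(opt$ramp %||% "0,200,2", ",")[[1]])
      bp <- bp_trajectory_config(duration = (rp[2] - rp[1]) / rp[3] + 5,
                                 sbp = 120, dbp = 75)
      env <- run_oscillometry(bp, ramp = ramp_protocol(rp[1], rp[2], rp[3]),
                              seed = seed)
      env <- estimate_sbp_dbp(env)
      jsonlite::write_json(
        list(A = env$A, mu = env$mu, sigma = env$sigma, mBP = env$mBP,
             P0 = env$P0, v0 = env$v0, sBP = env$sBP, dBP = env$dBP,
             fit_rmse = env$fit_rmse, n_points = nrow(env$points)),
        opt$out, auto_unbox = TRUE, digits = NA)
      TRUE
    },
    evaluate = {
      if (is.null(opt$test) || is.null(opt$ref) || is.null(opt$report)) {
        message(usage)
        return(invisible(2L))
      }
      ts <- read_signal_csv(opt$test)
      rs <- read_signal_csv(opt$ref)
      n <- min(length(ts$values), length(rs$values))
      ser <- paired_series("s1", signal_time(ts)[1:n], ts$values[1:n],
                           rs$values[1:n])
      avg <- average_windows(ser, 10)
      ba <- bland_altman(avg, repeated = FALSE)
      rep <- list(bias = ba$bias, sd = ba$sd, loa_low = ba$loa_low,
                  loa_high = ba$loa_high, n_pairs = ba$n_pairs)
      if (nrow(avg) >= 60) {
        cc <- concordance_5min(avg$test, avg$ref)
        rep$concordance_5min <- cc$concordance
        rep$n_deltas <- cc$n
      }
      jsonlite::write_json(rep, opt$report, auto_unbox = TRUE, digits = NA)
      TRUE
    },
    `power-budget` = {
      pb <- if (!is.null(opt$config)) {
        cfg <- read_run_config(opt$config)
        power_budget(setNames(as.numeric(unlist(cfg$components)),
                              names(cfg$components)))
      } else power_budget()
      print(pb)
      if (!is.null(opt$out))
        jsonlite::write_json(
          list(components = as.list(pb$components),
               total_mW = pb$total_mW, energy_24h_mWh = pb$energy_24h_mWh),
          opt$out, auto_unbox = TRUE, digits = NA)
      TRUE
    },
    {
      message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(2L))
    })
  invisible(if (isTRUE(ok)) 0L else 1L)
}
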