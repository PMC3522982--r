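# Configuration and command-line surface. Every energy or time given as text
# must carry a unit suffix (200meV, 0.15ns): the literature this model lives
# in mixes eV, meV and cm^-1 freely, and silent unit defaults are how those
# numbers get corrupted. The CLI is a thin dispatcher — each subcommand calls
# exactly the exported function of the same purpose and prints its result.

#' Parse a quantity string with a mandatory unit suffix
#'
#' `parse_energy_string("200meV")` returns [energy()] objects;
#' `parse_time_string("0.15ns")` returns seconds. Recognized time suffixes:
#' s, ms, us, ns, ps.
#'
#' @param text A string like `"200meV"`, `"0.027eV"`, `"2600cm-1"`,
#'   `"0.15ns"`, `"1ms"`.
#' @return [parse_energy_string()]: an [energy()]; [parse_time_string()]:
#'   numeric seconds.
#' @examples
#' parse_energy_string("30meV")
#' parse_time_string("87ns")
#' @export
parse_energy_string <- function(text) {
  m <- regmatches(text, regexec("^([-+0-9.eE]+)\\s*(eV|meV|cm-1|cm\\^-1|J)$",
                                text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse energy '", text,
         "': expected e.g. 200meV, 0.027eV, 2600cm-1", call. = FALSE)
  }
  energy(as.numeric(m[2]), m[3])
}

#' @rdname parse_energy_string
#' @export
parse_time_string <- function(text) {
  m <- regmatches(text, regexec("^([-+0-9.eE]+)\\s*(ps|ns|us|ms|s)$",
                                text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse time '", text, "': expected e.g. 0.15ns, 30us, 1ms",
         call. = FALSE)
  }
  as.numeric(m[2]) * switch(m[3], ps = 1e-12, ns = 1e-9, us = 1e-6,
                            ms = 1e-3, s = 1)
}

.config_known_keys <- c("receptor_params", "kinetics", "receptors", "io",
                        "seed", "verbosity")

#' Read / write a run configuration
#'
#' Run configurations are YAML with keys `receptor_params`, `kinetics`,
#' `receptors`, `io`, `seed`, `verbosity` (all optional, unknown keys
#' rejected). Quantities are strings with unit suffixes, e.g.
#' `vibrational_quantum: 200meV`, `window_time: 1ns`. Reading validates and
#' returns the built objects; writing a read configuration round-trips.
#'
#' @param path YAML file path.
#' @return [read_run_config()]: a list of class `run_config` with elements
#'   `receptor_params` ([receptor_params()] or NULL), `kinetics`
#'   ([kinetics_scenario()] or NULL), `receptors` (list of
#'   [receptor_definition()]), `io`, `seed`, `verbosity`, and `raw` (the
#'   parsed YAML, used for round-tripping).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_known_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rp <- NULL
  if (!is.null(raw$receptor_params)) {
    q <- raw$receptor_params
    args <- list()
    if (!is.null(q$vibrational_quantum))
      args$vibrational_quantum <- parse_energy_string(q$vibrational_quantum)
    if (!is.null(q$huang_rhys)) args$huang_rhys <- q$huang_rhys
    if (!is.null(q$reorganization))
      args$reorganization <- parse_energy_string(q$reorganization)
    if (!is.null(q$matrix_element))
      args$matrix_element <- parse_energy_string(q$matrix_element)
    if (!is.null(q$temperature_energy))
      args$temperature_energy <- parse_energy_string(q$temperature_energy)
    if (!is.null(q$da_gap)) args$da_gap <- parse_energy_string(q$da_gap)
    rp <- do.call(receptor_params, args)
  }
  kin <- NULL
  if (!is.null(raw$kinetics)) {
    k <- raw$kinetics
    args <- list()
    for (f in c("tunnel_time_right", "tunnel_time_wrong", "window_time",
                "replenish_time", "integration_window")) {
      if (!is.null(k[[f]])) args[[f]] <- parse_time_string(k[[f]])
    }
    kin <- do.call(kinetics_scenario, args)
  }
  receptors <- lapply(raw$receptors, function(r) {
    receptor_definition(
      name = r$name, tuned_frequency = r$tuned_frequency,
      resolution_window = if (is.null(r$resolution_window)) 25
                          else r$resolution_window,
      coupling_range = if (is.null(r$coupling_range))
        coupling_range_preset("broad") else unlist(r$coupling_range)
    )
  })
  structure(
    list(receptor_params = rp, kinetics = kin, receptors = receptors,
         io = raw$io, seed = raw$seed,
         verbosity = if (is.null(raw$verbosity)) 0L else raw$verbosity,
         raw = raw),
    class = "run_config"
  )
}

#' @rdname read_run_config
#' @param config A `run_config` (from [read_run_config()]) or a plain list
#'   using only the known keys.
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  unknown <- setdiff(names(raw), .config_known_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

# ---- CLI ------------------------------------------------------------------

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'", call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

.cli_params_from_flags <- function(flags) {
  args <- list()
  if (!is.null(flags[["hw0"]])) args$vibrational_quantum <- parse_energy_string(flags[["hw0"]])
  if (!is.null(flags[["S"]])) args$huang_rhys <- as.numeric(flags[["S"]])
  if (!is.null(flags[["lambda"]])) args$reorganization <- parse_energy_string(flags[["lambda"]])
  if (!is.null(flags[["t"]])) args$matrix_element <- parse_energy_string(flags[["t"]])
  if (!is.null(flags[["kT"]])) args$temperature_energy <- parse_energy_string(flags[["kT"]])
  if (!is.null(flags[["gap"]])) args$da_gap <- parse_energy_string(flags[["gap"]])
  do.call(receptor_params, args)
}

.cli_write_json <- function(x, flags) {
  if (!is.null(flags[["out"]])) {
    jsonlite::write_json(x, flags[["out"]], auto_unbox = TRUE, digits = NA)
  }
}

.cli_rates <- function(flags) {
  p <- .cli_params_from_flags(flags)
  cmp <- channel_comparison(p)
  cat(sprintf("tau_T0 (non-discriminating) ~ %s ns\n",
              format(signif(cmp$tau_T0 * 1e9, 2))))
  cat(sprintf("tau_T1 (discriminating)     ~ %s ns\n",
              format(signif(cmp$tau_T1 * 1e9, 2))))
  cat(sprintf("ratio tau_T0 / tau_T1       ~ %s\n", format(signif(cmp$ratio, 2))))
  .cli_write_json(list(tau_T0_s = cmp$tau_T0, tau_T1_s = cmp$tau_T1,
                       ratio = cmp$ratio), flags)
}

.cli_crossover <- function(flags) {
  p <- .cli_params_from_flags(flags)
  lam <- crossover_lambda(p)
  cat(sprintf("crossover lambda* ~ %s meV\n",
              format(signif(as_eV(lam) * 1e3, 2))))
  .cli_write_json(list(lambda_star_eV = as_eV(lam)), flags)
}

.cli_sweep <- function(flags) {
  p <- .cli_params_from_flags(flags)
  lo <- if (is.null(flags[["from"]])) energy(5, "meV") else parse_energy_string(flags[["from"]])
  hi <- if (is.null(flags[["to"]])) energy(100, "meV") else parse_energy_string(flags[["to"]])
  n <- if (is.null(flags[["n"]])) 40L else as.integer(flags[["n"]])
  grid <- seq(as_eV(lo), as_eV(hi), length.out = n)
  tab <- lambda_sweep(p, grid)
  if (!is.null(flags[["out"]])) {
    utils::write.table(tab, flags[["out"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat("sweep written to ", flags[["out"]], "\n", sep = "")
  } else {
    utils::write.table(format(tab, digits = 6), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
}

.cli_scenario_from_flags <- function(flags) {
  args <- list()
  if (!is.null(flags[["tauM"]])) args$tunnel_time_right <- parse_time_string(flags[["tauM"]])
  if (!is.null(flags[["tauW"]])) args$tunnel_time_wrong <- parse_time_string(flags[["tauW"]])
  if (!is.null(flags[["tauR"]])) args$window_time <- parse_time_string(flags[["tauR"]])
  if (!is.null(flags[["tauD"]])) args$replenish_time <- parse_time_string(flags[["tauD"]])
  if (!is.null(flags[["window"]])) args$integration_window <- parse_time_string(flags[["window"]])
  do.call(kinetics_scenario, args)
}

.cli_kinetics <- function(flags) {
  s <- .cli_scenario_from_flags(flags)
  fr <- frustration_ratio(s)
  sep <- signal_separation(s)
  dM <- delayed_transfer_time(s$replenish_time, s$tunnel_time_right, s$window_time)
  dW <- delayed_transfer_time(s$replenish_time, s$tunnel_time_wrong, s$window_time)
  cat(sprintf("frustration ratio (right:wrong successes) ~ %s\n",
              format(signif(fr, 2))))
  cat(sprintf("delayed signal time, right  ~ %s s\n", format(signif(dM, 2))))
  cat(sprintf("delayed signal time, wrong  ~ %s s\n", format(signif(dW, 2))))
  cat(sprintf("signal separation           ~ %s s\n", format(signif(sep, 2))))
  .cli_write_json(list(frustration_ratio = fr, delayed_right_s = dM,
                       delayed_wrong_s = dW, separation_s = sep), flags)
}

.cli_simulate <- function(flags) {
  if (is.null(flags[["seed"]])) stop("simulate requires --seed", call. = FALSE)
  s <- .cli_scenario_from_flags(flags)
  n <- if (is.null(flags[["n"]])) 1000L else as.integer(flags[["n"]])
  mode <- if (is.null(flags[["mode"]])) "single_shot" else flags[["mode"]]
  tr <- simulate_receptor_cycle(s, n_dockings = n,
                                seed = as.integer(flags[["seed"]]), mode = mode)
  cat(sprintf("dockings %d: influxes right %d (%s), wrong %d (%s)\n",
              tr$n_dockings, tr$influx_events_right,
              format(signif(tr$influx_events_right / tr$n_dockings, 2)),
              tr$influx_events_wrong,
              format(signif(tr$influx_events_wrong / tr$n_dockings, 2))))
  .cli_write_json(list(seed = tr$seed, mode = tr$mode, n_dockings = tr$n_dockings,
                       influx_events_right = tr$influx_events_right,
                       influx_events_wrong = tr$influx_events_wrong), flags)
}

.cli_discriminate <- function(flags) {
  if (is.null(flags[["spectrum"]])) stop("discriminate requires --spectrum <tsv>",
                                    call. = FALSE)
  if (is.null(flags[["tuned"]])) stop("discriminate requires --tuned <cm-1>",
                                 call. = FALSE)
  sp <- read_spectrum(flags[["spectrum"]])
  window <- if (is.null(flags[["window"]])) 25 else as.numeric(flags[["window"]])
  rec <- receptor_definition("cli-receptor", as.numeric(flags[["tuned"]]), window)
  rep <- receptor_activation(sp, rec)
  print(rep)
  .cli_write_json(list(odorant = rep$odorant, receptor = rep$receptor,
                       activated = rep$activated,
                       matching_modes = rep$matching_modes), flags)
}

.cli_fixture <- function(flags) {
  if (is.null(flags[["seed"]])) stop("fixture requires --seed", call. = FALSE)
  n <- if (is.null(flags[["n"]])) 8L else as.integer(flags[["n"]])
  sp <- generate_synthetic_spectrum(n, seed = as.integer(flags[["seed"]]))
  if (!is.null(flags[["out"]])) {
    write_spectrum(sp, flags[["out"]])
    cat("spectrum written to ", flags[["out"]], "\n", sep = "")
  } else {
    print(sp)
  }
}

.cli_constants <- function(flags) {
  tab <- physical_constants()
  print(tab, row.names = FALSE)
  .cli_write_json(tab, flags)
}

#' Command-line entry point
#'
#' Dispatcher behind the `inst/cli/ietolf` script. Subcommands: `rates`,
#' `sweep`, `crossover`, `kinetics`, `simulate`, `discriminate`, `fixture`,
#' `constants`. Energy flags take unit suffixes (`--lambda 62meV`), time
#' flags likewise (`--tauR 1ns`); stochastic subcommands require `--seed`.
#' Human-readable output is printed at 2 significant figures; `--out`
#' writes full-precision machine output (JSON, or TSV for `sweep` and
#' `fixture`). A `--config` flag naming a YAML [read_run_config()] file
#' supplies defaults that explicit flags override.
#'
#' @param args Character vector of command-line arguments
#'   (e.g. `c("rates", "--lambda", "30meV")`).
#' @return Invisibly, an integer exit status (0 on success, 1 on any
#'   usage or validation error, which is reported on stderr).
#' @examples
#' ietolf_main(c("rates"))
#' ietolf_main(c("crossover"))
#' @export
ietolf_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: ietolf <subcommand> [--flags]; ",
                                "subcommands: rates, sweep, crossover, ",
                                "kinetics, simulate, discriminate, fixture, ",
                                "constants", call. = FALSE)
    sub <- args[[1]]
    flags <- .cli_parse_flags(args[-1])
    if (!is.null(flags[["config"]])) {
      cfg <- read_run_config(flags[["config"]])
      # config supplies defaults; explicit flags already in `flags` win
      if (!is.null(cfg$seed) && is.null(flags[["seed"]])) flags[["seed"]] <- cfg$seed
      if (!is.null(cfg$receptor_params)) {
        p <- cfg$receptor_params
        defaults <- list(hw0 = paste0(p$hw0, "eV"), S = p$S,
                         lambda = paste0(p$lambda, "eV"),
                         t = paste0(p$t, "eV"), kT = paste0(p$kT, "eV"),
                         gap = paste0(p$gap, "eV"))
        for (k in names(defaults)) {
          if (is.null(flags[[k]])) flags[[k]] <- defaults[[k]]
        }
      }
    }
    switch(sub,
      rates        = .cli_rates(flags),
      sweep        = .cli_sweep(flags),
      crossover    = .cli_crossover(flags),
      kinetics     = .cli_kinetics(flags),
      simulate     = .cli_simulate(flags),
      discriminate = .cli_discriminate(flags),
      fixture      = .cli_fixture(flags),
      constants    = .cli_constants(flags),
      stop("unknown subcommand '", sub, "'", call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("ietolf: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
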