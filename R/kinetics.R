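# Receptor-level kinetic race models. The tunnelling event competes with
# other channels (the electron draining back to its reservoir, the odorant
# leaving); the window of opportunity this competition imposes is what turns
# a rate contrast between "right" and "wrong" odorants into a clean yes/no
# signal. All processes are taken as memoryless (constant hazard), the unique
# realization of a constant per-unit-time probability.

#' Kinetic scenario for the receptor signalling race
#'
#' Bundles the four timescales of the race picture: tunnelling times for the
#' right and wrong molecule, the window-of-opportunity time of the competing
#' process, and the donor-replenishment time, plus the neural integration
#' window.
#'
#' Defaults place tunnelling at the two channel times of the default
#' [receptor_params()] set (0.15 ns right, 87 ns wrong) and the slow supply
#' steps at ~30 us, midway (geometrically) through the 1 us - 1 ms range
#' typical of charge transport along the receptor.
#'
#' @param tunnel_time_right Tunnelling time for the right molecule (tau_M), s.
#' @param tunnel_time_wrong Tunnelling time for the wrong molecule (tau_W), s.
#' @param window_time Competing-process time (tau_R) setting the window of
#'   opportunity, s.
#' @param replenish_time Time to re-supply the donor electron (tau_D), s.
#' @param integration_window Neural integration period, s (default 1 ms).
#' @return An object of class `kinetics_scenario`. A scenario with
#'   `tunnel_time_right > tunnel_time_wrong` is unusual and triggers a
#'   warning, not an error.
#' @examples
#' kinetics_scenario(tunnel_time_right = 0.15e-9, tunnel_time_wrong = 87e-9,
#'                   window_time = 1e-9, replenish_time = 1e-6)
#' @export
kinetics_scenario <- function(tunnel_time_right = 0.15e-9,
                              tunnel_time_wrong = 87e-9,
                              window_time = 30e-6,
                              replenish_time = 30e-6,
                              integration_window = 1e-3) {
  ts <- c(tunnel_time_right, tunnel_time_wrong, window_time, replenish_time,
          integration_window)
  if (any(!is.finite(ts)) || any(ts <= 0)) {
    stop("all scenario times must be finite and > 0 seconds", call. = FALSE)
  }
  if (tunnel_time_right > tunnel_time_wrong) {
    warning("tunnel_time_right > tunnel_time_wrong: the 'wrong' molecule ",
            "tunnels faster than the 'right' one", call. = FALSE)
  }
  structure(
    list(
      tunnel_time_right = tunnel_time_right,
      tunnel_time_wrong = tunnel_time_wrong,
      window_time = window_time,
      replenish_time = replenish_time,
      integration_window = integration_window
    ),
    class = "kinetics_scenario"
  )
}

#' @export
print.kinetics_scenario <- function(x, ...) {
  cat("Receptor kinetics scenario (seconds):\n")
  cat(sprintf("  tunnel right (tau_M)  %s\n", format(signif(x$tunnel_time_right, 2))))
  cat(sprintf("  tunnel wrong (tau_W)  %s\n", format(signif(x$tunnel_time_wrong, 2))))
  cat(sprintf("  window       (tau_R)  %s\n", format(signif(x$window_time, 2))))
  cat(sprintf("  replenish    (tau_D)  %s\n", format(signif(x$replenish_time, 2))))
  cat(sprintf("  integration window    %s\n", format(signif(x$integration_window, 2))))
  invisible(x)
}

#' Probability that tunnelling beats the competing process
#'
#' For two memoryless processes with mean times `tau_X` (tunnelling) and
#' `tau_R` (the competing drain), tunnelling wins the race with probability
#' `tau_R / (tau_R + tau_X)`.
#'
#' @param tunnel_time Mean tunnelling time, s; > 0.
#' @param window_time Mean competing-process time, s; > 0.
#' @return Probability in (0, 1).
#' @examples
#' success_probability(0.15e-9, 1e-9)
#' @export
success_probability <- function(tunnel_time, window_time) {
  if (tunnel_time <= 0 || window_time <= 0) {
    stop("times must be > 0 seconds", call. = FALSE)
  }
  window_time / (window_time + tunnel_time)
}

#' Right-to-wrong success ratio under a finite window
#'
#' Ratio of successful docking events (those producing an ion influx) for
#' the right molecule over the wrong one:
#' `(tau_R + tau_W) / (tau_R + tau_M)`. A short window amplifies the
#' contrast — only the fast discriminating process fits inside it — while an
#' infinite window lets both molecules succeed eventually (ratio -> 1).
#'
#' @param scenario A [kinetics_scenario()].
#' @return Dimensionless ratio; >= 1 whenever tau_W >= tau_M.
#' @examples
#' frustration_ratio(kinetics_scenario(0.15e-9, 87e-9, window_time = 1e-9))
#' @export
frustration_ratio <- function(scenario) {
  stopifnot(inherits(scenario, "kinetics_scenario"))
  (scenario$window_time + scenario$tunnel_time_wrong) /
    (scenario$window_time + scenario$tunnel_time_right)
}

#' Effective signal time under slow donor replenishment
#'
#' When each tunnelling attempt must wait a donor-replenishment time `tau_D`
#' and succeeds per attempt with probability `tau_R / (tau_R + tau_X)`, the
#' expected time to the first successful transfer is
#' `tau_D (1 + tau_X / tau_R)` — the replenishment time inflated by the
#' expected number of attempts.
#'
#' @param replenish_time tau_D, s; > 0.
#' @param tunnel_time tau_X (tau_M or tau_W), s; > 0.
#' @param window_time tau_R, s; > 0.
#' @return Expected signal time, s.
#' @examples
#' delayed_transfer_time(1e-6, 87e-9, 1e-9)    # 88 us
#' @export
delayed_transfer_time <- function(replenish_time, tunnel_time, window_time) {
  if (replenish_time <= 0 || tunnel_time <= 0 || window_time <= 0) {
    stop("times must be > 0 seconds", call. = FALSE)
  }
  replenish_time * (1 + tunnel_time / window_time)
}

#' Separation between wrong- and right-molecule signal times
#'
#' Difference of the two delayed transfer times,
#' `(tau_W - tau_M) * tau_D / tau_R`: slow replenishment (tau_D >> tau_R)
#' stretches the raw tunnelling-time contrast into a far larger gap between
#' observable signal times.
#'
#' @param scenario A [kinetics_scenario()].
#' @return Time separation, s (positive when tau_W > tau_M).
#' @examples
#' signal_separation(kinetics_scenario(0.15e-9, 87e-9, window_time = 1e-9,
#'                                     replenish_time = 1e-7))
#' @export
signal_separation <- function(scenario) {
  stopifnot(inherits(scenario, "kinetics_scenario"))
  (scenario$tunnel_time_wrong - scenario$tunnel_time_right) *
    scenario$replenish_time / scenario$window_time
}

# run body with the RNG seeded, restoring the caller's RNG state afterwards
.with_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  body()
}

#' Stochastic simulation of receptor docking cycles
#'
#' Simulates `n_dockings` docking events for the right molecule and the same
#' number for the wrong one. Per docking, an exponential tunnelling time
#' (mean tau_M or tau_W) races an exponential window (mean tau_R); the
#' docking yields an ion influx when tunnelling wins.
#'
#' In `single_shot` mode each docking produces at most one influx. In
#' `multi_shot` mode a successful influx is followed by a donor-replenishment
#' wait of `replenish_time`, after which the race repeats, until a race is
#' lost or the integration window closes — so one residence can fire several
#' times.
#'
#' @param scenario A [kinetics_scenario()].
#' @param n_dockings Number of docking events per molecule kind; >= 1.
#' @param seed Integer RNG seed (required: runs are reproducible by
#'   construction). The caller's RNG state is left untouched.
#' @param mode `"single_shot"` (default) or `"multi_shot"`.
#' @param record_events If TRUE, keep a per-event log (time, kind).
#' @return An object of class `cycle_trace`: `seed`, `mode`, `n_dockings`,
#'   `influx_events_right`, `influx_events_wrong`, and `event_log` (NULL
#'   unless requested).
#' @examples
#' simulate_receptor_cycle(kinetics_scenario(), n_dockings = 100, seed = 1)
#' @export
simulate_receptor_cycle <- function(scenario, n_dockings, seed,
                                    mode = c("single_shot", "multi_shot"),
                                    record_events = FALSE) {
  stopifnot(inherits(scenario, "kinetics_scenario"))
  mode <- match.arg(mode)
  if (n_dockings < 1 || n_dockings != round(n_dockings)) {
    stop("n_dockings must be a positive integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required", call. = FALSE)
  }

  run_kind <- function(tau_x) {
    influxes <- 0L
    log_t <- numeric(0)
    log_k <- character(0)
    for (i in seq_len(n_dockings)) {
      if (mode == "single_shot") {
        t_tun <- stats::rexp(1, 1 / tau_x)
        t_win <- stats::rexp(1, 1 / scenario$window_time)
        if (t_tun < t_win) {
          influxes <- influxes + 1L
          if (record_events) {
            log_t <- c(log_t, t_tun); log_k <- c(log_k, "influx")
          }
        } else if (record_events) {
          log_t <- c(log_t, t_win); log_k <- c(log_k, "frustrated")
        }
      } else {
        now <- 0
        repeat {
          t_tun <- stats::rexp(1, 1 / tau_x)
          t_win <- stats::rexp(1, 1 / scenario$window_time)
          if (t_tun >= t_win || now + t_tun > scenario$integration_window) {
            if (record_events) {
              log_t <- c(log_t, now + min(t_tun, t_win))
              log_k <- c(log_k, "frustrated")
            }
            break
          }
          now <- now + t_tun
          influxes <- influxes + 1L
          if (record_events) { log_t <- c(log_t, now); log_k <- c(log_k, "influx") }
          now <- now + scenario$replenish_time
          if (now > scenario$integration_window) break
        }
      }
    }
    list(influxes = influxes, log_t = log_t, log_k = log_k)
  }

  res <- .with_seed(seed, function() {
    right <- run_kind(scenario$tunnel_time_right)
    wrong <- run_kind(scenario$tunnel_time_wrong)
    list(right = right, wrong = wrong)
  })

  event_log <- NULL
  if (record_events) {
    event_log <- data.frame(
      molecule = c(rep("right", length(res$right$log_t)),
                   rep("wrong", length(res$wrong$log_t))),
      time = c(res$right$log_t, res$wrong$log_t),
      event = c(res$right$log_k, res$wrong$log_k),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed),
      mode = mode,
      n_dockings = as.integer(n_dockings),
      influx_events_right = res$right$influxes,
      influx_events_wrong = res$wrong$influxes,
      event_log = event_log
    ),
    class = "cycle_trace"
  )
}

#' @export
print.cycle_trace <- function(x, ...) {
  cat(sprintf(
    "cycle trace (%s, seed %d): %d dockings; influxes right %d, wrong %d\n",
    x$mode, x$seed, x$n_dockings, x$influx_events_right, x$influx_events_wrong
  ))
  invisible(x)
}
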