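# The model core: vibronically weighted Marcus-type donor->acceptor transfer
# rates. Channel n = 0 is elastic with respect to the odorant (all energy is
# taken up by environment modes: non-discriminating); channel n = 1 deposits
# one quantum into the odorant's detected mode (discriminating). A receptor is
# "tuned" when its donor-acceptor gap equals the odorant quantum, so the n = 1
# channel is activationless and fast while n = 0 pays a large Marcus penalty.

#' Parameter bundle for the tunnelling-rate model
#'
#' Collects the quantities the transfer-rate expression needs. Defaults are
#' the working parameter set for a tuned receptor: vibrational quantum
#' 200 meV, Huang-Rhys factor S = 0.1, reorganization energy 30 meV,
#' electronic matrix element 1 meV, thermal energy 0.027 eV (physiological),
#' and a donor-acceptor gap equal to the quantum (the tuned case).
#'
#' @param vibrational_quantum Odorant mode quantum `hw0`, [energy()] or eV; > 0.
#' @param huang_rhys Dimensionless electron-vibration coupling S; >= 0.
#' @param reorganization Environment reorganization energy `lambda`; > 0.
#' @param matrix_element Electronic coupling `|t|`; > 0.
#' @param temperature_energy Thermal energy kBT; > 0.
#' @param da_gap Donor-acceptor electronic gap `delta_eps`; defaults to the
#'   vibrational quantum (tuned receptor). Set differently for a detuned one.
#' @return An object of class `receptor_params`.
#' @examples
#' receptor_params()
#' receptor_params(reorganization = energy(62, "meV"))
#' @export
receptor_params <- function(vibrational_quantum = energy(200, "meV"),
                            huang_rhys = 0.1,
                            reorganization = energy(30, "meV"),
                            matrix_element = energy(1, "meV"),
                            temperature_energy = energy(0.027, "eV"),
                            da_gap = vibrational_quantum) {
  p <- list(
    hw0   = as_eV(vibrational_quantum),
    S     = huang_rhys,
    lambda = as_eV(reorganization),
    t     = as_eV(matrix_element),
    kT    = as_eV(temperature_energy),
    gap   = as_eV(da_gap)
  )
  if (p$hw0 <= 0) stop("vibrational_quantum must be > 0", call. = FALSE)
  if (p$S < 0) stop("huang_rhys must be >= 0", call. = FALSE)
  if (p$lambda <= 0) stop("reorganization must be > 0", call. = FALSE)
  if (p$t <= 0) stop("matrix_element must be > 0", call. = FALSE)
  if (p$kT <= 0) stop("temperature_energy must be > 0", call. = FALSE)
  structure(p, class = "receptor_params")
}

#' @export
print.receptor_params <- function(x, ...) {
  cat("Receptor / tunnelling parameters:\n")
  cat(sprintf("  vibrational quantum  %s meV\n", format(signif(x$hw0 * 1e3, 2))))
  cat(sprintf("  Huang-Rhys S         %s\n", format(signif(x$S, 2))))
  cat(sprintf("  reorganization       %s meV\n", format(signif(x$lambda * 1e3, 2))))
  cat(sprintf("  matrix element |t|   %s meV\n", format(signif(x$t * 1e3, 2))))
  cat(sprintf("  thermal energy kBT   %s eV\n", format(signif(x$kT, 2))))
  cat(sprintf("  donor-acceptor gap   %s meV%s\n",
              format(signif(x$gap * 1e3, 2)),
              if (isTRUE(all.equal(x$gap, x$hw0))) " (tuned)" else ""))
  invisible(x)
}

#' Franck-Condon vibronic channel weights
#'
#' Low-temperature Franck-Condon weights for depositing n quanta into a
#' displaced harmonic mode with Huang-Rhys factor S: the Poisson
#' distribution `sigma_n = exp(-S) S^n / n!`. These normalize to 1 over all
#' n; for the weak couplings relevant here (S <= 0.3) the sum over the
#' first ten channels already captures all but ~1e-10 of the weight.
#'
#' @param S Huang-Rhys factor; >= 0.
#' @param n_max Highest channel index returned (default 10).
#' @return Numeric vector `sigma_0 .. sigma_n_max`.
#' @examples
#' vibronic_weights(0.1, 3)
#' @export
vibronic_weights <- function(S, n_max = 10) {
  if (!is.numeric(S) || length(S) != 1L || S < 0) {
    stop("S must be a single number >= 0", call. = FALSE)
  }
  if (n_max < 0) stop("n_max must be >= 0", call. = FALSE)
  n <- 0:n_max
  stats::dpois(n, S)
}

# channel energy: the electronic energy left for the environment after n
# quanta have gone into the odorant mode
.channel_energy <- function(params, n) params$gap - n * params$hw0

#' Vibronically weighted Marcus transfer rate for one channel
#'
#' Golden-rule rate for donor -> acceptor electron transfer in which the
#' odorant mode absorbs `n` quanta:
#' `rate = (2 pi / hbar) |t|^2 sigma_n (4 pi kBT lambda)^(-1/2)
#'         exp(-(eps_n - lambda)^2 / (4 kBT lambda))`
#' with channel energy `eps_n = delta_eps - n * hw0`. For the default tuned
#' parameter set the elastic channel (n = 0) has a characteristic time of
#' about 87 ns while the one-quantum discriminating channel (n = 1) takes
#' about 0.15 ns: the inelastic, odorant-specific route dominates.
#'
#' @param params A [receptor_params()] bundle.
#' @param n Channel index (quanta deposited in the odorant mode); >= 0.
#' @return An object of class `rate_result`: `channel_index`, `rate` (s^-1),
#'   `characteristic_time` (s), `weight` (sigma_n), and
#'   `activation_exponent` (the dimensionless Marcus exponent).
#' @examples
#' transfer_rate(receptor_params(), n = 1)
#' @export
transfer_rate <- function(params, n = 0) {
  stopifnot(inherits(params, "receptor_params"))
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer",
                                   call. = FALSE)
  sigma <- stats::dpois(n, params$S)
  eps_n <- .channel_energy(params, n)
  expo <- (eps_n - params$lambda)^2 / (4 * params$kT * params$lambda)
  rate <- (2 * pi / .const$hbar_eV_s) * params$t^2 * sigma *
    (4 * pi * params$kT * params$lambda)^(-1 / 2) * exp(-expo)
  structure(
    list(
      channel_index = as.integer(n),
      rate = rate,
      characteristic_time = 1 / rate,
      weight = sigma,
      activation_exponent = expo
    ),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "channel n=%d: rate %s s^-1, time %s s (weight %s)\n",
    x$channel_index, format(signif(x$rate, 2)),
    format(signif(x$characteristic_time, 2)), format(signif(x$weight, 2))
  ))
  invisible(x)
}

#' Compare the non-discriminating and discriminating channels
#'
#' Characteristic times of the elastic (n = 0) and one-quantum (n = 1)
#' channels and their ratio. The ratio depends only on the weights and the
#' Marcus exponents — it is exactly independent of the matrix element |t|.
#'
#' @param params A [receptor_params()] bundle.
#' @return List with `tau_T0`, `tau_T1` (seconds) and `ratio` = tau_T0/tau_T1.
#' @examples
#' channel_comparison(receptor_params())
#' @export
channel_comparison <- function(params) {
  r0 <- transfer_rate(params, 0)
  r1 <- transfer_rate(params, 1)
  list(
    tau_T0 = r0$characteristic_time,
    tau_T1 = r1$characteristic_time,
    ratio = r0$characteristic_time / r1$characteristic_time
  )
}

#' Reorganization energy at which the two channels trade places
#'
#' For a tuned receptor (gap = quantum) the elastic channel overtakes the
#' discriminating one once the environment couples strongly enough. Setting
#' the two rates equal gives the closed form
#' `lambda* = hw0^2 / (2 hw0 - 4 kBT ln S)`,
#' about 62 meV for the default parameter set — discrimination requires a
#' weakly coupled (dry, non-polar) environment with lambda below this.
#'
#' @param params A [receptor_params()] bundle; must be tuned
#'   (`da_gap == vibrational_quantum`) with `0 < S <= 1`. For `S > 1` the
#'   inelastic channel is never slower within `(0, hw0)` and an error is
#'   raised.
#' @param method `"closed_form"` (default) or `"bisection"` (numerical root
#'   of the rate ratio, used as an independent cross-check; agrees with the
#'   closed form to better than 1e-9 eV).
#' @return An [energy()] in eV.
#' @examples
#' convert_energy(crossover_lambda(receptor_params()), "meV")
#' @export
crossover_lambda <- function(params, method = c("closed_form", "bisection")) {
  stopifnot(inherits(params, "receptor_params"))
  method <- match.arg(method)
  if (!isTRUE(all.equal(params$gap, params$hw0))) {
    stop("crossover_lambda requires a tuned receptor (da_gap == quantum)",
         call. = FALSE)
  }
  if (params$S <= 0) stop("crossover requires S > 0 (no inelastic channel ",
                          "otherwise)", call. = FALSE)
  if (params$S > 1) {
    stop("no crossover in (0, hw0) for S > 1: the one-quantum channel ",
         "weight already exceeds the elastic one", call. = FALSE)
  }
  if (method == "closed_form") {
    lam <- params$hw0^2 / (2 * params$hw0 - 4 * params$kT * log(params$S))
  } else {
    # log rate0 - log rate1 as a function of lambda; sign change brackets
    # the crossover
    f <- function(lam) {
      p <- params
      p$lambda <- lam
      log(transfer_rate(p, 0)$rate) - log(transfer_rate(p, 1)$rate)
    }
    lam <- stats::uniroot(f, c(1e-3, params$hw0 - 1e-6),
                          tol = 1e-12)$root
  }
  energy(lam, "eV")
}

#' Channel times across a grid of reorganization energies
#'
#' Evaluates both channel times on a user grid of lambda values; the
#' machine-readable table reproduces the characteristic crossing of the two
#' curves at [crossover_lambda()].
#'
#' @param params A [receptor_params()] bundle (its own `lambda` is ignored).
#' @param lambda_grid Energies to sweep: numeric vector in eV, or a list of
#'   [energy()] objects. All must be > 0.
#' @return Data frame with columns `lambda_meV`, `tau0_s`, `tau1_s`.
#' @examples
#' lambda_sweep(receptor_params(), seq(0.01, 0.1, by = 0.01))
#' @export
lambda_sweep <- function(params, lambda_grid) {
  stopifnot(inherits(params, "receptor_params"))
  lams <- if (is.list(lambda_grid)) vapply(lambda_grid, as_eV, numeric(1))
          else as.numeric(lambda_grid)
  if (length(lams) == 0L || any(lams <= 0)) {
    stop("lambda_grid values must be > 0", call. = FALSE)
  }
  rows <- lapply(lams, function(lam) {
    p <- params
    p$lambda <- lam
    c(lambda_meV = lam * 1e3,
      tau0_s = transfer_rate(p, 0)$characteristic_time,
      tau1_s = transfer_rate(p, 1)$characteristic_time)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Inner-shell reorganization energy
#'
#' Harmonic inner-sphere contribution `lambda_i = 1/2 sum k_a Q_a^2` over
#' the modes whose equilibrium positions shift by `Q_a` upon charge
#' transfer, with force constants `k_a`.
#'
#' @param force_constant Numeric vector, eV / Angstrom^2; all >= 0. May be
#'   empty (no inner-shell modes).
#' @param displacement Numeric vector of the same length, Angstrom.
#' @return An [energy()] in eV.
#' @examples
#' inner_shell_reorganization(2, 0.1)   # 0.01 eV
#' @export
inner_shell_reorganization <- function(force_constant = numeric(),
                                       displacement = numeric()) {
  if (length(force_constant) != length(displacement)) {
    stop("force_constant and displacement must have equal length", call. = FALSE)
  }
  if (any(force_constant < 0)) stop("force constants must be >= 0", call. = FALSE)
  energy(0.5 * sum(force_constant * displacement^2), "eV")
}

#' Outer-shell (dielectric continuum) reorganization energy
#'
#' Two-sphere continuum estimate of the environment's slow polarization
#' response to moving a charge `delta_e` between cavities of radii `r1`,
#' `r2` a distance `r12` apart:
#' `lambda_o = delta_e^2 (e^2/4 pi eps0) (1/2r1 + 1/2r2 +- 1/r12)
#'             (1/D_op - 1/D_S)`.
#' In a non-polar binding pocket `D_op ~ D_S` and lambda_o vanishes — the
#' condition the discriminating channel needs. The cross-term sign is
#' selectable: `"as_printed"` uses `+1/r12`; `"standard_marcus"` uses the
#' conventional `-1/r12` of the two-sphere Marcus expression.
#'
#' @param transferred_charge Charge moved, units of e.
#' @param radius_1,radius_2 Cavity radii, Angstrom; > 0.
#' @param separation Centre-to-centre distance `r12`, Angstrom; > 0.
#' @param optical_dielectric Fast (optical) dielectric constant `D_op`; >= 1.
#' @param static_dielectric Static dielectric constant `D_S`; >= `D_op`.
#' @param separation_sign `"as_printed"` (default) or `"standard_marcus"`.
#' @return An [energy()] in eV.
#' @examples
#' outer_shell_reorganization(1, 3, 3, 8, 2, 4,
#'                            separation_sign = "standard_marcus")
#' @export
outer_shell_reorganization <- function(transferred_charge, radius_1, radius_2,
                                       separation, optical_dielectric,
                                       static_dielectric,
                                       separation_sign = c("as_printed",
                                                           "standard_marcus")) {
  separation_sign <- match.arg(separation_sign)
  if (radius_1 <= 0 || radius_2 <= 0 || separation <= 0) {
    stop("radii and separation must be > 0 Angstrom", call. = FALSE)
  }
  if (optical_dielectric < 1 || static_dielectric < optical_dielectric) {
    stop("require D_S >= D_op >= 1", call. = FALSE)
  }
  s <- if (separation_sign == "as_printed") 1 else -1
  geom <- 1 / (2 * radius_1) + 1 / (2 * radius_2) + s / separation
  energy(transferred_charge^2 * .const$coulomb_eV_A * geom *
           (1 / optical_dielectric - 1 / static_dielectric), "eV")
}

#' One-phonon vs two-phonon probability ratio
#'
#' In the very-weak-coupling limit the discriminating one-quantum transition
#' has probability proportional to the detected mode's Huang-Rhys factor
#' `S_M`, while the competing two-phonon transition (two modes sharing the
#' energy) carries `1/2 S' S''`. Their ratio `S_M / (1/2 S' S'')` measures
#' how cleanly one-quantum detection stands above the multiphonon
#' background: for S values in the usual 0.01-0.3 range it is easily a
#' factor of 100-500.
#'
#' @param S_M Huang-Rhys factor of the discriminating mode; >= 0.
#' @param S_prime,S_doubleprime Huang-Rhys factors of the two competing
#'   modes; > 0 (a zero denominator is an error).
#' @return Dimensionless ratio.
#' @examples
#' multiphonon_suppression(0.1, 0.04, 0.04)   # 125
#' @export
multiphonon_suppression <- function(S_M, S_prime, S_doubleprime) {
  if (S_M < 0 || S_prime < 0 || S_doubleprime < 0) {
    stop("Huang-Rhys factors must be >= 0", call. = FALSE)
  }
  denom <- 0.5 * S_prime * S_doubleprime
  if (denom == 0) stop("two-phonon factor is zero: S' and S'' must be > 0",
                       call. = FALSE)
  S_M / denom
}

#' Rate suppression from a reduced electronic matrix element
#'
#' Rates scale as |t|^2, so reducing the electronic coupling by a factor f
#' (e.g. ~30 for an empty receptor losing its through-odorant pathway)
#' suppresses the rate by f^2 (~1000 at f = 30, to order of magnitude).
#'
#' @param reduction_factor Factor by which |t| is reduced; > 0.
#' @return The rate reduction factor `reduction_factor^2`.
#' @examples
#' matrix_element_suppression(30)   # 900
#' @export
matrix_element_suppression <- function(reduction_factor) {
  if (reduction_factor <= 0) stop("reduction_factor must be > 0", call. = FALSE)
  reduction_factor^2
}
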