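# Closed-form oscillator, electrostatic and transport estimates that the
# tunnelling model leans on: thermal occupation of a high-frequency mode,
# zero-point/thermal rms displacement, donor-acceptor Coulomb splitting,
# diffusive vs field-biased charge-transport rates, and isotope frequency
# scaling.

#' Thermal occupation probability of a vibrational mode
#'
#' Boltzmann probability `exp(-hw0 / kBT)` that a mode of quantum `hw0` is
#' found thermally excited. For a typical odorant quantum of 0.2 eV at
#' physiological temperature (kBT = 0.027 eV) this is about 6e-4: odorant
#' modes start in their ground state, which is what lets the inelastic
#' channel *deposit* a quantum rather than absorb one.
#'
#' @param quantum Mode quantum `hw0`, an [energy()] or numeric eV; must be > 0.
#' @param temperature_energy Thermal energy `kBT`, an [energy()] or numeric
#'   eV; must be >= 0. Zero is the documented limit and returns exactly 0.
#' @return Probability in `[0, 1)`.
#' @examples
#' thermal_occupation(energy(0.2, "eV"), energy(0.027, "eV"))
#' @export
thermal_occupation <- function(quantum, temperature_energy) {
  hw <- as_eV(quantum)
  kT <- as_eV(temperature_energy)
  if (hw <= 0) stop("quantum must be > 0", call. = FALSE)
  if (kT < 0) stop("temperature_energy must be >= 0", call. = FALSE)
  if (kT == 0) return(0)
  exp(-hw / kT)
}

#' Root-mean-square thermal displacement of a harmonic oscillator
#'
#' Evaluates `sqrt( (hbar / 2 M w) * coth(hbar w / 2 kBT) )` for a mode of
#' quantum `hbar w` carried by a mass `M`. For a hydrogen-stretch quantum of
#' 360 meV with M = 1 amu at 300 K this gives 0.076 Angstrom — dominated by
#' zero-point motion, since the quantum far exceeds kBT.
#'
#' @param quantum Vibrational quantum `hbar w`, [energy()] or numeric eV; > 0.
#' @param mass Oscillating mass in amu (default 1, the bare-proton
#'   convention for hydrogen stretches; pass a reduced mass to use the
#'   two-body convention instead).
#' @param temperature Temperature in kelvin (default 300). Ignored when
#'   `temperature_energy` is given.
#' @param temperature_energy Optional thermal energy kBT as [energy()] or
#'   numeric eV; overrides `temperature`. Zero gives the zero-point amplitude.
#' @return rms displacement in Angstrom.
#' @examples
#' rms_displacement(energy(360, "meV"))            # ~0.076 Angstrom
#' rms_displacement(energy(360, "meV"), temperature_energy = 0)  # zero-point
#' @export
rms_displacement <- function(quantum, mass = 1, temperature = 300,
                             temperature_energy = NULL) {
  hw <- as_eV(quantum)
  if (hw <= 0) stop("quantum must be > 0", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0) stop("mass must be > 0 amu", call. = FALSE)
  kT <- if (is.null(temperature_energy)) {
    if (temperature < 0) stop("temperature must be >= 0 K", call. = FALSE)
    .const$kB_eV_per_K * temperature
  } else {
    as_eV(temperature_energy)
  }
  if (kT < 0) stop("temperature_energy must be >= 0", call. = FALSE)
  M <- mass * .const$amu_eV_s2_A2
  # <x^2> = hbar^2/(2 M hbar*w) * coth(hbar*w / 2 kBT); coth -> 1 as T -> 0
  coth <- if (kT == 0) 1 else 1 / tanh(hw / (2 * kT))
  sqrt(.const$hbar_eV_s^2 / (2 * M * hw) * coth)
}

#' Donor-acceptor energy splitting from a nearby point charge
#'
#' A single charge placed asymmetrically between the donor and acceptor
#' shifts their site energies by different Coulomb amounts, splitting the
#' pair by `(e^2 / 4 pi eps0) * (1/R_A - 1/R_D) / eps`. A proton at 5 A
#' from the donor and 4 A from the acceptor in a medium with dielectric
#' constant 3 splits them by 0.24 eV, i.e. about 1935 cm^-1 — the right
#' order to tune a receptor's gap onto a vibrational quantum.
#'
#' @param r_donor Distance from the charge to the donor, Angstrom; > 0.
#' @param r_acceptor Distance from the charge to the acceptor, Angstrom; > 0.
#' @param dielectric Relative dielectric constant of the medium; >= 1.
#' @param charge Perturbing charge in units of e (default 1).
#' @return An [energy()] in eV; positive when the acceptor is closer.
#' @examples
#' coulomb_splitting(r_donor = 5, r_acceptor = 4, dielectric = 3)
#' @export
coulomb_splitting <- function(r_donor, r_acceptor, dielectric = 1, charge = 1) {
  if (r_donor <= 0 || r_acceptor <= 0) {
    stop("donor and acceptor radii must be > 0 Angstrom", call. = FALSE)
  }
  if (dielectric < 1) stop("dielectric must be >= 1", call. = FALSE)
  de <- .const$coulomb_eV_A * charge^2 *
    (1 / r_acceptor - 1 / r_donor) / dielectric
  energy(de, "eV")
}

#' Charge-transport rate by unbiased diffusion
#'
#' Model 1 for getting an electron to the donor (or away from the acceptor):
#' charge diffusing a distance `L` with diffusion constant `D` arrives at a
#' characteristic rate `D / L^2`. With D = 1e-4 cm^2/s (liquid-like) and
#' L = 100 nm this is 1e6 per second — a microsecond-scale supply step, far
#' slower than the tunnelling event itself.
#'
#' @param diffusion_coefficient `D` in cm^2/s; > 0.
#' @param distance `L` in nm; > 0.
#' @return Rate in s^-1.
#' @examples
#' diffusive_rate(1e-4, 100)   # 1e6 s^-1
#' @export
diffusive_rate <- function(diffusion_coefficient, distance) {
  if (diffusion_coefficient <= 0) stop("diffusion_coefficient must be > 0",
                                       call. = FALSE)
  if (distance <= 0) stop("distance must be > 0 nm", call. = FALSE)
  L_cm <- distance * 1e-7
  diffusion_coefficient / L_cm^2
}

#' Charge-transport rate under a driving bias
#'
#' Model 2: diffusive motion biased by a potential drop `U` over the same
#' distance. Via the Nernst-Einstein mobility `mu = qD/kBT`, the drift rate
#' is `(qU / kBT) * D / L^2` — it exceeds the unbiased rate exactly when
#' `qU > kBT` (about 26 mV per elementary charge at 300 K).
#'
#' @inheritParams diffusive_rate
#' @param bias_potential `U` in volts.
#' @param charge Moving charge in units of e (default 1).
#' @param temperature_energy Thermal energy kBT, [energy()] or numeric eV;
#'   default kB * 300 K.
#' @return List with `rate` (s^-1), the `diffusive_rate` it is compared to,
#'   and `exceeds_diffusive` (TRUE iff `qU > kBT`).
#' @examples
#' biased_rate(1e-4, 100, bias_potential = 0.5)
#' @export
biased_rate <- function(diffusion_coefficient, distance, bias_potential,
                        charge = 1, temperature_energy = NULL) {
  kT <- if (is.null(temperature_energy)) .const$kB_eV_per_K * 300 else
    as_eV(temperature_energy)
  if (kT <= 0) stop("temperature_energy must be > 0", call. = FALSE)
  base <- diffusive_rate(diffusion_coefficient, distance)
  qU <- charge * bias_potential  # eV when U in volts and q in units of e
  list(
    rate = (qU / kT) * base,
    diffusive_rate = base,
    exceeds_diffusive = qU > kT
  )
}

#' Isotope scaling of a vibrational frequency
#'
#' Frequency ratio and fractional drop when an atom is substituted by a
#' heavier isotope. Under the `proton_only` convention (only the light atom
#' moves, `w ~ 1/sqrt(M)`), H -> D scales frequencies by `1/sqrt(2)`, a
#' fractional drop of `1 - 1/sqrt(2) ~ 0.29` — about 800 cm^-1 for the
#' high-frequency hydrogen stretches. The `reduced_mass` convention uses
#' the diatomic reduced mass with a stated partner atom instead.
#'
#' @param model `"proton_only"` (default) or `"reduced_mass"`.
#' @param mass_original,mass_substituted Masses of the substituted atom in
#'   amu (defaults 1 and 2: H -> D).
#' @param partner_mass Partner-atom mass in amu; required for
#'   `"reduced_mass"` (e.g. 12 for a C-H stretch).
#' @return List with `ratio` (new/old frequency) and `fractional_drop`
#'   (`1 - ratio`).
#' @examples
#' isotope_frequency_factor()                                    # H -> D
#' isotope_frequency_factor("reduced_mass", 1, 2, partner_mass = 12)
#' @export
isotope_frequency_factor <- function(model = c("proton_only", "reduced_mass"),
                                     mass_original = 1, mass_substituted = 2,
                                     partner_mass = NULL) {
  model <- match.arg(model)
  if (mass_original <= 0 || mass_substituted <= 0) {
    stop("masses must be > 0 amu", call. = FALSE)
  }
  ratio <- if (model == "proton_only") {
    sqrt(mass_original / mass_substituted)
  } else {
    if (is.null(partner_mass) || partner_mass <= 0) {
      stop("reduced_mass model needs a positive partner_mass", call. = FALSE)
    }
    mu_old <- mass_original * partner_mass / (mass_original + partner_mass)
    mu_new <- mass_substituted * partner_mass / (mass_substituted + partner_mass)
    sqrt(mu_old / mu_new)
  }
  list(ratio = ratio, fractional_drop = 1 - ratio)
}
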