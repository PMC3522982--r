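# CODATA 2018 constants, in the spectroscopist's working units (eV, Angstrom,
# seconds, amu). Everything downstream converts into these before computing.
.const <- list(
  hbar_eV_s      = 6.582119569e-16,  # reduced Planck constant
  eV_per_cm1     = 1 / 8065.543937,  # energy of one wavenumber
  cm1_per_eV     = 8065.543937,
  J_per_eV       = 1.602176634e-19,
  coulomb_eV_A   = 14.39964,         # e^2 / (4 pi eps0), eV * Angstrom
  kB_eV_per_K    = 8.617333262e-5,
  c_A_per_s      = 2.99792458e18,    # speed of light, Angstrom / s
  amu_eV_per_c2  = 931.49410242e6    # atomic mass unit as rest energy, eV
)

# one amu expressed in eV s^2 / Angstrom^2 (the mass unit that makes
# hbar^2 / (M * E) come out in Angstrom^2)
.const$amu_eV_s2_A2 <- .const$amu_eV_per_c2 / .const$c_A_per_s^2

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 constants underlying every calculation, in the
#' units the package works in (eV, Angstrom, seconds, amu). Useful for
#' cross-checking numbers by hand.
#'
#' @return A data frame with columns `constant`, `value`, `unit`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function() {
  data.frame(
    constant = c(
      "hbar", "1 cm^-1", "1 eV", "e^2/(4 pi eps0)", "k_B",
      "k_B * 300 K", "1 amu"
    ),
    value = c(
      .const$hbar_eV_s, .const$eV_per_cm1, .const$J_per_eV,
      .const$coulomb_eV_A, .const$kB_eV_per_K,
      .const$kB_eV_per_K * 300, .const$amu_eV_s2_A2
    ),
    unit = c(
      "eV s", "eV", "J", "eV Angstrom", "eV / K", "eV", "eV s^2 / Angstrom^2"
    ),
    stringsAsFactors = FALSE
  )
}
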