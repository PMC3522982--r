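# Energy quantities with explicit units. The paper mixes eV, meV and cm^-1
# freely; carrying the unit on the value prevents silent factor-of-8065 bugs.

.energy_units <- c("eV", "meV", "cm-1", "J")

# multiplicative factor taking one unit of `u` to eV
.to_eV_factor <- function(u) {
  switch(u,
    "eV"   = 1,
    "meV"  = 1e-3,
    "cm-1" = .const$eV_per_cm1,
    "J"    = 1 / .const$J_per_eV,
    stop("unknown energy unit: '", u, "' (use one of ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  )
}

.normalize_unit <- function(unit) {
  u <- gsub("⁻¹", "-1", unit)      # cm⁻¹ -> cm-1
  u <- gsub("\\^-1$", "-1", u)               # cm^-1 -> cm-1
  if (identical(tolower(u), "cm-1")) u <- "cm-1"
  if (!u %in% .energy_units) {
    stop("unknown energy unit: '", unit, "' (use one of ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  }
  u
}

#' Create an energy quantity with an explicit unit
#'
#' @param value Numeric scalar (finite).
#' @param unit One of `"eV"`, `"meV"`, `"cm-1"` (also accepted spelled
#'   `"cm^-1"`) or `"J"`.
#' @return An object of class `energy`.
#' @examples
#' energy(200, "meV")
#' energy(2600, "cm-1")
#' @export
energy <- function(value, unit = "eV") {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value)) stop("energy value must be finite", call. = FALSE)
  structure(list(value = value, unit = .normalize_unit(unit)),
            class = "energy")
}

#' @export
print.energy <- function(x, ...) {
  cat(format(signif(x$value, 6)), x$unit, "\n")
  invisible(x)
}

#' Convert an energy quantity to another unit
#'
#' Conversions go through eV using CODATA 2018 factors
#' (1 eV = 8065.543937 cm^-1 = 1.602176634e-19 J) and round-trip to within
#' 1e-12 relative error.
#'
#' @param x An [energy()] object.
#' @param unit Target unit.
#' @return An [energy()] in the target unit.
#' @examples
#' convert_energy(energy(1, "eV"), "cm-1")   # 8065.544 cm-1
#' convert_energy(energy(0.24, "eV"), "cm-1")
#' @export
convert_energy <- function(x, unit) {
  stopifnot(inherits(x, "energy"))
  target <- .normalize_unit(unit)
  if (identical(target, x$unit)) return(x)
  energy(x$value * .to_eV_factor(x$unit) / .to_eV_factor(target), target)
}

#' Numeric value of an energy in eV
#'
#' Plain numerics are passed through and interpreted as eV; this is the
#' coercion every physics routine applies to its energy arguments.
#'
#' @param x An [energy()] object or a plain numeric (assumed eV).
#' @return Numeric scalar, eV.
#' @export
as_eV <- function(x) {
  if (inherits(x, "energy")) return(x$value * .to_eV_factor(x$unit))
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(as.numeric(x))
  stop("expected an energy() object or a finite numeric scalar (eV)",
       call. = FALSE)
}
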