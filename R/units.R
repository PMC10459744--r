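# Reduced unit system and conversions to physical units.
#
# The simulator works in reduced units built from three base scales:
# length = one small-bead diameter (1 nm), mass = one bead mass (32 Da),
# energy = kB * 298 K.  Everything else (time, temperature, moduli,
# concentration) follows from these.

# CODATA values
.kB <- 1.380649e-23      # J/K
.NA <- 6.02214076e23     # 1/mol
.e_charge <- 1.602176634e-19  # C
.eps0 <- 8.8541878128e-12     # F/m
.Da <- 1.66053906660e-27      # kg

#' Reduced unit system of the capsomer model
#'
#' Defines the three base scales of the simulation's reduced units and the
#' derived time and temperature units. Defaults correspond to the capsomer
#' model: length = 1 nm (small-bead diameter), mass = 32 Da (one bead),
#' energy = kB * 298 K.
#'
#' @param length_nm Length unit in nanometres.
#' @param mass_da Mass unit in daltons.
#' @param temperature_K Temperature whose thermal energy defines the energy
#'   unit (energy unit = kB * `temperature_K` joules).
#' @return An object of class `unit_system` with elements `length_m`,
#'   `mass_kg`, `energy_J`, `time_s` (derived as sqrt(m l^2 / e)) and
#'   `temperature_K`.
#' @examples
#' us <- unit_system()
#' us$time_s * 1e12  # about 3.59 ps
#' @export
unit_system <- function(length_nm = 1, mass_da = 32, temperature_K = 298) {
  stopifnot(length_nm > 0, mass_da > 0, temperature_K > 0)
  length_m <- length_nm * 1e-9
  mass_kg <- mass_da * .Da
  energy_J <- .kB * temperature_K
  us <- list(
    length_m = length_m,
    mass_kg = mass_kg,
    energy_J = energy_J,
    time_s = sqrt(mass_kg * length_m^2 / energy_J),
    temperature_K = temperature_K
  )
  class(us) <- "unit_system"
  us
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced unit system:\n")
  cat(sprintf("  length:      %.6g nm\n", x$length_m * 1e9))
  cat(sprintf("  mass:        %.6g Da\n", x$mass_kg / .Da))
  cat(sprintf("  energy:      kB * %.6g K = %.6g J\n",
              x$temperature_K, x$energy_J))
  cat(sprintf("  time:        %.6g ps\n", x$time_s * 1e12))
  cat(sprintf("  temperature: %.6g K\n", x$temperature_K))
  invisible(x)
}

#' Derived time unit of the reduced system
#'
#' The reduced time unit is sqrt(m sigma^2 / epsilon) with m one bead mass,
#' sigma one small-bead diameter, and epsilon the thermal energy at 298 K.
#' With the default scales this evaluates to about 3.59 ps, so a reduced
#' timestep of 0.0005 corresponds to about 1.8 fs and one of 0.002 to about
#' 7 fs.
#'
#' @param us A [unit_system()].
#' @return Time unit in seconds.
#' @export
reduced_time_unit <- function(us = unit_system()) {
  us$time_s
}

#' Convert a reduced quantity to physical units
#'
#' @param x Numeric value(s) in reduced units.
#' @param quantity One of "length" (to m), "mass" (kg), "energy" (J),
#'   "time" (s), "temperature" (K).
#' @param us A [unit_system()].
#' @return `x` expressed in SI units (K for temperature).
#' @export
to_physical <- function(x, quantity = c("length", "mass", "energy", "time",
                                        "temperature"),
                        us = unit_system()) {
  quantity <- match.arg(quantity)
  x * switch(quantity,
             length = us$length_m,
             mass = us$mass_kg,
             energy = us$energy_J,
             time = us$time_s,
             temperature = us$temperature_K)
}

#' Convert a physical quantity to reduced units
#'
#' Inverse of [to_physical()]: `to_reduced(to_physical(x, q), q)` returns
#' `x` to machine precision.
#'
#' @inheritParams to_physical
#' @param x Numeric value(s) in SI units (K for temperature).
#' @return `x` in reduced units.
#' @export
to_reduced <- function(x, quantity = c("length", "mass", "energy", "time",
                                       "temperature"),
                       us = unit_system()) {
  quantity <- match.arg(quantity)
  x / switch(quantity,
             length = us$length_m,
             mass = us$mass_kg,
             energy = us$energy_J,
             time = us$time_s,
             temperature = us$temperature_K)
}

#' Protein concentration of a capsomer system
#'
#' Molar concentration of `n_capsomers` particles in a cubic box of edge
#' `box_edge` nanometres: n / (NA * L^3), reported in micromolar. 100
#' capsomers in a 59 nm box give about 808 uM (the model's standard
#' working concentration, usually quoted as 800 uM).
#'
#' @param n_capsomers Number of capsomers (>= 0).
#' @param box_edge Cubic box edge in nm (> 0).
#' @return Concentration in micromolar.
#' @examples
#' concentration_from_state(100, 59)
#' @export
concentration_from_state <- function(n_capsomers, box_edge) {
  if (any(box_edge <= 0)) stop("box edge must be positive")
  if (any(n_capsomers < 0)) stop("capsomer count must be non-negative")
  litres <- (box_edge * 1e-9)^3 * 1e3      # m^3 -> L
  n_capsomers / (.NA * litres) * 1e6       # mol/L -> uM
}
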