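#' Thermodynamic simulation conditions
#'
#' Bundles the temperature, Boltzmann constant, inverse temperature and
#' standard-state volume used throughout the package.  All energies are in
#' kcal/mol and all lengths in Angstrom; the defaults (310 K, standard
#' volume 1661 A^3 corresponding to the 1 M standard concentration) are the
#' conditions of the kinase unbinding study the package reproduces.
#'
#' @param temperature Simulation temperature in kelvin.
#' @param boltzmann_constant Boltzmann constant in kcal/mol/K.
#' @param standard_volume Standard-state volume per molecule in A^3
#'   (the inverse of the standard concentration C-standard).
#' @return An object of class `sim_conditions` with fields `temperature`,
#'   `boltzmann_constant`, `kT`, `beta` (1/(kB T)) and `standard_volume`.
#' @examples
#' cond <- sim_conditions()
#' cond$kT                      # 0.616 kcal/mol at 310 K
#' 1 / cond$beta - cond$kT      # exactly 0
#' @export
sim_conditions <- function(temperature = 310,
                           boltzmann_constant = 0.0019872041,
                           standard_volume = 1661) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  if (standard_volume <= 0) stop("standard_volume must be positive")
  kT <- boltzmann_constant * temperature
  structure(
    list(temperature = temperature,
         boltzmann_constant = boltzmann_constant,
         kT = kT,
         beta = 1 / kT,
         standard_volume = standard_volume),
    class = "sim_conditions")
}

#' @export
print.sim_conditions <- function(x, ...) {
  cat(sprintf("Simulation conditions: T = %g K, kB = %g kcal/mol/K\n",
              x$temperature, x$boltzmann_constant))
  cat(sprintf("  kT = %.5f kcal/mol, beta = %.5f mol/kcal, V0 = %g A^3\n",
              x$kT, x$beta, x$standard_volume))
  invisible(x)
}
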