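#' Physical constants of the AMBER energy function
#'
#' Returns the fixed constants used by the energy engine: the Coulomb
#' prefactor 1/(4 pi eps0) in kcal mol^-1 A e^-2, the 1-4 electrostatic
#' scale (1/1.2) and the 1-4 Lennard-Jones scale (0.5). These are part of
#' the Hamiltonian definition and are not user-configurable.
#'
#' @return Named list with elements `coulomb`, `coulomb14`, `lj14`.
#' @examples
#' physicalConstants()$coulomb
#' @export
physicalConstants <- function() {
  list(coulomb = 332.063712827427, coulomb14 = 1 / 1.2, lj14 = 0.5)
}

## Coulomb prefactor, kcal/mol * Angstrom per e^2 (vacuum permittivity)
.COULOMB <- 332.063712827427

## amber prmtop stores charges premultiplied by sqrt(coulomb const)
.PRMTOP_CHARGE_SCALE <- 18.2223

## pair classification codes, in order of increasing bond-path length
.PAIR_CLASSES <- c("excluded_12", "excluded_13", "scaled_14", "full")

## report section titles, fixed order
.TERM_CLASSES <- c("Bonds", "Angles", "Torsions", "Out-of-Plane",
                   "VDW", "Coulomb")

.deg2rad <- function(x) x * pi / 180
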