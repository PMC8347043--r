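#' Physical constants and nuclear data tables
#'
#' Internal tables used throughout the neutron modules. Cross-sections are
#' bound (rigidly held atom) total scattering cross-sections from the standard
#' neutron data tables; masses are standard atomic weights.
#'
#' @name glassprobe-constants
#' @keywords internal
NULL

## Boltzmann constant, meV per kelvin
.kB_meV <- 0.08617333262

## hbar^2 / m_neutron, meV * Angstrom^2 (so E[meV] = 2.0717 * k[1/A]^2)
.hbar2_over_mn <- 4.1434

## neutron speed: v [m/s] = .v_const * sqrt(E [meV])
.v_const <- 437.39

## Avogadro's number, 1/mol
.N_A <- 6.02214076e23

## barn in cm^2
.barn_cm2 <- 1e-24

## neutron mass, amu
.m_neutron_amu <- 1.00866492

## standard atomic weights, amu
.atomic_mass <- c(H = 1.00794, C = 12.011, O = 15.999, Al = 26.9815385)

## bound total scattering cross-sections, barns per atom
.sigma_bound <- c(H = 82.02, C = 5.551, O = 4.232, Al = 1.503)

#' Mass ratio of a nuclide to the neutron
#' @param element element symbol ("H", "C", "O", "Al")
#' @return dimensionless mass ratio A = m_atom / m_neutron
#' @keywords internal
mass_ratio <- function(element) {
  unname(.atomic_mass[element] / .m_neutron_amu)
}

## Default vibrational mode energies (meV) per functional group; three modes
## per group, one per momentum direction (weights sum to 3). Values are
## representative organic-hydrogen frequencies: C-H/O-H stretch, bend,
## torsion/libration. Heavy atoms get low-lying skeletal/lattice modes.
.default_group_modes <- list(
  CH2        = list(energies = c(360, 175,  90), weights = c(1, 1, 1)),
  CH         = list(energies = c(360, 160, 100), weights = c(1, 1, 1)),
  OH         = list(energies = c(420, 200,  80), weights = c(1, 1, 1)),
  water_OH   = list(energies = c(420, 200,  80), weights = c(1, 1, 1)),
  C_heavy    = list(energies = c(140,  80,  30), weights = c(1, 1, 1)),
  O_heavy    = list(energies = c(140,  80,  30), weights = c(1, 1, 1)),
  Al_heavy   = list(energies = c(30,   20,  10), weights = c(1, 1, 1))
)
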