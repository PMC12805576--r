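## Physical constants and unit conventions.
##
## Internal units follow the GROMACS convention: lengths in nm, energies in
## kJ/mol, masses in Da, angles in degrees at API boundaries (radians
## internally).

#' Physical constants used throughout the package
#'
#' Boltzmann constant in kJ/(mol K), Avogadro's number, the molar mass and
#' density of water, and the MARTINI water mapping (four molecules per W
#' bead).
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0083145 kJ mol^-1 K^-1.}
#'   \item{avogadro}{6.02214076e23 mol^-1.}
#'   \item{water_molar_mass}{18.015 g/mol.}
#'   \item{water_density}{1.000 g/cm^3.}
#'   \item{waters_per_bead}{4 water molecules per CG W bead.}
#'   \item{default_temperature}{300 K.}
#' }
#' @export
cg_constants <- list(
  kB                  = 0.0083145,
  avogadro            = 6.02214076e23,
  water_molar_mass    = 18.015,
  water_density       = 1.000,
  waters_per_bead     = 4L,
  default_temperature = 300
)

#' @rdname cg_constants
#' @details `water_molecules_per_nm3()` returns the number density of liquid
#'   water molecules at 1 g/cm^3 (about 33.43 nm^-3), the quantity used to
#'   fill free box volume with W beads.
#' @export
water_molecules_per_nm3 <- function() {
  ## 1 g/cm^3 = 1e-21 g/nm^3; molecules = mass / (M / N_A)
  1e-21 * cg_constants$water_density * cg_constants$avogadro /
    cg_constants$water_molar_mass
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## kB*T in kJ/mol
kBT <- function(temperature) cg_constants$kB * temperature
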