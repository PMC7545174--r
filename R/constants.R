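#' Physical constants used throughout the package
#'
#' A single table of the fixed unit conventions: energies in kcal/mol,
#' distances in angstroms, forces in piconewtons, temperatures in kelvin.
#' `kT` at 300 K is anchored to 0.5962 kcal/mol and the Boltzmann constant is
#' derived from that anchor so every temperature-dependent quantity in the
#' package is consistent with it.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kT_300K}{thermal energy at 300 K, kcal/mol (0.5962)}
#'   \item{boltzmann_kcal}{Boltzmann constant, kcal/mol/K}
#'   \item{pN_per_kcal_mol_A}{force conversion, 1 kcal/mol/A in pN (69.48)}
#'   \item{calcium_reference_sasa}{surface area of an isolated calcium ion with
#'     a 1.4 A probe, A^2 (105.7); the 100% normalisation reference}
#'   \item{calcium_radius}{calcium radius used for SASA, A (1.5), chosen so that
#'     4*pi*(r + 1.4)^2 reproduces the 105.7 A^2 reference}
#'   \item{default_probe_radius}{solvent probe radius, A (1.4)}
#'   \item{default_contact_cutoff}{calcium-oxygen contact cutoff, A (4.0)}
#' }
#' @export
mech_constants <- list(
  kT_300K                = 0.5962,
  boltzmann_kcal         = 0.5962 / 300,
  pN_per_kcal_mol_A      = 69.48,
  calcium_reference_sasa = 105.7,
  calcium_radius         = 1.5,
  default_probe_radius   = 1.4,
  default_contact_cutoff = 4.0
)

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Absolute temperature in kelvin.
#' @return kT in kcal/mol.
#' @examples
#' thermal_energy(300) # 0.5962
#' @export
thermal_energy <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  mech_constants$boltzmann_kcal * temperature
}

# van der Waals radii (A) by element symbol; calcium fixed at 1.5 A so the
# isolated-ion SASA with a 1.4 A probe equals the 105.7 A^2 reference.
vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  CA = 1.50, `NA` = 2.27, MG = 1.73, CL = 1.75
)

# one-letter amino-acid alphabet
amino_acids <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# log of the mean of exp(x), computed with a max shift so that work values of
# thousands of kT neither overflow nor underflow to -Inf
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    # all -Inf (infinite works): the mean of exp is 0 only if every entry is
    # -Inf; a single finite entry dominates through the shift above
    return(m)
  }
  m + log(mean(exp(x - m)))
}
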