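#' Unit conversion constants
#'
#' Single source of unit conversions used across the package.  All internal
#' energies are in hartree and lengths in bohr; the reporting layer converts
#' once on output.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_kcal}{kcal/mol per hartree (627.509)}
#'   \item{bohr_angstrom}{Angstrom per bohr (0.529177)}
#'   \item{ebohr_debye}{Debye per e*bohr (2.541746)}
#'   \item{coulomb_kcal}{Coulomb constant in kcal*Angstrom/(mol*e^2) (332.0637)}
#'   \item{prmtop_charge}{Amber prmtop internal charge factor (18.2223)}
#'   \item{boltzmann_kcal}{k_B in kcal/(mol*K) (0.0019872)}
#' }
#' @export
iqa_units <- list(
  hartree_kcal  = 627.509,
  bohr_angstrom = 0.529177,
  ebohr_debye   = 2.541746,
  coulomb_kcal  = 332.0637,
  prmtop_charge = 18.2223,
  boltzmann_kcal = 0.0019872
)

#' Convert energies between hartree and kcal/mol
#'
#' @param x numeric energies.
#' @param from,to one of `"hartree"`, `"kcal"`.
#' @return converted numeric vector.
#' @export
convert_energy <- function(x, from = "hartree", to = "kcal") {
  rate <- c(hartree = 1, kcal = iqa_units$hartree_kcal) # units per hartree
  if (!from %in% names(rate) || !to %in% names(rate))
    stop("unknown energy unit")
  x * rate[[to]] / rate[[from]]
}
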