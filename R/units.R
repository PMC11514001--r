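#' Physical constants and unit conversions
#'
#' Internal energy unit is kJ/mol, length unit is Angstrom, time unit is fs.
#' Velocities are Angstrom/fs; masses are g/mol. With these units a kinetic
#' energy 0.5*m*v^2 must be multiplied by `.kE_KIN` to land in kJ/mol.
#'
#' @name units
#' @keywords internal
NULL

## 1 Hartree in kJ/mol
.kHARTREE_KJMOL <- 2625.4996

## Coulomb constant e^2/(4 pi eps0) in kJ * Angstrom / mol / e^2
.kCOULOMB <- 1389.35457644382

## Boltzmann constant in kJ/mol/K
.kBOLTZ <- 8.31446261815324e-3

## (g/mol) * (Angstrom/fs)^2 -> kJ/mol
.kE_KIN <- 1e4

## chemical accuracy threshold, kJ/mol (1 kcal/mol)
.kCHEM_ACC <- 4.184

## atomic masses, g/mol
.kMASS <- c(O = 15.999, H = 1.008)

#' Convert Hartree to kJ/mol
#'
#' @param x energies in Hartree.
#' @return energies in kJ/mol.
#' @examples
#' hartree_to_kjmol(1)
#' @export
hartree_to_kjmol <- function(x) x * .kHARTREE_KJMOL

#' Convert kJ/mol to Hartree
#'
#' @param x energies in kJ/mol.
#' @return energies in Hartree.
#' @export
kjmol_to_hartree <- function(x) x / .kHARTREE_KJMOL

#' Chemical accuracy threshold in kJ/mol
#'
#' 1 kcal/mol = 4.184 kJ/mol, the conventional "chemical accuracy" error bar.
#' @return a single number, kJ/mol.
#' @export
chemical_accuracy <- function() .kCHEM_ACC
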