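#' Physical constants and unit conversions
#'
#' All internal energies are expressed in units of the thermal energy kBT at
#' the simulation temperature of 310 K.  With the Boltzmann constant
#' kB = 0.0083145 kJ mol^-1 K^-1 this gives kBT = 2.5775 kJ/mol.
#'
#' @name polfid-units
#' @keywords internal
NULL

#. Boltzmann constant, kJ mol^-1 K^-1
KB_KJ_MOL_K <- 0.0083145

#. simulation temperature, K
TEMPERATURE_K <- 310

#. thermal energy at 310 K, kJ/mol
KBT_KJ_MOL <- KB_KJ_MOL_K * TEMPERATURE_K

#' Convert a harmonic force constant to internal units
#'
#' Umbrella-window force constants are conventionally quoted in
#' kJ mol^-1 nm^-2 (as for the 210 000 kJ/mol/nm^2 restraint used here);
#' internally all bias potentials are evaluated in kBT with coordinates in
#' Angstrom, so the conversion divides by kBT and by 100 A^2/nm^2.
#'
#' @param k force constant in kJ mol^-1 nm^-2
#' @return force constant in kBT A^-2
#' @examples
#' k_to_kbt_a2(210000)            # ~814.7 kBT/A^2
#' sqrt(1 / k_to_kbt_a2(210000))  # harmonic width ~0.035 A
#' @export
k_to_kbt_a2 <- function(k) {
  stopifnot(is.numeric(k), all(is.finite(k)), all(k > 0))
  k / KBT_KJ_MOL / 100
}

#' Convert an energy in kJ/mol to kBT at 310 K
#' @param e energy in kJ/mol
#' @return energy in kBT
#' @export
kj_mol_to_kbt <- function(e) e / KBT_KJ_MOL
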