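## Unit system: lengths in nm, energies in k_BT, time in s, forces in pN.
## All conversion factors are centralized here.

#' Physical constants of the unit system
#'
#' The package works in a consistent unit system with lengths in nanometres,
#' energies in units of the thermal energy \eqn{k_BT} (T = 298 K), forces in
#' piconewtons and time in seconds, so that every printed constant of the
#' membrane model is directly usable.  \code{kbt_pN_nm()} returns the single
#' conversion factor \eqn{k_BT = 4.114} pN nm from which all others derive.
#'
#' @return \code{kbt_pN_nm()}: the thermal energy in pN nm.
#' @export
kbt_pN_nm <- function() 4.114

#' Convert a surface tension from SI units to k_BT/nm^2
#'
#' @param gamma_si surface tension in N/m (J/m^2).
#' @return tension in k_BT/nm^2.
#' @examples
#' tension_si_to_kbt(1.5e-4)  # ~0.0365 k_BT/nm^2
#' @export
tension_si_to_kbt <- function(gamma_si) gamma_si * 1e3 / kbt_pN_nm()

#' Convert a pressure from pN/nm^2 to k_BT/nm^3
#'
#' @param p_pn pressure in pN/nm^2.
#' @return pressure in k_BT/nm^3.
#' @export
pressure_pn_to_kbt <- function(p_pn) p_pn / kbt_pN_nm()
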