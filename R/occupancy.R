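# Competitive D2 receptor occupancy algebra shared by both PD systems.
#
# With unbound drug Cu, potency KI and scaled dopamine DAs competing for the
# receptor, the bound fractions are
#   RO_drug     = (Cu/KI) / (DAs + Cu/KI + 1) * 100
#   RO_dopamine =    DAs  / (DAs + Cu/KI + 1) * 100
# and the remaining 100/(DAs + Cu/KI + 1) percent of receptors are free, so
# the three terms always sum to 100.

#' Drug receptor occupancy under competitive binding
#'
#' @param cu unbound drug concentration (nmol/L), nonnegative; vectorized.
#' @param ki drug potency (nmol/L), strictly positive.
#' @param das scaled dopamine concentration competing for the receptor,
#'   nonnegative; `das = 0` gives the classical competition-free form
#'   `100 * Cu / (Cu + KI)`.
#' @return occupancy in percent, in `[0, 100)`.
#' @export
occupancy_drug <- function(cu, ki, das = 0) {
  check_nonnegative(cu, "cu"); check_positive(ki, "ki")
  check_nonnegative(das, "das")
  s <- cu / ki
  100 * s / (das + s + 1)
}

#' Dopamine receptor occupancy under competitive binding
#'
#' @inheritParams occupancy_drug
#' @return occupancy in percent, in `[0, 100)`.
#' @export
occupancy_dopamine <- function(cu, ki, das = 0) {
  check_nonnegative(cu, "cu"); check_positive(ki, "ki")
  check_nonnegative(das, "das")
  100 * das / (das + cu / ki + 1)
}

#' Occupancy at the half-maximal unbound concentration
#'
#' `RO50` is defined as the drug occupancy evaluated at `Cu = ECu50`; it maps
#' a concentration-scale potency onto the occupancy scale for a given
#' competitive environment.
#'
#' @param ecu50 unbound concentration at half-maximal effect (nmol/L).
#' @param ki drug potency (nmol/L).
#' @param das scaled dopamine concentration (default 0).
#' @return occupancy in percent.
#' @export
ro50_from_potency <- function(ecu50, ki, das = 0) {
  check_positive(ecu50, "ecu50")
  occupancy_drug(ecu50, ki, das)
}
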