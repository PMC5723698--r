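# Agonist-antagonist interaction (AAI) PD system.
#
# A hypothetical scaled dopamine concentration DAs competes with the drug at
# the D2 receptor and inhibits prolactin release; prolactin in turn
# stimulates dopamine production (negative feedback loop on prolactin):
#   dC_prl/dt = K_in0 * (1 + DAs0) * (1 - DAs/(DAs + Cu/KI + 1)) * (1 + f(DIU))
#               - K_out * C_prl
#   dDAs/dt   = K_DA * DAs0 * (C_prl/C_prl0)^gamma - K_DA * DAs
# The release term is the product form: at baseline (Cu = 0, DAs = DAs0) the
# inhibition factor is 1/(1 + DAs0), so release collapses to K_in0 and the
# printed baseline relation C_prl,0 = K_in0/K_out holds identically.  An
# additive reading of the flattened equation would violate that relation and
# is not implemented.  The diurnal modulation f(DIU) is hard-set to zero, as
# in the translation exercise this package reproduces; the hook is exposed
# for completeness but untested.

#' Time derivatives of the agonist-antagonist interaction system
#'
#' @param state numeric vector `c(c_prl, das)`: plasma prolactin (ng/mL) and
#'   scaled dopamine (dimensionless).
#' @param cu unbound drug concentration (nmol/L), nonnegative.
#' @param params an [aai_params()] object.
#' @param f_diu diurnal modulation, fixed at 0 (untested stub hook).
#' @return numeric vector of rates `c(dc_prl, ddas)`.
#' @export
aai_derivatives <- function(state, cu, params, f_diu = 0) {
  check_nonnegative(cu, "cu")
  c_prl <- state[[1L]]; das <- state[[2L]]
  s <- cu / params$ki
  release <- params$k_in0 * (1 + params$das0) *
    (1 - das / (das + s + 1)) * (1 + f_diu)
  c_prl0 <- params$k_in0 / params$k_out
  c(release - params$k_out * c_prl,
    params$k_da * params$das0 * (c_prl / c_prl0)^params$gamma -
      params$k_da * das)
}

#' Analytic baseline of the interaction system
#'
#' `C_prl,0 = K_in0/K_out`; dopamine starts at its baseline `DAs0`.
#'
#' @param params an [aai_params()] object.
#' @return named numeric vector `c(c_prl0, das0)`.
#' @export
aai_baseline <- function(params) {
  check_positive(params$k_out, "k_out")
  c(c_prl0 = params$k_in0 / params$k_out, das0 = params$das0)
}
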