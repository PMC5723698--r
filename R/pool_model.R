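# Precursor-pool (PP) PD system.
#
# Prolactin is synthesized at a zero-order rate into a lactotroph pool and
# released into plasma at a first-order rate that the drug stimulates:
#   dC_pool/dt = R_form * (1 + PF) - K_base * (1 + DE) * C_pool
#   dC_prl /dt = K_base * (1 + DE) * C_pool - K_out * C_prl
# Tolerance on repeated dosing arises from depletion of the pool.  The drug
# effect DE is a Hill function of either the unbound concentration or the
# receptor occupancy (the two parameterizations are exactly equivalent under
# the odds transform; see drug_effect_ro).

#' Drug effect from unbound concentration
#'
#' `DE = Emax * Cu^gamma / (ECu50^gamma + Cu^gamma)`.
#'
#' @param cu unbound drug concentration (nmol/L), nonnegative; vectorized.
#' @param emax maximal fold-stimulation, nonnegative.
#' @param ecu50 unbound concentration at half-maximal effect (nmol/L), > 0.
#' @param gamma Hill slope, > 0.
#' @return dimensionless stimulation in `[0, emax)`.
#' @export
drug_effect_conc <- function(cu, emax, ecu50, gamma = 1) {
  check_nonnegative(cu, "cu"); check_nonnegative(emax, "emax")
  check_positive(ecu50, "ecu50"); check_positive(gamma, "gamma")
  cg <- cu^gamma
  emax * cg / (ecu50^gamma + cg)
}

#' Drug effect from receptor occupancy
#'
#' `DE = Emax * X^gamma / (X50^gamma + X^gamma)` with the occupancy odds
#' `X = RO/(100-RO)` and `X50 = RO50/(100-RO50)`.  Because the odds of the
#' competitive occupancy equal `Cu / (KI * (DAs+1))`, the dopamine term
#' cancels between numerator and denominator and this parameterization is
#' algebraically identical to [drug_effect_conc()] whenever
#' `RO50 = ro50_from_potency(ECu50, KI, DAs)` with the same `DAs` — which is
#' why predictions are insensitive to the absolute RO50 value used.
#'
#' @param ro receptor occupancy (percent), in `[0, 100)`; vectorized.
#' @param emax maximal fold-stimulation.
#' @param ro50 occupancy at half-maximal effect (percent), in (0, 100).
#' @param gamma Hill slope, > 0.
#' @return dimensionless stimulation in `[0, emax]`.
#' @export
drug_effect_ro <- function(ro, emax, ro50, gamma = 1) {
  check_nonnegative(ro, "ro"); check_nonnegative(emax, "emax")
  check_positive(gamma, "gamma")
  if (any(ro >= 100)) lt_stop("domain", "'ro' must be below 100 percent")
  if (ro50 <= 0 || ro50 >= 100) lt_stop("invalid_parameter", "'ro50' must be in (0, 100)")
  x <- (ro / (100 - ro))^gamma
  x50 <- (ro50 / (100 - ro50))^gamma
  emax * x / (x50 + x)
}

#' Time derivatives of the precursor-pool system
#'
#' @param state numeric vector `c(c_pool, c_prl)` (ng/mL).
#' @param de dimensionless drug effect, nonnegative.
#' @param params a [pool_params()] object.
#' @return numeric vector of rates `c(dc_pool, dc_prl)` (ng/mL/h).
#' @export
pool_derivatives <- function(state, de, params) {
  check_nonnegative(de, "de")
  release <- params$k_base * (1 + de) * state[[1L]]
  c(params$r_form * (1 + params$pf) - release,
    release - params$k_out * state[[2L]])
}

#' Analytic baseline of the precursor-pool system
#'
#' With no drug and `PF = 0` the steady state is `C_pool,0 = R_form/K_base`
#' and `C_prl,0 = R_form/K_out`.
#'
#' @param params a [pool_params()] object.
#' @return named numeric vector `c(c_pool0, c_prl0)` (ng/mL).
#' @export
pool_baseline <- function(params) {
  check_positive(params$k_base, "k_base"); check_positive(params$k_out, "k_out")
  c(c_pool0 = params$r_form / params$k_base,
    c_prl0 = params$r_form / params$k_out)
}
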