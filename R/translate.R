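# Rat-to-human translation rules.
#
# Turnover rate constants scale allometrically with body weight,
#   K_hum = K_rat * (BW_hum/BW_rat)^b,  b = -0.25;
# dimensionless and potency quantities (Emax, RO50, DAs0, gamma) never scale.
# Drug potency translates either directly from in vitro human assays or by
# normalizing the in vivo rat estimate with the in vitro rat/human ratio:
#   KI_hum = in-vitro KI_hum * KI_rat(in vivo) / in-vitro KI_rat.
# A missing human EC50 can be borrowed cross-compound through the ratio of
# in vitro human KIs: EC50_target = EC50_ref * KI_target / KI_ref.

#' Interspecies scaling specification
#'
#' @param bw_human human body weight (kg), default 70.
#' @param bw_rat rat body weight (kg), default 0.28.
#' @param exponent_b allometric exponent for rate constants, default -0.25.
#' @return object of class `scaling_spec`.
#' @export
scaling_spec <- function(bw_human = 70, bw_rat = 0.28, exponent_b = -0.25) {
  check_positive(bw_human, "bw_human"); check_positive(bw_rat, "bw_rat")
  structure(list(bw_human = bw_human, bw_rat = bw_rat,
                 exponent_b = exponent_b),
            class = "scaling_spec")
}

#' Allometric scaling of a turnover rate constant
#'
#' @param k_rat rat-scale rate (1/h, or ng/mL/h for the zero-order synthesis
#'   rate, which scales with the same exponent), strictly positive.
#' @param spec a [scaling_spec()].
#' @return the human-scale rate, same unit.
#' @export
allometric_scale <- function(k_rat, spec = scaling_spec()) {
  check_positive(k_rat, "k_rat")
  k_rat * (spec$bw_human / spec$bw_rat)^spec$exponent_b
}

#' Translate a drug potency across species
#'
#' @param ki_invitro_human in vitro human KI (nmol/L).
#' @param ki_invitro_rat in vitro rat KI (nmol/L).
#' @param ki_invivo_rat in vivo (model-estimated) rat KI (nmol/L).
#' @return scaled human KI (nmol/L): `ki_invitro_human * ki_invivo_rat /
#'   ki_invitro_rat`.
#' @export
scale_ki <- function(ki_invitro_human, ki_invitro_rat, ki_invivo_rat) {
  check_positive(ki_invitro_human, "ki_invitro_human")
  check_positive(ki_invitro_rat, "ki_invitro_rat")
  check_positive(ki_invivo_rat, "ki_invivo_rat")
  ki_invitro_human * ki_invivo_rat / ki_invitro_rat
}

#' Borrow a human EC50 from a reference compound
#'
#' @param ec50_ref_human reference compound's human EC50 (any concentration
#'   unit; the result carries the same unit).
#' @param ki_target_human target compound's in vitro human KI (nmol/L).
#' @param ki_ref_human reference compound's in vitro human KI (nmol/L).
#' @return putative human EC50 of the target compound.
#' @export
derive_ec50_cross_compound <- function(ec50_ref_human, ki_target_human,
                                       ki_ref_human) {
  check_positive(ec50_ref_human, "ec50_ref_human")
  check_positive(ki_target_human, "ki_target_human")
  check_positive(ki_ref_human, "ki_ref_human")
  ec50_ref_human * ki_target_human / ki_ref_human
}

#' Translate a rat precursor-pool parameter set to human
#'
#' `r_form`, `k_base` and `k_out` are allometrically scaled; `emax` is fixed
#' to the published human estimate; `ro50` and `gamma` carry over unscaled
#' (occupancy-scale potency is assumed species-invariant).
#'
#' @param rat a rat-scale [pool_params()] object; it must use the `ro50`
#'   parameterization or supply `ro50_fixed`.
#' @param spec a [scaling_spec()].
#' @param emax_fixed human Emax to fix (default 66).
#' @param ro50_fixed occupancy potency carried over (default 56.3 percent,
#'   the rat estimate).
#' @return a human-scale [pool_params()] object.
#' @export
translate_pool <- function(rat, spec = scaling_spec(), emax_fixed = 66,
                           ro50_fixed = 56.3) {
  if (!inherits(rat, "pool_params")) lt_stop("invalid_parameter", "'rat' must be pool_params")
  pool_params(
    r_form = allometric_scale(rat$r_form, spec),
    k_base = allometric_scale(rat$k_base, spec),
    k_out = allometric_scale(rat$k_out, spec),
    emax = emax_fixed, ro50 = ro50_fixed, gamma = rat$gamma, pf = rat$pf
  )
}

#' Translate a rat interaction-model parameter set to human
#'
#' `k_in0`, `k_out` and `k_da` are allometrically scaled; `das0` and `gamma`
#' carry over unscaled; the potency is set from the compound's in vitro
#' human KI (`ki_mode = "invitro"`) or from [scale_ki()]
#' (`ki_mode = "scaled"`).
#'
#' @param rat a rat-scale [aai_params()] object.
#' @param spec a [scaling_spec()].
#' @param compound a [compound_spec()] supplying the KI variants.
#' @param ki_mode `"invitro"` or `"scaled"`.
#' @return a human-scale [aai_params()] object.
#' @export
translate_aai <- function(rat, spec = scaling_spec(), compound,
                          ki_mode = c("invitro", "scaled")) {
  if (!inherits(rat, "aai_params")) lt_stop("invalid_parameter", "'rat' must be aai_params")
  ki_mode <- match.arg(ki_mode)
  ki <- switch(ki_mode,
    invitro = compound$ki_invitro_human,
    scaled = scale_ki(compound$ki_invitro_human, compound$ki_invitro_rat,
                      compound$ki_invivo_rat)
  )
  aai_params(
    k_in0 = allometric_scale(rat$k_in0, spec),
    k_out = allometric_scale(rat$k_out, spec),
    k_da = allometric_scale(rat$k_da, spec),
    das0 = rat$das0, ki = ki, gamma = rat$gamma
  )
}
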