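# Unit discipline: drug concentrations are nmol/L everywhere inside the
# package (receptor potencies are tabulated in nmol/L); prolactin stays in
# ng/mL.  Conversions happen only at input/output boundaries.

#' Convert a dose in milligrams to nanomoles
#'
#' @param amount_mg dose amount (mg), strictly positive.
#' @param mw molecular weight (g/mol), strictly positive.
#' @return dose in nmol: `amount_mg * 1e6 / mw`.
#' @examples
#' dose_to_molar(426.48, 426.48)  # one millimole = 1e6 nmol
#' @export
dose_to_molar <- function(amount_mg, mw) {
  check_positive(amount_mg, "amount_mg")
  check_positive(mw, "mw")
  amount_mg * 1e6 / mw
}

#' Unbound plasma concentration
#'
#' The pharmacodynamic driver throughout is the unbound drug concentration
#' `Cu = fu * C_total`.
#'
#' @param c_total total plasma concentration (nmol/L), nonnegative.
#' @param fraction_unbound unbound fraction, in (0, 1].
#' @return unbound concentration, same unit as `c_total`.
#' @export
unbound <- function(c_total, fraction_unbound) {
  check_nonnegative(c_total, "c_total")
  if (!is.numeric(fraction_unbound) || length(fraction_unbound) != 1L ||
      !is.finite(fraction_unbound) ||
      fraction_unbound <= 0 || fraction_unbound > 1) {
    lt_stop("invalid_parameter", "'fraction_unbound' must be in (0, 1]")
  }
  c_total * fraction_unbound
}

# mg/L -> nmol/L for a given molecular weight (g/mol)
mgL_to_nmolL <- function(c_mg_per_L, mw) c_mg_per_L * 1e6 / mw
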