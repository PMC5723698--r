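# Classed error helpers so callers can distinguish invalid parameters,
# domain violations, registry lookups, configuration and numerical failures.

lt_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("lactotran_", class), "lactotran_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    lt_stop("invalid_parameter", sprintf("'%s' must be strictly positive and finite", what))
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    lt_stop("invalid_parameter", sprintf("'%s' must be nonnegative and finite", what))
  }
  invisible(x)
}
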