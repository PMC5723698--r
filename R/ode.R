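# Self-contained adaptive Dormand-Prince 5(4) integrator.
#
# The simulation and estimation machinery needs a stiff-tolerant, event-aware
# ODE solver; the turnover systems here are small (2 states) and non-stiff at
# the tolerances used, so an embedded explicit Runge-Kutta pair with step
# rejection is adequate and keeps the package dependency-free.

# Butcher tableau, Dormand & Prince (1980)
.DP_C <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.DP_A <- list(
  c2 = c(1/5),
  c3 = c(3/40, 9/40),
  c4 = c(44/45, -56/15, 32/9),
  c5 = c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c6 = c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c7 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
)
.DP_B5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.DP_B4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
.DP_E <- .DP_B5 - .DP_B4

#' Integrate an ODE system with dose-event restarts
#'
#' Adaptive Dormand-Prince 5(4) integration of `dy/dt = deriv(t, y)`,
#' recording the solution at every time in `times`.  The solver steps exactly
#' onto every requested output time and every event time, restarting step-size
#' control there, so derivative discontinuities at dose events (bolus input,
#' start/stop of zero-order release) never straddle a step.
#'
#' @param deriv function of `(t, y)` returning `dy/dt` (numeric vector).
#' @param y0 numeric initial state at `times[1]`.
#' @param times strictly increasing numeric vector of output times.
#' @param events numeric vector of additional restart times (dose times,
#'   release endpoints); values outside the integration span are ignored.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param hmax maximum step size.
#' @param jump optional function of `(t, y)` applied to the state when an
#'   event time is reached (used for bolus amount additions); must return the
#'   updated state.
#' @return matrix with `length(times)` rows and `length(y0)` columns.
#' @keywords internal
ode_rk45 <- function(deriv, y0, times, events = numeric(0),
                     rtol = 1e-8, atol = 1e-10, hmax = Inf, jump = NULL) {
  if (length(times) < 1L || any(diff(times) <= 0)) {
    lt_stop("domain", "'times' must be strictly increasing")
  }
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n)
  out[1L, ] <- y0
  if (length(times) == 1L) return(out)

  events <- sort(unique(events))
  events <- events[events > times[1L] & events < times[length(times)]]
  # breakpoints: every output time and every event time
  brk <- sort(unique(c(times, events)))
  is_event <- brk %in% events
  out_idx <- match(times, brk)

  y <- y0
  t <- brk[1L]
  h <- NA_real_  # initialized per segment
  rec <- 1L      # next output row to fill
  max_reject <- 2000L

  for (seg in 2L:length(brk)) {
    tb <- brk[seg]
    if (is.na(h) || h <= 0) h <- min(hmax, (tb - t) / 4, 1)
    reject <- 0L
    while (t < tb) {
      h <- min(h, tb - t, hmax)
      # unrolled Dormand-Prince stages (hot path)
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 5, y + h * (k1 / 5))
      k3 <- deriv(t + 3 * h / 10, y + h * (3 / 40 * k1 + 9 / 40 * k2))
      k4 <- deriv(t + 4 * h / 5, y + h * (44 / 45 * k1 - 56 / 15 * k2 + 32 / 9 * k3))
      k5 <- deriv(t + 8 * h / 9,
                  y + h * (19372 / 6561 * k1 - 25360 / 2187 * k2 +
                           64448 / 6561 * k3 - 212 / 729 * k4))
      k6 <- deriv(t + h,
                  y + h * (9017 / 3168 * k1 - 355 / 33 * k2 + 46732 / 5247 * k3 +
                           49 / 176 * k4 - 5103 / 18656 * k5))
      y5 <- y + h * (35 / 384 * k1 + 500 / 1113 * k3 + 125 / 192 * k4 -
                     2187 / 6784 * k5 + 11 / 84 * k6)
      k7 <- deriv(t + h, y5)
      err_vec <- h * (.DP_E[1L] * k1 + .DP_E[3L] * k3 + .DP_E[4L] * k4 +
                      .DP_E[5L] * k5 + .DP_E[6L] * k6 + .DP_E[7L] * k7)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean((err_vec / sc)^2))
      if (!is.finite(err)) {
        h <- h / 10
        reject <- reject + 1L
        if (reject > max_reject) {
          lt_stop("numerical",
                  sprintf("solver failed near t = %.6g (non-finite error estimate, h = %.3g)", t, h))
        }
        next
      }
      if (err <= 1) {
        t <- t + h
        y <- y5
        fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
        h <- h * fac
      } else {
        reject <- reject + 1L
        if (reject > max_reject) {
          lt_stop("numerical",
                  sprintf("solver failed near t = %.6g (step repeatedly rejected, h = %.3g, err = %.3g)", t, h, err))
        }
        h <- h * min(1, max(0.2, 0.9 * err^(-0.2)))
      }
    }
    t <- tb
    if (is_event[seg] && !is.null(jump)) y <- jump(t, y)
    idx <- which(out_idx == seg)
    if (length(idx)) out[idx, ] <- rep(y, each = length(idx))
  }
  out
}
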