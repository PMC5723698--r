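# PK engine: analytic concentration time courses for the two human PK
# structures (two-compartment IV; one-compartment oral with sequential
# zero-/first-order absorption) and a generic rat IV model, under arbitrary
# dose regimens.  Both models are linear, so multiple dosing is handled by
# superposition of single-event solutions; an ODE route over the same mass
# balances serves as the independent verification oracle in tests.

#' Two-compartment IV disposition parameters
#'
#' @param cl clearance (L/h).
#' @param v1 central volume (L).
#' @param q intercompartmental clearance (L/h).
#' @param v2 peripheral volume (L).
#' @return object of class `pk_2cmt`.
#' @export
pk_2cmt_params <- function(cl, v1, q, v2) {
  check_positive(cl, "cl"); check_positive(v1, "v1")
  check_positive(q, "q"); check_positive(v2, "v2")
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2), class = "pk_2cmt")
}

#' Sequential zero-/first-order oral absorption parameters
#'
#' The dose is released at zero order into an absorption depot over
#' `release_duration`, absorbed at first order (`ka`) into a one-compartment
#' disposition (apparent `cl_over_f`, `v_over_f`).  This release-then-absorb
#' chain matches an osmotic controlled-release formulation; release and
#' absorption directly in series into the central compartment is not
#' implemented.
#'
#' @param release_duration zero-order release duration (h), > 0.
#' @param ka first-order absorption rate (1/h).
#' @param cl_over_f apparent clearance (L/h).
#' @param v_over_f apparent volume (L).
#' @return object of class `pk_oros`.
#' @export
pk_oros_params <- function(release_duration, ka, cl_over_f, v_over_f) {
  check_positive(release_duration, "release_duration")
  check_positive(ka, "ka")
  check_positive(cl_over_f, "cl_over_f"); check_positive(v_over_f, "v_over_f")
  structure(list(release_duration = release_duration, ka = ka,
                 cl_over_f = cl_over_f, v_over_f = v_over_f),
            class = "pk_oros")
}

# macro constants of the biexponential unit response
.biexp <- function(p) {
  k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  l1 <- (s + disc) / 2; l2 <- (s - disc) / 2
  list(l1 = l1, l2 = l2,
       A = (l1 - k21) / (l1 - l2), B = (k21 - l2) / (l1 - l2),
       k10 = k10, k12 = k12, k21 = k21)
}

# ---------------------------------------------------------------------------
# analytic concentration functions (mg/L), scalar-or-vector t

# bolus D at t0: C(t) = D/V1 * (A e^{-l1 s} + B e^{-l2 s}),  s = t - t0
.conc_2cmt_bolus <- function(t, t0, D, p, m) {
  s <- t - t0
  on <- s >= 0
  out <- numeric(length(t))
  out[on] <- D / p$v1 * (m$A * exp(-m$l1 * s[on]) + m$B * exp(-m$l2 * s[on]))
  out
}

# unit-step response of constant-rate infusion R (mg/h) started at 0
.conc_2cmt_infstep <- function(s, R, p, m) {
  out <- numeric(length(s))
  on <- s > 0
  out[on] <- R / p$v1 * (m$A / m$l1 * (1 - exp(-m$l1 * s[on])) +
                         m$B / m$l2 * (1 - exp(-m$l2 * s[on])))
  out
}

#' Simulate a two-compartment IV regimen (analytic superposition)
#'
#' @param regimen a [dose_regimen()] with `iv_bolus` / `iv_infusion` events.
#' @param params a [pk_2cmt_params()] object.
#' @param grid strictly increasing time grid (h) covering all events.
#' @param mw molecular weight (g/mol) for the mg/L to nmol/L conversion.
#' @return total plasma concentration (nmol/L) on `grid`.
#' @export
simulate_iv_2cmt <- function(regimen, params, grid, mw) {
  .check_grid(grid, regimen)
  f <- pk_profile_fun(regimen, params, mw)
  f(grid)
}

#' Simulate an oral controlled-release regimen (analytic superposition)
#'
#' @param regimen a [dose_regimen()] whose events all have route
#'   `oral_oros` and positive duration.
#' @param params a [pk_oros_params()] object.
#' @inheritParams simulate_iv_2cmt
#' @return total plasma concentration (nmol/L) on `grid`.
#' @export
simulate_oral_oros <- function(regimen, params, grid, mw) {
  .check_grid(grid, regimen)
  if (!all(regimen$route == "oral_oros")) {
    lt_stop("invalid_parameter", "all events must have route 'oral_oros'")
  }
  f <- pk_profile_fun(regimen, params, mw)
  f(grid)
}

.check_grid <- function(grid, regimen) {
  if (any(diff(grid) <= 0)) lt_stop("domain", "'grid' must be strictly increasing")
  if (nrow(regimen) > 0L && max(grid) < max(regimen$time)) {
    lt_stop("domain", "'grid' does not cover all dose events")
  }
}

# cumulative central-amount response to a unit impulse into the depot
# (integral of the Bateman amount curve)
.oros_G <- function(s, ka, ke) {
  out <- numeric(length(s))
  on <- s > 0
  out[on] <- ka / (ka - ke) * ((1 - exp(-ke * s[on])) / ke -
                               (1 - exp(-ka * s[on])) / ka)
  out
}

#' Build a fast concentration-vs-time function for a regimen
#'
#' Returns a vectorized function `C(t)` (nmol/L total) computed by analytic
#' superposition; this is the PD driver used by the simulation engine.
#'
#' @inheritParams simulate_iv_2cmt
#' @param params a `pk_2cmt` or `pk_oros` parameter object.
#' @return function mapping time (h) to total concentration (nmol/L).
#' @export
pk_profile_fun <- function(regimen, params, mw) {
  check_positive(mw, "mw")
  if (inherits(params, "pk_2cmt")) {
    m <- .biexp(params)
    ev <- regimen
    if (nrow(ev) > 0L && all(ev$route == "iv_bolus")) {
      # fast path for the common all-bolus case, vectorized over events for
      # the scalar-time calls issued by the PD derivative
      tev <- ev$time
      coef <- ev$amount / params$v1
      A <- m$A; B <- m$B; l1 <- m$l1; l2 <- m$l2
      conv <- 1e6 / mw
      return(function(t) {
        if (length(t) == 1L) {
          s <- t - tev
          on <- s >= 0
          return(conv * sum(coef[on] * (A * exp(-l1 * s[on]) + B * exp(-l2 * s[on]))))
        }
        out <- numeric(length(t))
        for (i in seq_along(tev)) {
          s <- t - tev[i]
          on <- s >= 0
          out[on] <- out[on] + coef[i] * (A * exp(-l1 * s[on]) + B * exp(-l2 * s[on]))
        }
        conv * out
      })
    }
    function(t) {
      c_mgL <- numeric(length(t))
      for (i in seq_len(nrow(ev))) {
        if (ev$route[i] == "iv_bolus") {
          c_mgL <- c_mgL + .conc_2cmt_bolus(t, ev$time[i], ev$amount[i], params, m)
        } else if (ev$route[i] == "iv_infusion") {
          R <- ev$amount[i] / ev$duration[i]
          c_mgL <- c_mgL +
            .conc_2cmt_infstep(t - ev$time[i], R, params, m) -
            .conc_2cmt_infstep(t - ev$time[i] - ev$duration[i], R, params, m)
        } else {
          lt_stop("config", "oral_oros events require the oros PK model")
        }
      }
      mgL_to_nmolL(c_mgL, mw)
    }
  } else if (inherits(params, "pk_oros")) {
    ke <- params$cl_over_f / params$v_over_f
    ka <- params$ka
    if (abs(ka - ke) < 1e-12) ka <- ka * (1 + 1e-9)  # guard the degenerate pair
    ev <- regimen
    tev <- ev$time; Tm <- ev$duration; R0 <- ev$amount / ev$duration
    conv <- 1e6 / (mw * params$v_over_f)
    function(t) {
      if (length(t) == 1L) {
        s <- t - tev
        return(conv * sum(R0 * (.oros_G(s, ka, ke) - .oros_G(s - Tm, ka, ke))))
      }
      a_c <- numeric(length(t))  # central amount (mg)
      for (i in seq_len(nrow(ev))) {
        a_c <- a_c + R0[i] * (.oros_G(t - tev[i], ka, ke) -
                              .oros_G(t - tev[i] - Tm[i], ka, ke))
      }
      conv * a_c
    }
  } else {
    lt_stop("invalid_parameter", "unknown PK parameter class")
  }
}

# ---------------------------------------------------------------------------
# ODE verification route (used by tests and by the mass-balance bookkeeping)

#' Numerically integrate the PK mass balances (verification oracle)
#'
#' Integrates the same mass-balance ODEs as the analytic route, with
#' integrator restarts (and bolus state jumps) at dose times.  Intended for
#' verification; the analytic route is the production path.
#'
#' @inheritParams simulate_iv_2cmt
#' @param params a `pk_2cmt` or `pk_oros` parameter object.
#' @param rtol,atol solver tolerances.
#' @return total plasma concentration (nmol/L) on `grid`, with the state
#'   matrix attached as attribute `"states"` (amounts in mg; for the oral
#'   model the columns are depot/central/eliminated, for IV central and
#'   peripheral).
#' @export
ode_reference <- function(regimen, params, grid, mw, rtol = 1e-10, atol = 1e-12) {
  .check_grid(grid, regimen)
  ev <- regimen
  if (inherits(params, "pk_2cmt")) {
    m <- .biexp(params)
    rate_at <- function(t) {
      r <- 0
      inf <- ev$route == "iv_infusion"
      for (i in which(inf)) {
        if (t >= ev$time[i] && t < ev$time[i] + ev$duration[i]) {
          r <- r + ev$amount[i] / ev$duration[i]
        }
      }
      r
    }
    deriv <- function(t, y) {
      c(rate_at(t) - (m$k10 + m$k12) * y[1L] + m$k21 * y[2L] * 1,
        m$k12 * y[1L] - m$k21 * y[2L])
    }
    jump <- function(t, y) {
      i <- which(ev$route == "iv_bolus" & abs(ev$time - t) < 1e-12)
      y[1L] <- y[1L] + sum(ev$amount[i])
      y
    }
    y0 <- c(0, 0)
    t0 <- min(grid[1L], 0)
    times <- sort(unique(c(t0, grid)))
    events <- unique(c(ev$time, ev$time + ev$duration))
    # bolus at the very first output point needs the jump applied up front
    i0 <- which(ev$route == "iv_bolus" & abs(ev$time - times[1L]) < 1e-12)
    if (length(i0)) y0[1L] <- y0[1L] + sum(ev$amount[i0])
    sol <- ode_rk45(deriv, y0, times, events = events, rtol = rtol, atol = atol,
                    jump = jump)
    keep <- match(grid, times)
    states <- sol[keep, , drop = FALSE]
    colnames(states) <- c("central_mg", "peripheral_mg")
    conc <- mgL_to_nmolL(states[, 1L] / params$v1, mw)
  } else if (inherits(params, "pk_oros")) {
    ke <- params$cl_over_f / params$v_over_f
    release_at <- function(t) {
      r <- 0
      for (i in seq_len(nrow(ev))) {
        if (t >= ev$time[i] && t < ev$time[i] + ev$duration[i]) {
          r <- r + ev$amount[i] / ev$duration[i]
        }
      }
      r
    }
    deriv <- function(t, y) {
      c(release_at(t) - params$ka * y[1L],
        params$ka * y[1L] - ke * y[2L],
        ke * y[2L])
    }
    y0 <- c(0, 0, 0)
    times <- sort(unique(c(min(grid[1L], 0), grid)))
    events <- unique(c(ev$time, ev$time + ev$duration))
    sol <- ode_rk45(deriv, y0, times, events = events, rtol = rtol, atol = atol)
    keep <- match(grid, times)
    states <- sol[keep, , drop = FALSE]
    colnames(states) <- c("depot_mg", "central_mg", "eliminated_mg")
    conc <- mgL_to_nmolL(states[, 2L] / params$v_over_f, mw)
  } else {
    lt_stop("invalid_parameter", "unknown PK parameter class")
  }
  attr(conc, "states") <- states
  conc
}
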