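# Simulation engine: couples an analytic PK driver to one of the two PD
# derivative systems, initialized at the analytic baseline, with integrator
# restarts at every dose event.

#' Load a packaged human PK parameter set (synthetic stand-in)
#'
#' Remoxipride: two-compartment IV disposition (clinical oral doses are
#' simulated through this IV model, as in the translation exercise the
#' package reproduces).  Paliperidone: OROS one-compartment model with
#' sequential zero-/first-order absorption.
#'
#' @param compound compound name.
#' @return a `pk_2cmt` or `pk_oros` parameter object.
#' @export
load_human_pk <- function(compound) {
  .load_pk_entry("human_pk_synthetic.json", compound)
}

#' Load a packaged rat IV PK parameter set (synthetic stand-in)
#' @param compound compound name.
#' @return a `pk_2cmt` parameter object.
#' @export
load_rat_pk <- function(compound) {
  .load_pk_entry("rat_pk_synthetic.json", compound)
}

.load_pk_entry <- function(file, compound) {
  models <- .lt_read_json(file)$models
  if (!compound %in% names(models)) {
    lt_stop("lookup", paste("no PK model for compound:", compound))
  }
  x <- models[[compound]]
  switch(x$type,
    iv_2cmt = pk_2cmt_params(x$cl, x$v1, x$q, x$v2),
    oral_oros = pk_oros_params(x$release_duration, x$ka, x$cl_over_f, x$v_over_f),
    lt_stop("config", paste("unknown PK model type:", x$type))
  )
}

#' Build a standard human dose regimen for a compound
#'
#' Paliperidone doses become `oral_oros` events whose zero-order release
#' duration is taken from the packaged OROS PK model; remoxipride doses
#' become `iv_bolus` events.
#'
#' @param compound compound name.
#' @param dose per-administration dose (mg).
#' @param interval dosing interval (h).
#' @param n_doses number of administrations.
#' @param horizon simulation horizon (h), default `interval * n_doses`.
#' @return a [dose_regimen()].
#' @export
human_regimen <- function(compound, dose, interval = 24, n_doses = 8,
                          horizon = NULL) {
  pk <- load_human_pk(compound)
  if (inherits(pk, "pk_oros")) {
    regimen_repeated(dose, interval, n_doses, route = "oral_oros",
                     duration = pk$release_duration,
                     horizon = horizon %||% max(interval * n_doses,
                                                interval * (n_doses - 1) + pk$release_duration))
  } else {
    regimen_repeated(dose, interval, n_doses, route = "iv_bolus",
                     horizon = horizon %||% (interval * n_doses))
  }
}

#' Run a PK/PD dosing scenario
#'
#' Integrates the chosen PD system driven by the unbound concentration of an
#' analytic PK profile.  States start at the analytic baseline; the
#' integrator restarts at every dose event (and release endpoint).
#'
#' @param model `"pp"` (precursor pool) or `"aai"` (agonist-antagonist
#'   interaction).
#' @param compound a [compound_spec()].
#' @param regimen a [dose_regimen()].
#' @param pd_params a [pool_params()] (pp) or [aai_params()] (aai) object.
#' @param pk_params a `pk_2cmt` or `pk_oros` parameter object.
#' @param grid_step output grid step (h), default 0.1.
#' @param rtol,atol integrator tolerances.
#' @param occupancy_das scaled dopamine used in the PP model's occupancy
#'   mapping and reported occupancies (default 0: classical competition-free
#'   occupancy; the AAI model always uses its dynamic dopamine state).
#' @param ki occupancy potency (nmol/L) for the PP model's occupancy mapping;
#'   default the compound's in vitro human KI, falling back to the in vivo
#'   rat KI for rat scenarios.
#' @param grid optional explicit output grid (h), overrides `grid_step`.
#' @return a `prl_sim` data frame with columns `time`, `c_total`,
#'   `c_unbound` (nmol/L), `c_pool`, `c_prl` (ng/mL), `das`, `ro_drug`,
#'   `ro_dopamine` (percent), and metadata in `attr(, "meta")`.
#' @export
run_scenario <- function(model = c("pp", "aai"), compound, regimen, pd_params,
                         pk_params, grid_step = 0.1, rtol = 1e-8, atol = 1e-10,
                         occupancy_das = 0, ki = NULL, grid = NULL) {
  model <- match.arg(model)
  check_positive(grid_step, "grid_step")
  horizon <- attr(regimen, "horizon")
  if (is.null(grid)) {
    grid <- seq(0, horizon, by = grid_step)
    if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  }
  if (inherits(pk_params, "pk_oros") && !all(regimen$route == "oral_oros")) {
    lt_stop("config", "oros PK model requires oral_oros dose events")
  }
  if (inherits(pk_params, "pk_2cmt") && any(regimen$route == "oral_oros")) {
    lt_stop("config", "oral_oros dose events require the oros PK model")
  }
  conc_fun <- pk_profile_fun(regimen, pk_params, compound$molecular_weight)
  fu <- compound$fraction_unbound
  events <- unique(c(regimen$time, regimen$time + regimen$duration))

  if (model == "pp") {
    if (!inherits(pd_params, "pool_params")) lt_stop("config", "pp model requires pool_params")
    use_ro <- !is.na(pd_params$ro50)
    if (use_ro || !is.null(ki)) {
      ki_occ <- ki %||% compound$ki_invitro_human
      if (is.na(ki_occ)) ki_occ <- compound$ki_invivo_rat
      if (is.na(ki_occ)) lt_stop("config", "no KI available for the occupancy mapping")
    } else {
      ki_occ <- compound$ki_invitro_human
      if (is.na(ki_occ)) ki_occ <- compound$ki_invivo_rat
    }
    # inlined hot-path derivative: identical algebra to pool_derivatives()
    # with drug_effect_conc()/drug_effect_ro(); the RO route is evaluated
    # through the occupancy odds cu/(ki*(das+1)), which the odds transform
    # makes exactly equivalent (see drug_effect_ro)
    g <- pd_params$gamma; emax <- pd_params$emax
    half_g <- if (use_ro) {
      (pd_params$ro50 / (100 - pd_params$ro50))^g * (ki_occ * (occupancy_das + 1))^g
    } else {
      if (is.na(pd_params$ecu50)) {
        lt_stop("invalid_parameter", "pool_params needs ecu50 or ro50 for drug-effect evaluation")
      }
      pd_params$ecu50^g
    }
    rf <- pd_params$r_form * (1 + pd_params$pf)
    kb <- pd_params$k_base; ko <- pd_params$k_out
    y0 <- pool_baseline(pd_params)
    deriv <- function(t, y) {
      cg <- (fu * conc_fun(t))^g
      rel <- kb * (1 + emax * cg / (half_g + cg)) * y[1L]
      c(rf - rel, rel - ko * y[2L])
    }
    sol <- ode_rk45(deriv, unname(y0), grid, events = events,
                    rtol = rtol, atol = atol)
    c_total <- conc_fun(grid)
    cu <- c_total * fu
    out <- data.frame(
      time = grid, c_total = c_total, c_unbound = cu,
      c_pool = sol[, 1L], c_prl = sol[, 2L], das = NA_real_,
      ro_drug = occupancy_drug(cu, ki_occ, occupancy_das),
      ro_dopamine = occupancy_dopamine(cu, ki_occ, occupancy_das)
    )
  } else {
    if (!inherits(pd_params, "aai_params")) lt_stop("config", "aai model requires aai_params")
    y0 <- aai_baseline(pd_params)
    # inlined hot-path derivative: identical algebra to aai_derivatives()
    kin_tot <- pd_params$k_in0 * (1 + pd_params$das0)
    ko <- pd_params$k_out; kda <- pd_params$k_da
    das0 <- pd_params$das0; ki_inv <- 1 / pd_params$ki
    ga <- pd_params$gamma; inv_prl0 <- ko / pd_params$k_in0
    deriv <- function(t, y) {
      s <- fu * conc_fun(t) * ki_inv
      c(kin_tot * (1 - y[2L] / (y[2L] + s + 1)) - ko * y[1L],
        kda * (das0 * (y[1L] * inv_prl0)^ga - y[2L]))
    }
    sol <- ode_rk45(deriv, unname(y0), grid, events = events,
                    rtol = rtol, atol = atol)
    c_total <- conc_fun(grid)
    cu <- c_total * fu
    out <- data.frame(
      time = grid, c_total = c_total, c_unbound = cu,
      c_pool = NA_real_, c_prl = sol[, 1L], das = sol[, 2L],
      ro_drug = occupancy_drug(cu, pd_params$ki, sol[, 2L]),
      ro_dopamine = occupancy_dopamine(cu, pd_params$ki, sol[, 2L])
    )
  }
  structure(out,
            meta = list(model = model, compound = compound$name,
                        regimen = as.data.frame(regimen),
                        horizon = horizon,
                        pd_params = pd_params, pk_params = pk_params),
            class = c("prl_sim", "data.frame"))
}

#' Summarize a simulated drug occupancy time course
#'
#' Peak is taken over the full horizon; median and the 5th/95th percentiles
#' are computed over the time points of the stated window (interpreted as
#' percentiles of the within-window time course).
#'
#' @param result a `prl_sim` from [run_scenario()].
#' @param window numeric `c(t_start, t_end)` (h).
#' @return object of class `occupancy_summary`: list with `peak`, `median`,
#'   `p5`, `p95` (percent) and `window`.
#' @export
summarize_occupancy <- function(result, window) {
  sel <- result$time >= window[1L] & result$time <= window[2L]
  if (!any(sel)) lt_stop("domain", "empty summary window")
  ro <- result$ro_drug[sel]
  structure(list(
    peak = max(result$ro_drug),
    median = stats::median(ro),
    p5 = unname(stats::quantile(ro, 0.05)),
    p95 = unname(stats::quantile(ro, 0.95)),
    window = window
  ), class = "occupancy_summary")
}

#' Ratio of daily prolactin peaks (tolerance metric)
#'
#' @param result a `prl_sim`.
#' @param day_a,day_b 1-based day indices; day `d` spans
#'   `[(d-1)*24, d*24]` h.
#' @return `max(prolactin on day_b) / max(prolactin on day_a)`.
#' @export
tolerance_ratio <- function(result, day_a, day_b) {
  peak_on <- function(d) {
    sel <- result$time >= (d - 1) * 24 & result$time <= d * 24
    if (!any(sel)) lt_stop("domain", paste("day", d, "outside simulation horizon"))
    max(result$c_prl[sel])
  }
  pa <- peak_on(day_a)
  if (pa <= 0) lt_stop("domain", "zero prolactin peak in reference day")
  peak_on(day_b) / pa
}

#' Run a benchmark scenario with the published human parameter sets
#'
#' Same engine as [run_scenario()], with the PD parameters taken from the
#' registry benchmark sets (`pp_movin_osswald` or `aai_friberg_ma`) and the
#' packaged human PK models.
#'
#' @inheritParams run_scenario
#' @param ... passed on to [run_scenario()].
#' @return a `prl_sim`.
#' @export
run_benchmark <- function(model = c("pp", "aai"), compound, regimen, ...) {
  model <- match.arg(model)
  set_name <- if (model == "pp") "pp_movin_osswald" else "aai_friberg_ma"
  pd <- load_parameter_set(set_name, compound = compound$name)
  pk <- load_human_pk(compound$name)
  run_scenario(model, compound, regimen, pd, pk, ...)
}
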