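# Maximum-likelihood estimation of PD parameters from synthetic rat
# observations, conditional on known PK.  The objective is the exact
# lognormal likelihood (Gaussian on log observations with standard deviation
# sqrt(log(1 + CV^2))), not least squares, so positivity is built in.
# Optimization runs on log-transformed parameters with box bounds and a
# jittered multistart to mitigate local minima.

.pd_param_names <- function(model) {
  if (model == "pp") c("r_form", "k_base", "k_out", "emax", "ecu50", "gamma")
  else c("k_in0", "k_out", "k_da", "das0", "ki", "gamma")
}

.pd_from_vector <- function(model, v) {
  if (model == "pp") {
    pool_params(r_form = v[["r_form"]], k_base = v[["k_base"]],
                k_out = v[["k_out"]], emax = v[["emax"]],
                ecu50 = v[["ecu50"]], gamma = v[["gamma"]], pf = 0)
  } else {
    aai_params(k_in0 = v[["k_in0"]], k_out = v[["k_out"]], k_da = v[["k_da"]],
               das0 = v[["das0"]], ki = v[["ki"]], gamma = v[["gamma"]])
  }
}

# Precompile everything fixed across objective evaluations: per-arm regimen,
# PK driver, compound, observation indices.
.make_nll <- function(model, observations, error_cv, rtol = 1e-6) {
  truth <- attr(observations, "truth")
  if (is.null(truth)) lt_stop("config", "observations lack the design metadata attribute")
  design <- truth$design
  if (any(observations$dv_ng_ml <= 0)) {
    lt_stop("data", "nonpositive observations are incompatible with the lognormal error model")
  }
  if (length(unique(observations$compound)) != 1L) {
    lt_stop("config", "fit/likelihood supports observation sets of a single compound; subset by compound first")
  }
  sdlog <- sqrt(log(1 + error_cv^2))
  arms <- sort(unique(observations$arm))
  ctx <- lapply(arms, function(i) {
    sel <- observations$arm == i
    times <- .arm_obs_times(design, i)
    list(sel = sel,
         times = times,
         t_index = match(observations$time_h[sel], times),
         regimen = .arm_regimen(design, i),
         compound = default_compounds(unique(observations$compound[sel])),
         pk = truth$pk_params[[unique(observations$compound[sel])]],
         logdv = log(observations$dv_ng_ml[sel]))
  })
  const <- sum(log(observations$dv_ng_ml)) +
    nrow(observations) * 0.5 * log(2 * pi * sdlog^2)
  function(pd_params) {
    dev <- 0
    for (a in ctx) {
      sim <- run_scenario(model, a$compound, a$regimen, pd_params, a$pk,
                          grid = a$times, rtol = rtol, atol = 1e-8)
      logpred <- log(sim$c_prl[a$t_index])
      dev <- dev + sum((a$logdv - logpred)^2)
    }
    const + dev / (2 * sdlog^2)
  }
}

#' Negative log-likelihood of PD parameters given observations
#'
#' @param model `"pp"` or `"aai"`.
#' @param pd_params a [pool_params()] or [aai_params()] object.
#' @param observations an `observation_set` from [generate_study()] (or read
#'   back with its truth sidecar); must contain a single compound.
#' @param error_cv residual coefficient of variation of the lognormal error
#'   model.
#' @param rtol integrator tolerance used for predictions.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(model = c("pp", "aai"), pd_params, observations,
                               error_cv, rtol = 1e-6) {
  model <- match.arg(model)
  check_positive(error_cv, "error_cv")
  .make_nll(model, observations, error_cv, rtol)(pd_params)
}

#' Fit PD parameters by maximum likelihood
#'
#' Bounded quasi-Newton optimization (`nlminb`) on log-transformed free
#' parameters within `[1e-6, 1e6]`, with `n_starts` jittered restarts (the
#' first start is unjittered).  Non-convergence is flagged in the result,
#' not raised.
#'
#' @inheritParams neg_log_likelihood
#' @param start full named numeric vector of starting values; names must be
#'   the model's parameter set (`r_form, k_base, k_out, emax, ecu50, gamma`
#'   for pp; `k_in0, k_out, k_da, das0, ki, gamma` for aai).
#' @param fixed character vector of parameter names held fixed at their
#'   start values; fixed parameters are returned bit-exactly unchanged.
#' @param n_starts number of multistart launches (default 5).
#' @param jitter_sd log-scale standard deviation of the start jitter.
#' @param seed seed for the jitter.
#' @return object of class `fit_result`: list with `estimates` (full named
#'   vector), `objective`, `convergence` (logical), `iterations`, `fixed`,
#'   `start`, `message`.
#' @export
fit <- function(model = c("pp", "aai"), observations, start,
                fixed = character(0), error_cv, n_starts = 5,
                jitter_sd = 0.3, seed = 1, rtol = 1e-6) {
  model <- match.arg(model)
  pnames <- .pd_param_names(model)
  if (!setequal(names(start), pnames)) {
    lt_stop("config", paste("'start' must have exactly the names:",
                            paste(pnames, collapse = ", ")))
  }
  start <- start[pnames]
  free <- setdiff(pnames, fixed)
  if (length(free) == 0L) lt_stop("config", "at least one parameter must be free")
  nll <- .make_nll(model, observations, error_cv, rtol)

  obj <- function(logv) {
    v <- start
    v[free] <- exp(logv)
    val <- tryCatch(nll(.pd_from_vector(model, v)), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  set.seed(seed)
  base <- log(start[free])
  best <- NULL
  iters <- 0L
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    s0 <- if (s == 1L) base else base + stats::rnorm(length(free), 0, jitter_sd)
    ans <- tryCatch(
      stats::nlminb(s0, obj, lower = log(1e-6), upper = log(1e6),
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    iters <- iters + ans$iterations
    if (is.null(best) || ans$objective < best$objective) best <- ans
    if (ans$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) {
    return(structure(list(estimates = start, objective = NA_real_,
                          convergence = FALSE, iterations = iters,
                          fixed = fixed, start = start,
                          message = "all starts failed"),
                     class = "fit_result"))
  }
  est <- start
  est[free] <- exp(best$par)
  structure(list(estimates = est, objective = best$objective,
                 convergence = conv, iterations = iters, fixed = fixed,
                 start = start, message = best$message),
            class = "fit_result")
}

#' Profile likelihood over one parameter
#'
#' Refits the free parameters at each value of `param`, returning the
#' profiled objective.  Used to demonstrate, for example, that the baseline
#' scaled dopamine `das0` of the interaction model is not identifiable from
#' prolactin-only data.
#'
#' @inheritParams fit
#' @param param name of the profiled parameter.
#' @param values grid of values for `param`.
#' @param ... passed to [fit()].
#' @return data frame with columns `value` and `objective`.
#' @export
profile_likelihood <- function(model, observations, param, values, start,
                               fixed = character(0), error_cv, ...) {
  rows <- lapply(values, function(v) {
    st <- start
    st[[param]] <- v
    fr <- fit(model, observations, st, fixed = union(fixed, param),
              error_cv = error_cv, ...)
    data.frame(value = v, objective = fr$objective)
  })
  do.call(rbind, rows)
}
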