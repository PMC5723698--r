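# Synthetic rat-study generator: emulates the single/two-dose IV rat design
# (risperidone 2 mg/kg, paliperidone 0.5 mg/kg, remoxipride 4/8/16 mg/kg,
# remoxipride 3.8 mg/kg twice) with a multiplicative lognormal residual
# error, so the estimation stage is testable with fully known ground truth.

#' Rat study design
#'
#' @param arms data frame with columns `compound`, `dose_mg_per_kg`,
#'   `n_animals`, `n_doses`, `dose_interval` (h between repeated doses;
#'   ignored for single-dose arms).  Default: the six-arm single/two-dose IV
#'   design.  The second-dose interval for the two-dose arm is not published;
#'   the documented default is 8 h.
#' @param sampling_times sampling times (h) after each dose, nonnegative and
#'   sorted; applied after every administration of an arm.
#' @param body_weight rat body weight (kg), default 0.28.
#' @return object of class `rat_study_design`.
#' @export
rat_study_design <- function(arms = NULL,
                             sampling_times = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8),
                             body_weight = 0.28) {
  if (is.null(arms)) {
    arms <- data.frame(
      compound = c("risperidone", "paliperidone", "remoxipride",
                   "remoxipride", "remoxipride", "remoxipride"),
      dose_mg_per_kg = c(2, 0.5, 4, 8, 16, 3.8),
      n_animals = 8L,
      n_doses = c(1L, 1L, 1L, 1L, 1L, 2L),
      dose_interval = 8,
      stringsAsFactors = FALSE
    )
  }
  check_positive(arms$dose_mg_per_kg, "dose_mg_per_kg")
  check_nonnegative(sampling_times, "sampling_times")
  if (is.unsorted(sampling_times)) lt_stop("config", "sampling_times must be sorted")
  check_positive(body_weight, "body_weight")
  structure(list(arms = arms, sampling_times = sampling_times,
                 body_weight = body_weight),
            class = "rat_study_design")
}

.arm_obs_times <- function(design, i) {
  a <- design$arms[i, ]
  dose_times <- a$dose_interval * (seq_len(a$n_doses) - 1)
  sort(unique(as.vector(outer(design$sampling_times, dose_times, `+`))))
}

.arm_regimen <- function(design, i) {
  a <- design$arms[i, ]
  dose_times <- a$dose_interval * (seq_len(a$n_doses) - 1)
  dose_regimen(time = dose_times,
               amount = a$dose_mg_per_kg * design$body_weight,
               route = "iv_bolus",
               horizon = max(.arm_obs_times(design, i)) + 1)
}

#' Generate a synthetic rat prolactin study
#'
#' Simulates noise-free prolactin profiles for every arm of the design with
#' the simulation engine, then applies multiplicative lognormal residual
#' error with coefficient of variation `error_cv` (log-scale standard
#' deviation `sqrt(log(1 + cv^2))`).  Fully reproducible from `seed`; the
#' generating truth is recorded in the `truth` attribute.
#'
#' @param design a [rat_study_design()].
#' @param model `"pp"` or `"aai"`.
#' @param pd_params named list of PD parameter objects by compound; default:
#'   the packaged synthetic rat sets for the chosen model.
#' @param rat_pk_params named list of `pk_2cmt` objects by compound; default:
#'   the packaged synthetic rat PK sets.
#' @param error_cv residual coefficient of variation, nonnegative
#'   (default 0.15).
#' @param seed integer seed, required.
#' @param rtol integrator relative tolerance for the noise-free profiles.
#' @return an `observation_set`: data frame with columns `arm`, `compound`,
#'   `animal`, `time_h`, `dv_ng_ml`, with the generating truth in
#'   `attr(, "truth")`.
#' @export
generate_study <- function(design = rat_study_design(), model = c("pp", "aai"),
                           pd_params = NULL, rat_pk_params = NULL,
                           error_cv = 0.15, seed, rtol = 1e-8) {
  model <- match.arg(model)
  check_nonnegative(error_cv, "error_cv")
  if (missing(seed)) lt_stop("config", "an explicit 'seed' is required")
  set.seed(seed)
  sdlog <- sqrt(log(1 + error_cv^2))
  compounds <- default_compounds()
  records <- vector("list", nrow(design$arms))
  pd_used <- list(); pk_used <- list()
  for (i in seq_len(nrow(design$arms))) {
    a <- design$arms[i, ]
    cmp <- compounds[[a$compound]]
    if (is.null(cmp)) lt_stop("config", paste("unknown compound in design:", a$compound))
    pd <- (pd_params[[a$compound]] %||%
             load_parameter_set(paste0(model, "_rat_", a$compound)))
    pk <- (rat_pk_params[[a$compound]] %||% load_rat_pk(a$compound))
    pd_used[[a$compound]] <- pd; pk_used[[a$compound]] <- pk
    times <- .arm_obs_times(design, i)
    sim <- run_scenario(model, cmp, .arm_regimen(design, i), pd, pk,
                        grid = times, rtol = rtol)
    pred <- sim$c_prl
    n_t <- length(times)
    n_id <- a$n_animals
    records[[i]] <- data.frame(
      arm = i, compound = a$compound,
      animal = rep(seq_len(n_id), each = n_t),
      time_h = rep(times, n_id),
      dv_ng_ml = rep(pred, n_id) * exp(stats::rnorm(n_t * n_id, 0, sdlog)),
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, records)
  rownames(obs) <- NULL
  structure(obs,
            truth = list(model = model, pd_params = pd_used,
                         pk_params = pk_used, error_cv = error_cv,
                         seed = seed, design = design),
            class = c("observation_set", "data.frame"))
}

#' Write an observation set as CSV plus a truth JSON sidecar
#'
#' @param obs an `observation_set`.
#' @param path CSV output path; the truth sidecar is written next to it as
#'   `<path>.truth.json`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  truth <- attr(obs, "truth")
  side <- list(
    model = truth$model, error_cv = truth$error_cv, seed = truth$seed,
    pd_params = lapply(truth$pd_params, unclass),
    pk_params = lapply(truth$pk_params, unclass),
    design = list(arms = truth$design$arms,
                  sampling_times = truth$design$sampling_times,
                  body_weight = truth$design$body_weight)
  )
  jsonlite::write_json(side, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
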