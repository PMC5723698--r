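# shared helpers: relative error, small study designs, cached fixtures

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# maximum relative deviation with a floor on the denominator so near-zero
# tails do not dominate (floor = frac of the series maximum)
max_rel_dev <- function(a, b, floor_frac = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor_frac * max(abs(b))))
}

# one-arm rat study design used by the estimation tests
design_one_arm <- function(compound = "remoxipride", dose = 8, n_animals = 8L,
                           times = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8)) {
  rat_study_design(
    arms = data.frame(compound = compound, dose_mg_per_kg = dose,
                      n_animals = n_animals, n_doses = 1L, dose_interval = 8,
                      stringsAsFactors = FALSE),
    sampling_times = times
  )
}

pp_trans <- function() load_parameter_set("pp_translational")
cmp_rem <- function() default_compounds("remoxipride")
cmp_pa <- function() default_compounds("paliperidone")
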