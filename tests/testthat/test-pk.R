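# pk_engine: analytic superposition vs ODE mass balances

mw_rem <- 371.26
mw_pa <- 426.48
pk_iv <- function() pk_2cmt_params(cl = 8, v1 = 40, q = 15, v2 = 18)
pk_or <- function() pk_oros_params(22, 0.5, 12, 485)

test_that("bolus initial condition and elimination limit hold", {
  grid <- c(0, seq(0.1, 200, by = 0.5))
  reg <- dose_regimen(0, 200, horizon = 200)
  conc <- simulate_iv_2cmt(reg, pk_iv(), grid, mw_rem)
  expect_equal(conc[1], lactotran:::mgL_to_nmolL(200 / 40, mw_rem))
  expect_lt(conc[length(conc)] / max(conc), 1e-6)
  expect_true(all(conc >= 0))
})

test_that("the IV model is linear and obeys superposition", {
  grid <- seq(0, 72, by = 0.25)
  one <- simulate_iv_2cmt(dose_regimen(0, 100, horizon = 72), pk_iv(), grid, mw_rem)
  shifted <- simulate_iv_2cmt(dose_regimen(24, 100, horizon = 72), pk_iv(), grid, mw_rem)
  both <- simulate_iv_2cmt(dose_regimen(c(0, 24), 100, horizon = 72), pk_iv(), grid, mw_rem)
  expect_equal(both, one + shifted, tolerance = 1e-12)
  double <- simulate_iv_2cmt(dose_regimen(c(0, 24), 200, horizon = 72), pk_iv(), grid, mw_rem)
  expect_equal(double, 2 * both, tolerance = 1e-12)
})

test_that("analytic and ODE routes agree within 0.1% (IV and oral)", {
  grid <- seq(0, 48, by = 0.2)
  reg_iv <- dose_regimen(c(0, 12, 24), c(100, 100, 100), horizon = 48)
  a <- simulate_iv_2cmt(reg_iv, pk_iv(), grid, mw_rem)
  o <- ode_reference(reg_iv, pk_iv(), grid, mw_rem)
  expect_lt(max_rel_dev(o, a), 1e-3)

  reg_inf <- dose_regimen(c(0, 24), 150, route = "iv_infusion", duration = 2,
                          horizon = 48)
  a2 <- simulate_iv_2cmt(reg_inf, pk_iv(), grid, mw_rem)
  o2 <- ode_reference(reg_inf, pk_iv(), grid, mw_rem)
  expect_lt(max_rel_dev(o2, a2), 1e-3)

  reg_or <- dose_regimen(c(0, 24), 12, route = "oral_oros", duration = 22,
                         horizon = 48)
  a3 <- simulate_oral_oros(reg_or, pk_or(), grid, mw_pa)
  o3 <- ode_reference(reg_or, pk_or(), grid, mw_pa)
  expect_lt(max_rel_dev(o3, a3), 1e-3)
})

test_that("oral model conserves mass at all times", {
  grid <- seq(0, 72, by = 0.5)
  reg <- dose_regimen(c(0, 24), 12, route = "oral_oros", duration = 22,
                      horizon = 72)
  o <- ode_reference(reg, pk_or(), grid, mw_pa)
  st <- attr(o, "states")
  released <- sapply(grid, function(t) {
    sum(pmin(pmax(t - reg$time, 0), reg$duration) * reg$amount / reg$duration)
  })
  in_system <- rowSums(st)
  expect_lt(max(abs(in_system - released)) / max(released), 1e-6)
  # and the absorbed amount tends to the full released dose
  expect_equal(unname(sum(st[length(grid), ])), 24, tolerance = 1e-6)
})

test_that("short release converges to the first-order Bateman curve", {
  grid <- seq(0, 48, by = 0.2)
  p <- pk_or()
  ke <- p$cl_over_f / p$v_over_f
  reg <- dose_regimen(0, 12, route = "oral_oros", duration = 1e-4, horizon = 48)
  conc <- simulate_oral_oros(reg, p, grid, mw_pa)
  bateman <- lactotran:::mgL_to_nmolL(
    12 * p$ka / (p$v_over_f * (p$ka - ke)) * (exp(-ke * grid) - exp(-p$ka * grid)),
    mw_pa)
  expect_lt(max_rel_dev(conc, bateman, floor_frac = 1e-3), 1e-3)
})

test_that("once-daily oral dosing accumulates to steady state around day 4", {
  # the ~28 h half-life implies ~90% of the steady-state trough at day 4
  # (the conventional 3.3-half-life rule) and >=95% by day 6
  reg <- regimen_repeated(6, 24, 30, route = "oral_oros", duration = 22,
                          horizon = 30 * 24)
  grid <- seq(0, 30 * 24, by = 1)
  conc <- simulate_oral_oros(reg, pk_or(), grid, mw_pa)
  trough <- conc[match(24 * (1:29), grid)]
  ss <- trough[29]
  expect_gt(trough[4] / ss, 0.90)
  expect_gt(trough[6] / ss, 0.95)
  expect_lt(trough[2] / ss, 0.90)
})

test_that("grid and route preconditions are enforced", {
  reg <- dose_regimen(c(0, 24), 100, horizon = 48)
  expect_error(simulate_iv_2cmt(reg, pk_iv(), seq(0, 12, 0.5), mw_rem),
               class = "lactotran_domain")
  reg_mix <- dose_regimen(0, 100, route = "iv_bolus", horizon = 24)
  expect_error(simulate_oral_oros(reg_mix, pk_or(), seq(0, 24, 0.5), mw_pa),
               class = "lactotran_invalid_parameter")
  expect_error(pk_oros_params(0, 0.5, 12, 485),
               class = "lactotran_invalid_parameter")
  # zero-dose regimen integrates to identically zero
  z <- ode_reference(dose_regimen(numeric(0), horizon = 24), pk_iv(),
                     seq(0, 24, 1), mw_rem)
  expect_equal(as.numeric(z), rep(0, 25))
})
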