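# simulation_engine: scenario runs, summaries, benchmarks

test_that("zero-dose scenarios stay flat at the analytic baseline", {
  reg <- dose_regimen(numeric(0), horizon = 48)
  pp <- pp_trans()
  sim <- run_scenario("pp", cmp_rem(), reg, pp, load_human_pk("remoxipride"),
                      grid_step = 0.5)
  base <- pool_baseline(pp)
  expect_lt(max(rel_err(sim$c_pool, base[["c_pool0"]])), 1e-6)
  expect_lt(max(rel_err(sim$c_prl, base[["c_prl0"]])), 1e-6)
  expect_equal(max(sim$ro_drug), 0)

  aai <- load_parameter_set("aai_translational", compound = "remoxipride")
  sima <- run_scenario("aai", cmp_rem(), reg, aai, load_human_pk("remoxipride"),
                       grid_step = 0.5)
  ab <- aai_baseline(aai)
  expect_lt(max(rel_err(sima$c_prl, ab[["c_prl0"]])), 1e-6)
  expect_lt(max(rel_err(sima$das, ab[["das0"]])), 1e-6)
})

test_that("scenario output respects the result-shape contract", {
  reg <- human_regimen("remoxipride", 100, 24, 2)
  sim <- run_scenario("pp", cmp_rem(), reg, pp_trans(),
                      load_human_pk("remoxipride"), grid_step = 0.5)
  expect_true(all(c("time", "c_total", "c_unbound", "c_pool", "c_prl",
                    "das", "ro_drug", "ro_dopamine") %in% names(sim)))
  expect_true(all(sim$ro_drug >= 0 & sim$ro_drug <= 100))
  expect_true(all(sim$c_prl >= 0))
  expect_equal(sim$c_unbound, sim$c_total * 0.2)
  meta <- attr(sim, "meta")
  expect_equal(meta$model, "pp")
  expect_equal(meta$compound, "remoxipride")
})

test_that("route/model mismatches raise config errors", {
  reg_iv <- dose_regimen(0, 100, horizon = 24)
  expect_error(
    run_scenario("pp", cmp_pa(), reg_iv, pp_trans(), load_human_pk("paliperidone")),
    class = "lactotran_config")
  reg_or <- dose_regimen(0, 12, route = "oral_oros", duration = 22, horizon = 24)
  expect_error(
    run_scenario("pp", cmp_rem(), reg_or, pp_trans(), load_human_pk("remoxipride")),
    class = "lactotran_config")
  expect_error(
    run_scenario("pp", cmp_rem(), reg_iv, load_parameter_set("aai_friberg_ma"),
                 load_human_pk("remoxipride")),
    class = "lactotran_config")
})

test_that("summarize_occupancy computes window order statistics", {
  flat <- data.frame(time = 0:10, ro_drug = 40, c_prl = 1)
  s <- summarize_occupancy(flat, c(2, 8))
  expect_equal(c(s$peak, s$median, s$p5, s$p95), rep(40, 4))
  expect_error(summarize_occupancy(flat, c(100, 110)), class = "lactotran_domain")

  reg <- human_regimen("remoxipride", 100, 8, 24)
  sim <- run_scenario("pp", cmp_rem(), reg, pp_trans(),
                      load_human_pk("remoxipride"), grid_step = 0.25)
  s2 <- summarize_occupancy(sim, c(168, 192))
  expect_lte(s2$p5, s2$median)
  expect_lte(s2$median, s2$p95)
  expect_lte(s2$p95, s2$peak)
})

test_that("tolerance_ratio is 1 for identical days and guards its domain", {
  reg <- dose_regimen(numeric(0), horizon = 72)
  sim <- run_scenario("pp", cmp_rem(), reg, pp_trans(),
                      load_human_pk("remoxipride"), grid_step = 0.5)
  expect_equal(tolerance_ratio(sim, 1, 3), 1, tolerance = 1e-6)
  expect_error(tolerance_ratio(sim, 1, 30), class = "lactotran_domain")
})

test_that("benchmark runs use the published human sets", {
  reg <- human_regimen("remoxipride", 100, 24, 8)
  bm <- run_benchmark("aai", cmp_rem(), reg, grid_step = 0.5)
  expect_equal(signif(bm$c_prl[1], 3), 12.7)
  # the original pool model predicts less tolerance than the translational
  # set: later-day peaks recover more
  bm_pp <- run_benchmark("pp", cmp_rem(), reg, grid_step = 0.25)
  tr <- run_scenario("pp", cmp_rem(), reg, pp_trans(),
                     load_human_pk("remoxipride"), grid_step = 0.25)
  expect_gt(tolerance_ratio(bm_pp, 1, 8), tolerance_ratio(tr, 1, 8))
})

test_that("release flux bookkeeping balances over a scenario", {
  # integral of K_base*(1+DE)*C_pool equals the change in plasma content
  # plus integrated elimination
  reg <- dose_regimen(0, 200, horizon = 48)
  pd <- pp_trans()
  sim <- run_scenario("pp", cmp_rem(), reg, pd, load_human_pk("remoxipride"),
                      grid_step = 0.01)
  de <- drug_effect_ro(occupancy_drug(sim$c_unbound, 165.75, 0),
                       pd$emax, pd$ro50, pd$gamma)
  release <- pd$k_base * (1 + de) * sim$c_pool
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  lhs <- trapz(sim$time, release)
  rhs <- (sim$c_prl[nrow(sim)] - sim$c_prl[1]) +
    pd$k_out * trapz(sim$time, sim$c_prl)
  expect_lt(abs(lhs - rhs) / rhs, 1e-4)
})
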