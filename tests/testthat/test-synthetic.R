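small_cfg <- function(...) {
  scenario_config(
    n_cities = 8L, n_sites = 9L, n_core_cities = 4L,
    ...
  )
}

test_that("generation is deterministic under a fixed seed", {
  a <- generate_scenario(small_cfg(seed = 77))
  b <- generate_scenario(small_cfg(seed = 77))
  expect_identical(a$dataset$measurements, b$dataset$measurements)
  expect_identical(a$dataset$catchments, b$dataset$catchments)
  expect_identical(a$truth, b$truth)
  c <- generate_scenario(small_cfg(seed = 78))
  expect_false(identical(a$dataset$measurements, c$dataset$measurements))
})

test_that("invalid configurations fail before any generation", {
  expect_error(scenario_config(n_cities = 0), "n_cities")
  expect_error(scenario_config(n_sites = 5, n_cities = 10), "n_sites")
  expect_error(scenario_config(years = c(2015, 2011)), "sorted")
  expect_error(scenario_config(n_core_cities = 200), "n_core_cities")
  expect_error(scenario_config(noise_sd = -1), "noise_sd")
})

test_that("zero noise, unit trends and no weekend effect give flat weeks", {
  cfg <- small_cfg(
    noise_sd = 0,
    weekend_uplift = setNames(rep(1, 6), WBE_SUBSTANCES),
    loq = setNames(rep(1e-9, 6), WBE_SUBSTANCES),
    dumping_rate = 0, seed = 5
  )
  g <- generate_scenario(cfg)
  daily <- compute_daily_loads(g$dataset)$daily
  spread <- daily |>
    dplyr::group_by(.data$site_id, .data$year, .data$substance) |>
    dplyr::summarise(
      n = dplyr::n(), span = max(.data$load) - min(.data$load),
      .groups = "drop"
    )
  expect_true(all(spread$n == 7))
  expect_true(all(abs(spread$span) < 1e-9))
  # and the flat level is the city baseline recorded in the ground truth
  chk <- dplyr::inner_join(
    daily, g$truth$city_year,
    by = c("city", "year", "substance")
  )
  expect_equal(chk$load, chk$true_mean_load, tolerance = 1e-12)
})

test_that("generated concentrations invert back to the realized loads", {
  g <- generate_scenario(small_cfg(seed = 9))
  m <- g$dataset$measurements
  pop <- setNames(g$dataset$catchments$population, g$dataset$catchments$site_id)
  keep <- !m$censored
  recovered <- daily_load(
    m$concentration[keep], m$flow[keep], unname(pop[m$site_id[keep]])
  )
  truth <- g$truth$daily
  key <- paste(truth$site_id, truth$date, truth$substance)
  idx <- match(paste(m$site_id, m$date, m$substance)[keep], key)
  expect_equal(recovered, truth$realized_load[idx], tolerance = 1e-12)
})

test_that("the heavy-censoring scenario censors about half of all days", {
  g <- bench_suite()$heavy_censoring
  frac <- mean(g$dataset$measurements$censored)
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
  # censoring flags in the dataset agree with the generator's ground truth
  m <- g$dataset$measurements
  truth <- g$truth$daily
  key <- paste(truth$site_id, truth$date, truth$substance)
  idx <- match(paste(m$site_id, m$date, m$substance), key)
  expect_identical(m$censored, truth$censored[idx])
})

test_that("true doses are recoverable from a noiseless campaign", {
  cfg <- small_cfg(
    noise_sd = 0,
    weekend_uplift = setNames(rep(1, 6), WBE_SUBSTANCES),
    loq = setNames(rep(1e-9, 6), WBE_SUBSTANCES),
    dumping_rate = 0, seed = 31
  )
  g <- generate_scenario(cfg)
  dt <- city_dose_table(g$dataset)
  comb <- merge(
    dt[dt$substance == "combined", ], g$truth$combined,
    by = c("city", "year")
  )
  expect_gt(nrow(comb), 0)
  expect_lt(max(abs(comb$doses_1000p_d / comb$true_combined_doses - 1)), 1e-9)
})

test_that("the benchmark suite covers the six standard scenarios", {
  suite <- bench_suite()
  expect_named(
    suite,
    c(
      "null", "increase", "decrease", "heavy_censoring",
      "dumping_rich", "eindhoven_like"
    )
  )
  expect_true(all(suite$increase$truth$trends$direction == "increase"))
  expect_true(all(suite$decrease$truth$trends$direction == "decrease"))
  expect_true(all(suite$null$truth$trends$direction == "none"))
  expect_gt(nrow(suite$dumping_rich$truth$dumping), 0)
  expect_equal(nrow(suite$eindhoven_like$truth$outliers), 2)
})
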