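test_that("a well-formed file parses, normalising the <LOQ token", {
  mp <- write_fixture_csv(fixture_measurement_lines)
  sp <- write_fixture_csv(fixture_sites_lines)
  ds <- read_dataset(mp, sp)
  expect_s3_class(ds, "wbe_dataset")
  expect_equal(nrow(ds$measurements), 3L)
  expect_equal(sum(ds$measurements$censored), 1L)
  expect_true(is.na(ds$measurements$concentration[ds$measurements$censored]))
  expect_equal(ds$measurements$flow[1], 2e7)
})

test_that("a missing mandatory column is a hard error naming the column", {
  bad <- sub(",flow_l_d", "", fixture_measurement_lines)
  bad <- sub(",20000000$", "", bad)
  bad <- sub(",60000000$", "", bad)
  mp <- write_fixture_csv(bad)
  expect_error(read_measurements(mp), "flow")
})

test_that("unknown substances and orphan site ids are hard errors", {
  mp <- write_fixture_csv(c(
    fixture_measurement_lines,
    "s1,2015-03-06,ketamine,5,1,FALSE,20000000"
  ))
  sp <- write_fixture_csv(fixture_sites_lines)
  expect_error(read_dataset(mp, sp), "ketamine")

  mp <- write_fixture_csv(c(
    fixture_measurement_lines,
    "s9,2015-03-06,mdma,5,1,FALSE,20000000"
  ))
  expect_error(read_dataset(mp, sp), "s9")
})

test_that("uncensored concentrations between 0 and the LOQ warn but load", {
  mp <- write_fixture_csv(c(
    fixture_measurement_lines,
    "s2,2015-03-05,mdma,5.0,10,FALSE,60000000"
  ))
  sp <- write_fixture_csv(fixture_sites_lines)
  expect_warning(ds <- read_dataset(mp, sp), "between 0 and the LOQ")
  expect_equal(nrow(ds$measurements), 4L)
  expect_false(ds$measurements$censored[4])
})

test_that("flows reported in m3/day are converted to L/day on ingest", {
  lines <- c(
    "site_id,date,substance,concentration_ng_l,loq_ng_l,censored,flow_l_d,flow_unit",
    "s1,2015-03-04,mdma,50,5,FALSE,20000,m3/day",
    "s1,2015-03-05,mdma,50,5,FALSE,20000000,L/day"
  )
  m <- read_measurements(write_fixture_csv(lines))
  expect_equal(m$flow, c(2e7, 2e7))
})

test_that("write/read round-trip preserves numerics and censoring exactly", {
  ds <- make_tiny_dataset()
  dir <- tempfile("roundtrip")
  write_dataset(ds, dir)
  ds2 <- read_dataset(
    file.path(dir, "measurements.csv"), file.path(dir, "sites.csv"),
    file.path(dir, "params.csv")
  )
  expect_identical(ds2$measurements$concentration, ds$measurements$concentration)
  expect_identical(ds2$measurements$censored, ds$measurements$censored)
  expect_identical(ds2$measurements$flow, ds$measurements$flow)
  expect_identical(ds2$measurements$loq, ds$measurements$loq)
  expect_identical(ds2$catchments$population, ds$catchments$population)
  expect_identical(ds2$params, ds$params)
})

test_that("validate_dataset reports invariant violations without mutating", {
  ds <- make_tiny_dataset()
  rep <- validate_dataset(ds)
  expect_equal(rep$n_errors, 0L)
  expect_equal(rep$n_warnings, 0L)

  bad <- ds
  bad$catchments$population[1] <- 0
  rep <- validate_dataset(bad)
  expect_equal(rep$n_errors, 1L)
  expect_match(rep$errors, "s1")
  # reporting is side-effect-free and idempotent
  expect_identical(validate_dataset(bad), rep)
  expect_equal(bad$catchments$population[1], 0)
})

test_that("duplicate (site, date, substance) rows raise a warning per group", {
  ds <- make_tiny_dataset()
  dup <- ds
  dup$measurements <- dplyr::bind_rows(
    dup$measurements, dup$measurements[1, ]
  )
  rep <- validate_dataset(dup)
  expect_equal(rep$n_errors, 0L)
  expect_equal(rep$n_warnings, 1L)
  expect_match(rep$warnings, "duplicate")
  # and the load stage averages them with a warning
  expect_warning(res <- compute_daily_loads(dup), "averaged")
  expect_equal(
    res$daily$load[res$daily$date == as.Date("2015-03-04") &
      res$daily$substance == "benzoylecgonine"],
    daily_load(800, 2e7, 1e5)
  )
})

test_that("YAML parameter files are accepted", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "benzoylecgonine:",
    "  excretion_fraction: 0.29",
    "  molar_mass_ratio: 1.0485",
    "  dose_mg: 100"
  ), f)
  p <- read_drug_params(f)
  expect_equal(p$excretion_fraction, 0.29)
  expect_equal(p$dose_mg, 100)
})
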