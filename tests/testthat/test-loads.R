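test_that("daily_load performs the unit conversion exactly", {
  expect_identical(daily_load(1000, 1e7, 1e5), 100)
  expect_identical(daily_load(500, 2e7, 5e4), 200)
  expect_identical(daily_load(0, 3e6, 12345), 0)
  expect_error(daily_load(10, 0, 100), "flow")
  expect_error(daily_load(10, 1e6, 0), "population")
  expect_error(daily_load(-1, 1e6, 100), "concentration")
})

test_that("daily_load is homogeneous in concentration and inversely scales with population", {
  set.seed(42)
  for (i in 1:200) {
    conc <- runif(1, 0, 2000)
    flow <- runif(1, 1e5, 1e8)
    pop <- runif(1, 1e3, 2e6)
    k <- runif(1, 0.1, 10)
    expect_equal(daily_load(k * conc, flow, pop), k * daily_load(conc, flow, pop))
    expect_equal(daily_load(conc, flow, 2 * pop), daily_load(conc, flow, pop) / 2)
  }
})

week_fixture <- function(conc, censored, loq = 10, flow = 1e7) {
  n <- length(conc)
  tibble::tibble(
    date = as.Date("2015-03-04") + seq_len(n) - 1,
    concentration = conc, loq = loq, censored = censored, flow = flow
  )
}

test_that("an all-censored week is excluded and emits no loads", {
  wk <- week_fixture(rep(NA_real_, 7), rep(TRUE, 7))
  res <- apply_loq_policy(wk, population = 1e5)
  expect_false(res$included)
  expect_equal(nrow(res$loads), 0L)
})

test_that("partially censored weeks substitute 0.5 x LOQ and flag imputation", {
  wk <- week_fixture(c(NA, 20, 30, 40, 50, 60, 70), c(TRUE, rep(FALSE, 6)))
  res <- apply_loq_policy(wk, population = 1e5)
  expect_true(res$included)
  expect_equal(res$loads$load[1], daily_load(5, 1e7, 1e5))
  expect_identical(res$loads$imputed, c(TRUE, rep(FALSE, 6)))
  expect_equal(res$loads$load[2], daily_load(20, 1e7, 1e5))
})

test_that("uncensored weeks pass through unchanged", {
  wk <- week_fixture(10 * 1:7, rep(FALSE, 7))
  res <- apply_loq_policy(wk, population = 1e5)
  expect_true(res$included)
  expect_false(any(res$loads$imputed))
  expect_equal(res$loads$load, daily_load(10 * 1:7, 1e7, 1e5))
  expect_error(apply_loq_policy(wk[0, ], 1e5), "empty")
})

test_that("imputed loads lie strictly between 0 and the full-LOQ load", {
  set.seed(7)
  for (i in 1:100) {
    loq <- runif(1, 1, 50)
    wk <- week_fixture(
      c(NA, runif(6, loq, 1000)), c(TRUE, rep(FALSE, 6)),
      loq = loq, flow = runif(1, 1e6, 1e8)
    )
    pop <- runif(1, 1e4, 1e6)
    res <- apply_loq_policy(wk, pop)
    full <- daily_load(loq, wk$flow[1], pop)
    expect_gt(res$loads$load[1], 0)
    expect_lt(res$loads$load[1], full)
  }
})

test_that("weekly_summary computes mean, sample SD, min, max and n_days", {
  s <- weekly_summary(c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$min, 10)
  expect_equal(s$max, 30)
  expect_equal(s$n_days, 3L)

  s <- weekly_summary(rep(100, 7))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)

  s <- weekly_summary(42)
  expect_equal(s$mean, 42)
  expect_equal(s$sd, 0)
  expect_equal(s$n_days, 1L)

  expect_error(weekly_summary(numeric()), "empty")
})

test_that("weekly means equal the brute-force mean of emitted daily loads", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:7, 1)
    loq <- runif(1, 1, 20)
    cens <- runif(n) < 0.3
    conc <- ifelse(cens, NA, runif(n, loq, 500))
    if (all(cens)) cens[1] <- FALSE
    if (!cens[1] && is.na(conc[1])) conc[1] <- loq + 1
    wk <- week_fixture(conc, cens, loq = loq)
    res <- apply_loq_policy(wk, 1e5)
    oracle <- mean(daily_load(ifelse(cens, loq / 2, conc), 1e7, 1e5))
    expect_equal(weekly_summary(res$loads$load)$mean, oracle)
  }
})

test_that("city_load is the population-weighted mean of site means", {
  expect_equal(city_load(150, 2e5), 150)
  expect_equal(city_load(c(100, 300), c(1e5, 3e5)), 250)
  expect_true(is.na(city_load(c(NA_real_, NA_real_), c(1e5, 3e5))))
})

test_that("compute_daily_loads applies the week policy per site/substance/year", {
  ds <- make_tiny_dataset()
  res <- compute_daily_loads(ds)
  expect_equal(nrow(res$daily), 3L)
  expect_equal(sum(res$daily$imputed), 1L)
  imput <- res$daily[res$daily$imputed, ]
  expect_equal(imput$load, daily_load(5, 2e7, 1e5))
  expect_equal(nrow(res$excluded_weeks), 0L)

  # make the s1 week fully censored: it must disappear from loads
  ds$measurements$censored[1] <- TRUE
  ds$measurements$concentration[1] <- NA
  res <- compute_daily_loads(ds)
  expect_equal(nrow(res$excluded_weeks), 1L)
  expect_equal(res$excluded_weeks$reason, "all_below_loq")
  expect_false("benzoylecgonine" %in% res$daily$substance)
})
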