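# independent oracle: normal-equations OLS + t CDF
ols_oracle <- function(years, values) {
  n <- length(years)
  x <- years - mean(years)
  slope <- sum(x * values) / sum(x^2)
  intercept <- mean(values) - slope * mean(years)
  resid <- values - (intercept + slope * years)
  se <- sqrt(sum(resid^2) / (n - 2) / sum(x^2))
  t <- slope / se
  list(slope = slope, p = 2 * pt(-abs(t), n - 2))
}

test_that("a perfect increasing line is classified as an increase", {
  tc <- classify_trend(2014:2017, c(10, 20, 30, 40))
  expect_equal(tc$call, "increase")
  expect_equal(tc$slope, 10)
  expect_lt(tc$p_value, 1e-10)
})

test_that("two observations never earn a trend call", {
  tc <- classify_trend(c(2011, 2013), c(10, 40))
  expect_equal(tc$call, "no_trend")
  expect_true(is.na(tc$p_value))
})

test_that("flat series and sub-threshold evidence give no_trend", {
  expect_equal(classify_trend(2014:2017, rep(10, 4))$call, "no_trend")
  # noisy short series whose oracle P is far above 0.2
  yrs <- 2013:2017
  vals <- c(12, 9, 13, 8, 11)
  expect_gt(ols_oracle(yrs, vals)$p, 0.2)
  expect_equal(classify_trend(yrs, vals)$call, "no_trend")
})

test_that("fewer than two observations are insufficient; duplicate years error", {
  expect_equal(classify_trend(2015, 10)$call, "insufficient")
  expect_equal(classify_trend(integer(), numeric())$call, "insufficient")
  expect_error(classify_trend(c(2015, 2015, 2016), c(1, 2, 3)), "duplicate")
})

test_that("classify_trend agrees with a brute-force OLS oracle", {
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    yrs <- sort(sample(2010:2019, n))
    vals <- abs(rnorm(n, 50, 20))
    tc <- classify_trend(yrs, vals)
    or <- ols_oracle(yrs, vals)
    expect_equal(tc$slope, or$slope, tolerance = 1e-8)
    if (!is.nan(or$p)) expect_equal(tc$p_value, or$p, tolerance = 1e-8)
    expected <- if (is.nan(or$p) || or$p >= 0.2 || or$slope == 0) {
      "no_trend"
    } else if (or$slope > 0) "increase" else "decrease"
    expect_identical(tc$call, expected)
  }
})

test_that("reflecting a series about its mean flips increase and decrease", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    yrs <- sort(sample(2010:2019, n))
    vals <- abs(rnorm(n, 50, 25))
    a <- classify_trend(yrs, vals)
    b <- classify_trend(yrs, 2 * mean(vals) - vals)
    expect_equal(b$slope, -a$slope, tolerance = 1e-9)
    flip <- c(
      increase = "decrease", decrease = "increase",
      no_trend = "no_trend", insufficient = "insufficient"
    )
    expect_identical(b$call, unname(flip[a$call]))
  }
})

test_that("period_mean averages annual means inside the window", {
  yrs <- c(2011, 2012, 2013)
  expect_equal(period_mean(yrs, c(100, 200, 300), c(2011, 2013)), 200)
  expect_equal(period_mean(yrs, c(100, 200, 300), c(2013, 2013)), 300)
  expect_true(is.na(period_mean(yrs, c(100, 200, 300), c(2014, 2017))))
})

test_that("core-city selection thresholds on distinct monitored years", {
  sums <- make_summaries(tibble::tibble(
    site_id = c(rep("a", 5), rep("b", 4)),
    city = c(rep("A", 5), rep("B", 4)),
    year = c(2011:2015, 2011:2014)
  ))
  ds <- list(catchments = tibble::tibble(site_id = c("a", "b")))
  expect_equal(core_city_selection(ds, 5, summaries = sums), "A")
  expect_equal(core_city_selection(ds, 4, summaries = sums), c("A", "B"))
  # excluded weeks do not count toward the year tally
  sums$included[5] <- FALSE
  sums$exclusion_reason[5] <- "all_below_loq"
  expect_equal(core_city_selection(ds, 5, summaries = sums), character())
})

test_that("the synthetic default campaign has exactly 26 core cities", {
  g <- generate_scenario(scenario_config(seed = 101))
  expect_setequal(core_city_selection(g$dataset), g$truth$core_cities)
  expect_length(core_city_selection(g$dataset), 26)
})

overall_fixture <- function() {
  cl <- tibble::tibble(
    city = c("A", "B", "C"), year = 2015L, substance = "amphetamine",
    load = c(100, 200, 300), n_sites = 1L, included = TRUE
  )
  ds <- list(
    exclusions = empty_exclusions(),
    catchments = tibble::tibble(
      site_id = c("a", "b", "c"), city = c("A", "B", "C")
    )
  )
  list(cl = cl, ds = ds)
}

test_that("overall means average eligible cities and honour exclusions", {
  fx <- overall_fixture()
  om <- overall_mean(fx$ds, 2015, "amphetamine",
    variant = "all_cities", city_loads = fx$cl
  )
  expect_equal(om$mean, 200)
  expect_equal(om$n_cities, 3L)

  fx$ds$exclusions <- tibble::tibble(
    scope = "city", name = "C", substance = "amphetamine",
    reason = "manufacturing discharges"
  )
  om <- overall_mean(fx$ds, 2015, "amphetamine",
    variant = "all_cities", city_loads = fx$cl
  )
  expect_equal(om$mean, 150)
  # the exclusion is substance-specific
  om2 <- overall_mean(fx$ds, 2015, "mdma",
    variant = "all_cities",
    city_loads = dplyr::mutate(fx$cl, substance = "mdma")
  )
  expect_equal(om2$mean, 200)
})

test_that("the core-cities variant matches a brute-force filter and mean", {
  g <- bench_suite()$eindhoven_like
  ds <- g$dataset
  cl <- city_year_loads(ds)
  core <- core_city_selection(ds, min_years = 5)
  for (yr in c(2012L, 2016L)) {
    om <- overall_mean(ds, yr, "benzoylecgonine",
      variant = "core_cities",
      city_loads = cl, core_cities = core
    )
    brute <- cl[cl$year == yr & cl$substance == "benzoylecgonine" &
      cl$included & cl$city %in% core, ]
    expect_equal(om$mean, mean(brute$load))
    expect_equal(om$n_cities, nrow(brute))
  }
})

test_that("trend power rises with effect size on synthetic campaigns", {
  rate_for <- function(mult, seed) {
    g <- generate_scenario(trend_scenario_config(mult, seed))
    tc <- trend_calls(g$dataset, periods = list(c(2011, 2017)))
    tc <- tc[tc$substance != "cocaine", ]
    mean(tc$call == "increase")
  }
  null_rate <- rate_for(1.00, 301)
  mid_rate <- rate_for(1.05, 302)
  high_rate <- rate_for(1.10, 303)
  expect_gt(mid_rate, null_rate)
  expect_gte(high_rate, mid_rate)
  expect_gt(high_rate, 0.5)
})
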