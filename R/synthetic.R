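region_country_pool <- list(
  south_west_europe = c("ES", "PT", "IT", "FR", "CH", "BE", "NL", "GB"),
  north_europe = c("NO", "SE", "FI", "DK", "IS"),
  east_central_europe = c("CZ", "SK", "PL", "DE", "HR", "SI", "RS", "GR", "CY"),
  non_europe = c("AU", "NZ", "US", "CA", "CO", "KR", "IL", "MQ")
)

default_baseline_gm <- function() {
  # geometric-mean loads (mg/1000 people/day) by region x substance,
  # patterned on the published spatial profile: cocaine (via BZE) dominant
  # in the south-west, amphetamine in the north, methamphetamine in the
  # east and outside Europe
  rbind(
    south_west_europe = c(
      benzoylecgonine = 250, amphetamine = 15, methamphetamine = 5,
      mdma = 20, thc_cooh = 80
    ),
    north_europe = c(
      benzoylecgonine = 80, amphetamine = 50, methamphetamine = 20,
      mdma = 25, thc_cooh = 60
    ),
    east_central_europe = c(
      benzoylecgonine = 40, amphetamine = 30, methamphetamine = 80,
      mdma = 10, thc_cooh = 50
    ),
    non_europe = c(
      benzoylecgonine = 60, amphetamine = 10, methamphetamine = 120,
      mdma = 8, thc_cooh = 70
    )
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' The defaults emulate the structure of the 2011-2017 international
#' monitoring campaigns: 120 cities served by 143 treatment plants, one
#' 7-day composite-sampling week per site-year starting on the first
#' Wednesday of March, a 26-city core subset monitored in every year,
#' region-stratified lognormal city baselines whose cross-city span
#' exceeds two orders of magnitude, day-of-week uplift on the
#' cocaine/MDMA channels, below-LOQ censoring, and occasional
#' direct-disposal (dumping) spikes on the cocaine parent.
#'
#' @param n_cities,n_sites Numbers of cities and treatment plants
#'   (`n_sites >= n_cities`; extra plants are second sites of randomly
#'   chosen cities).
#' @param years Monitored calendar years (sorted).
#' @param days_per_week Consecutive sampling days per campaign (default 7).
#' @param substances Substance tokens to generate.
#' @param baseline_gm Region x substance matrix of geometric-mean loads
#'   (mg/1000 people/day); cocaine is derived from benzoylecgonine via
#'   `cocaine_bze_ratio`, so it needs no column.
#' @param region_weights Named sampling weights for city regions.
#' @param city_gsd Geometric SD of city baselines around the regional
#'   geometric mean (default 3.2, sized so a 120-city campaign spans more
#'   than two orders of magnitude between the 2.5th and 97.5th city
#'   percentiles).
#' @param trend_multipliers Named per-substance annual multiplicative
#'   trends (default 1 = stationary).
#' @param weekend_uplift Named per-substance Saturday/Sunday multipliers
#'   (default 1.3 for benzoylecgonine, cocaine and MDMA).
#' @param noise_sd Log-scale SD of the day-to-day lognormal noise
#'   (default 0.25).
#' @param loq Named per-substance limits of quantification (ng/L).
#' @param population_range Site population range (log-uniform draw).
#' @param flow_per_capita_range Daily per-person wastewater production
#'   (L/person/day, uniform per site-day).
#' @param cocaine_bze_ratio Clean-day cocaine:benzoylecgonine load ratio
#'   (default 0.4; well below typical disposal-flag thresholds).
#' @param dumping_rate Probability that a site-year contains one
#'   direct-disposal day (cocaine parent multiplied by
#'   `dumping_magnitude`).
#' @param dumping_magnitude Multiplier applied to the cocaine load on a
#'   disposal day (default 5).
#' @param n_outlier_cities Number of cities given a persistent
#'   manufacturing-discharge signature (`outlier_substances` multiplied by
#'   `outlier_magnitude` in every monitored year).
#' @param outlier_magnitude,outlier_substances Outlier-city parameters.
#' @param n_core_cities Cities monitored in every year (default 26).
#' @param non_core_years_range Range of monitored-year counts for the
#'   remaining cities (default 1-4, biased toward later years).
#' @param seed Integer seed; the whole generation is deterministic in it.
#' @return A list of class `wbe_scenario`.
#' @export
scenario_config <- function(n_cities = 120L,
                            n_sites = 143L,
                            years = 2011:2017,
                            days_per_week = 7L,
                            substances = WBE_SUBSTANCES,
                            baseline_gm = default_baseline_gm(),
                            region_weights = c(
                              south_west_europe = 40, north_europe = 25,
                              east_central_europe = 35, non_europe = 20
                            ),
                            city_gsd = 3.2,
                            trend_multipliers = NULL,
                            weekend_uplift = NULL,
                            noise_sd = 0.25,
                            loq = NULL,
                            population_range = c(8e4, 1e6),
                            flow_per_capita_range = c(200, 400),
                            cocaine_bze_ratio = 0.4,
                            dumping_rate = 0.02,
                            dumping_magnitude = 5,
                            n_outlier_cities = 0L,
                            outlier_magnitude = 30,
                            outlier_substances = c("amphetamine", "mdma"),
                            n_core_cities = 26L,
                            non_core_years_range = c(1L, 4L),
                            seed = 1L) {
  if (is.null(trend_multipliers)) {
    trend_multipliers <- setNames(rep(1, length(substances)), substances)
  }
  if (is.null(weekend_uplift)) {
    weekend_uplift <- setNames(rep(1, length(substances)), substances)
    for (s in intersect(c("benzoylecgonine", "cocaine", "mdma"), substances)) {
      weekend_uplift[s] <- 1.3
    }
  }
  if (is.null(loq)) {
    loq <- setNames(rep(10, length(substances)), substances)
    if ("thc_cooh" %in% substances) loq["thc_cooh"] <- 20
  }
  cfg <- structure(
    list(
      n_cities = as.integer(n_cities), n_sites = as.integer(n_sites),
      years = as.integer(years), days_per_week = as.integer(days_per_week),
      substances = substances, baseline_gm = baseline_gm,
      region_weights = region_weights, city_gsd = city_gsd,
      trend_multipliers = trend_multipliers,
      weekend_uplift = weekend_uplift, noise_sd = noise_sd, loq = loq,
      population_range = population_range,
      flow_per_capita_range = flow_per_capita_range,
      cocaine_bze_ratio = cocaine_bze_ratio,
      dumping_rate = dumping_rate, dumping_magnitude = dumping_magnitude,
      n_outlier_cities = as.integer(n_outlier_cities),
      outlier_magnitude = outlier_magnitude,
      outlier_substances = outlier_substances,
      n_core_cities = as.integer(n_core_cities),
      non_core_years_range = as.integer(non_core_years_range),
      seed = as.integer(seed)
    ),
    class = "wbe_scenario"
  )
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_cities >= 1, "n_cities must be >= 1")
  chk(cfg$n_sites >= cfg$n_cities, "n_sites must be >= n_cities")
  chk(!is.unsorted(cfg$years), "years must be sorted")
  chk(cfg$days_per_week >= 1 && cfg$days_per_week <= 7,
    "days_per_week must be in 1..7"
  )
  chk(all(cfg$substances %in% WBE_SUBSTANCES), "unknown substance token")
  chk(all(cfg$baseline_gm > 0), "baseline geometric means must be > 0")
  chk(cfg$city_gsd >= 1, "city_gsd must be >= 1")
  chk(all(cfg$trend_multipliers > 0), "trend multipliers must be > 0")
  chk(all(cfg$weekend_uplift > 0), "weekend uplift must be > 0")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(all(cfg$loq > 0), "LOQ values must be > 0")
  chk(all(cfg$population_range > 0) && diff(cfg$population_range) >= 0,
    "population_range must be positive and ordered"
  )
  chk(all(cfg$flow_per_capita_range > 0) &&
    diff(cfg$flow_per_capita_range) >= 0,
  "flow_per_capita_range must be positive and ordered"
  )
  chk(cfg$cocaine_bze_ratio > 0, "cocaine_bze_ratio must be > 0")
  chk(cfg$dumping_rate >= 0 && cfg$dumping_rate <= 1,
    "dumping_rate must be in [0, 1]"
  )
  chk(cfg$dumping_magnitude > 0, "dumping_magnitude must be > 0")
  chk(cfg$n_outlier_cities >= 0 && cfg$n_outlier_cities <= cfg$n_cities,
    "n_outlier_cities must be in [0, n_cities]"
  )
  chk(cfg$outlier_magnitude > 0, "outlier_magnitude must be > 0")
  chk(cfg$n_core_cities >= 0 && cfg$n_core_cities <= cfg$n_cities,
    "n_core_cities must be <= n_cities"
  )
  if (length(problems)) {
    stop("invalid scenario config:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  invisible(cfg)
}

first_wednesday_of_march <- function(year) {
  d <- as.Date(sprintf("%d-03-01", year))
  offset <- (3 - as.POSIXlt(d)$wday) %% 7 # POSIXlt wday: 0 = Sunday
  d + offset
}

#' Generate a synthetic monitoring campaign with ground truth
#'
#' Draws city baseline loads lognormally within regions, applies annual
#' trend multipliers and day-of-week effects, adds daily lognormal noise
#' (shared between cocaine and benzoylecgonine, which originate from the
#' same consumption events), converts loads to influent concentrations via
#' the inverse of [daily_load()], censors concentrations below the LOQ,
#' and injects direct-disposal spikes and manufacturing-discharge outlier
#' cities. Fully deterministic under `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return List with `dataset` (a [wbe_dataset()]) and `truth`, a list of
#'   tibbles: `daily` (per site/date/substance true pre-noise load,
#'   realized load, censoring flag), `city_year` (true weekly-mean loads
#'   and back-calculated true doses), `trends` (per city/substance
#'   multiplier and direction), `dumping` (injected disposal days),
#'   `outliers` (injected outlier city-substance pairs), and `core_cities`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  validate_scenario(config)
  cfg <- config
  set.seed(cfg$seed)

  ## --- cities, regions, monitored years -------------------------------
  regions <- sample(
    names(cfg$region_weights), cfg$n_cities,
    replace = TRUE, prob = cfg$region_weights
  )
  cities <- sprintf("city_%03d", seq_len(cfg$n_cities))
  countries <- vapply(
    regions, function(r) sample(region_country_pool[[r]], 1L), ""
  )
  core <- sort(sample(cfg$n_cities, cfg$n_core_cities))
  city_years <- vector("list", cfg$n_cities)
  for (i in seq_len(cfg$n_cities)) {
    if (i %in% core || length(cfg$years) == 1L) {
      city_years[[i]] <- cfg$years
    } else {
      k <- sample(
        seq(cfg$non_core_years_range[1],
          min(cfg$non_core_years_range[2], length(cfg$years) - 1L)
        ), 1L
      )
      # participation grew over the campaign: favour later years
      city_years[[i]] <- sort(sample(
        cfg$years, k,
        prob = seq_along(cfg$years)
      ))
    }
  }

  ## --- sites ----------------------------------------------------------
  extra <- cfg$n_sites - cfg$n_cities
  second_site_city <- if (extra > 0) sort(sample(cfg$n_cities, extra)) else integer()
  site_city_idx <- c(seq_len(cfg$n_cities), second_site_city)
  n_sites <- length(site_city_idx)
  population <- exp(runif(
    n_sites, log(cfg$population_range[1]), log(cfg$population_range[2])
  ))
  multi <- site_city_idx %in% second_site_city
  coverage <- ifelse(multi, runif(n_sites, 0.35, 0.5), runif(n_sites, 0.7, 1))
  sites <- tibble::tibble(
    site_id = sprintf("wwtp_%03d", seq_len(n_sites)),
    city = cities[site_city_idx],
    country = countries[site_city_idx],
    region = regions[site_city_idx],
    population = round(population),
    city_coverage = round(coverage, 3)
  )

  ## --- per-city baselines and trends ----------------------------------
  subs <- cfg$substances
  gen_subs <- setdiff(subs, "cocaine")
  base <- matrix(NA_real_,
    nrow = cfg$n_cities, ncol = length(subs),
    dimnames = list(cities, subs)
  )
  for (s in gen_subs) {
    base[, s] <- rlnorm(
      cfg$n_cities,
      meanlog = log(cfg$baseline_gm[regions, s]),
      sdlog = log(cfg$city_gsd)
    )
  }
  if ("cocaine" %in% subs) {
    stopifnot("benzoylecgonine" %in% subs)
    base[, "cocaine"] <- cfg$cocaine_bze_ratio * base[, "benzoylecgonine"]
  }
  mult <- matrix(
    rep(cfg$trend_multipliers[subs], each = cfg$n_cities),
    nrow = cfg$n_cities, dimnames = list(cities, subs)
  )
  if ("cocaine" %in% subs) mult[, "cocaine"] <- mult[, "benzoylecgonine"]
  outlier_cities <- if (cfg$n_outlier_cities > 0) {
    sort(sample(cfg$n_cities, cfg$n_outlier_cities))
  } else {
    integer()
  }
  out_subs <- intersect(cfg$outlier_substances, subs)
  base_out <- base
  if (length(outlier_cities) && length(out_subs)) {
    base_out[outlier_cities, out_subs] <-
      base_out[outlier_cities, out_subs] * cfg$outlier_magnitude
  }

  ## --- site-day grid --------------------------------------------------
  sy <- dplyr::bind_rows(lapply(seq_len(n_sites), function(i) {
    tibble::tibble(
      site_idx = i, year = city_years[[site_city_idx[i]]]
    )
  }))
  day_grid <- dplyr::bind_rows(lapply(seq_len(nrow(sy)), function(i) {
    start <- first_wednesday_of_march(sy$year[i])
    tibble::tibble(
      site_idx = sy$site_idx[i], year = sy$year[i],
      date = start + seq_len(cfg$days_per_week) - 1L
    )
  }))
  n_days <- nrow(day_grid)
  day_grid$flow_pc <- runif(
    n_days, cfg$flow_per_capita_range[1], cfg$flow_per_capita_range[2]
  )
  wday <- as.POSIXlt(day_grid$date)$wday
  is_weekend <- wday %in% c(0L, 6L)

  ## --- daily loads per substance --------------------------------------
  eps <- matrix(1, nrow = n_days, ncol = length(subs),
    dimnames = list(NULL, subs)
  )
  for (s in gen_subs) {
    eps[, s] <- rlnorm(n_days, 0, cfg$noise_sd)
  }
  if ("cocaine" %in% subs) eps[, "cocaine"] <- eps[, "benzoylecgonine"]

  city_idx_day <- site_city_idx[day_grid$site_idx]
  year_pow <- day_grid$year - cfg$years[1]
  rows <- lapply(subs, function(s) {
    uplift <- ifelse(is_weekend, cfg$weekend_uplift[[s]], 1)
    true_load <- base_out[cbind(city_idx_day, match(s, subs))] *
      mult[cbind(city_idx_day, match(s, subs))]^year_pow * uplift
    tibble::tibble(
      site_idx = day_grid$site_idx,
      year = day_grid$year,
      date = day_grid$date,
      flow_pc = day_grid$flow_pc,
      substance = s,
      true_load = true_load,
      realized_load = true_load * eps[, s]
    )
  })
  daily <- dplyr::bind_rows(rows)

  ## --- dumping spikes on the cocaine parent ---------------------------
  dumping <- tibble::tibble(site_id = character(), date = as.Date(character()))
  if ("cocaine" %in% subs && cfg$dumping_rate > 0) {
    hit <- rbinom(nrow(sy), 1L, cfg$dumping_rate) == 1L
    if (any(hit)) {
      pick <- sy[hit, ]
      pick$day_offset <- sample.int(cfg$days_per_week, nrow(pick), replace = TRUE) - 1L
      pick$date <- first_wednesday_of_march(pick$year) + pick$day_offset
      key <- paste(daily$site_idx, daily$date, daily$substance)
      target <- paste(pick$site_idx, pick$date, "cocaine")
      idx <- match(target, key)
      daily$realized_load[idx] <- daily$realized_load[idx] * cfg$dumping_magnitude
      dumping <- tibble::tibble(
        site_id = sites$site_id[pick$site_idx], date = pick$date
      )
    }
  }

  ## --- measurements ---------------------------------------------------
  pop_day <- sites$population[daily$site_idx]
  flow <- pop_day * daily$flow_pc
  conc <- daily$realized_load * pop_day / (flow * 1e-3)
  loq <- unname(cfg$loq[daily$substance])
  censored <- conc < loq
  meas <- tibble::tibble(
    site_id = sites$site_id[daily$site_idx],
    date = daily$date,
    substance = daily$substance,
    concentration = ifelse(censored, NA_real_, conc),
    loq = loq,
    censored = censored,
    flow = flow
  )
  ds <- wbe_dataset(
    measurements = meas, catchments = sites,
    params = default_drug_params(), check = FALSE
  )

  ## --- ground truth ---------------------------------------------------
  truth_daily <- tibble::tibble(
    site_id = sites$site_id[daily$site_idx],
    city = sites$city[daily$site_idx],
    year = daily$year,
    date = daily$date,
    substance = daily$substance,
    true_load = daily$true_load,
    realized_load = daily$realized_load,
    censored = censored
  )
  # city-level true weekly mean: identical across a city's sites, so take
  # the per-date mean of one site's true loads
  city_year <- truth_daily |>
    dplyr::distinct(.data$city, .data$year, .data$substance, .data$date,
      .keep_all = TRUE
    ) |>
    dplyr::group_by(.data$city, .data$year, .data$substance) |>
    dplyr::summarise(true_mean_load = mean(.data$true_load), .groups = "drop")
  params <- ds$params
  dose_map <- setNames(
    lapply(params$substance, function(s) params_row(params, s)),
    params$substance
  )
  city_year$true_doses <- NA_real_
  for (s in intersect(DOSE_CHANNELS, unique(city_year$substance))) {
    i <- city_year$substance == s
    city_year$true_doses[i] <- dose_count(city_year$true_mean_load[i], dose_map[[s]])
  }
  combined <- city_year[city_year$substance %in% DOSE_CHANNELS, ] |>
    dplyr::group_by(.data$city, .data$year) |>
    dplyr::summarise(
      true_combined_doses = sum(.data$true_doses), .groups = "drop"
    )
  eps_dir <- 1e-9
  trends <- dplyr::bind_rows(lapply(subs, function(s) {
    tibble::tibble(
      city = cities, substance = s, multiplier = mult[, s],
      direction = ifelse(mult[, s] > 1 + eps_dir, "increase",
        ifelse(mult[, s] < 1 - eps_dir, "decrease", "none")
      )
    )
  }))
  outliers <- if (length(outlier_cities) && length(out_subs)) {
    expand.grid(
      city = cities[outlier_cities], substance = out_subs,
      stringsAsFactors = FALSE
    ) |> tibble::as_tibble()
  } else {
    tibble::tibble(city = character(), substance = character())
  }

  list(
    dataset = ds,
    truth = list(
      daily = truth_daily,
      city_year = city_year,
      combined = combined,
      trends = trends,
      dumping = dumping,
      outliers = outliers,
      core_cities = sort(cities[core])
    )
  )
}

#' Fixed benchmark scenarios with ground truth
#'
#' Generates the standard test scenarios used throughout the package's
#' validation: a stationary null (for trend-rule calibration), +10%/yr and
#' -10%/yr trends, heavy censoring (LOQ at the median concentration, so
#' about half the days fall below it), a disposal-rich scenario, and a
#' manufacturing-discharge ("Eindhoven-like") outlier city.
#'
#' @param seed Integer master seed; per-scenario seeds are derived from it.
#' @return Named list of `generate_scenario()` results.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6L)
  list(
    null = generate_scenario(trend_scenario_config(1.0, seeds[1])),
    increase = generate_scenario(trend_scenario_config(1.1, seeds[2])),
    decrease = generate_scenario(trend_scenario_config(0.9, seeds[3])),
    heavy_censoring = generate_scenario(censoring_scenario_config(seeds[4])),
    dumping_rich = generate_scenario(scenario_config(
      n_cities = 20L, n_sites = 20L, n_core_cities = 20L,
      dumping_rate = 0.3,
      loq = setNames(rep(1e-6, 6), WBE_SUBSTANCES),
      seed = seeds[5]
    )),
    eindhoven_like = generate_scenario(scenario_config(
      n_cities = 12L, n_sites = 12L, n_core_cities = 12L,
      n_outlier_cities = 1L, outlier_magnitude = 30,
      # one region and moderate spread: flags isolate the injected discharge
      region_weights = c(south_west_europe = 1),
      baseline_gm = default_baseline_gm()["south_west_europe", , drop = FALSE],
      city_gsd = 1.8,
      dumping_rate = 0,
      loq = setNames(rep(1e-6, 6), WBE_SUBSTANCES),
      seed = seeds[6]
    ))
  )
}

#' Scenario configurations for the trend and censoring benchmarks
#'
#' `trend_scenario_config()` builds a 26-core-city, 7-year scenario with a
#' common annual multiplier on every substance, negligible censoring and
#' no disposal events — the setting used to calibrate the trend rule.
#' `censoring_scenario_config()` builds the heavy-censoring scenario: one
#' region, identical city baselines, fixed per-capita flow and the LOQ at
#' the median concentration, so each sampling day is censored with
#' probability one half independently.
#'
#' @param multiplier Annual trend multiplier applied to all substances.
#' @param seed Integer seed.
#' @return A [scenario_config()].
#' @export
trend_scenario_config <- function(multiplier = 1.0, seed = 1L) {
  scenario_config(
    n_cities = 26L, n_sites = 26L, n_core_cities = 26L,
    trend_multipliers = setNames(
      rep(multiplier, length(WBE_SUBSTANCES)), WBE_SUBSTANCES
    ),
    dumping_rate = 0,
    loq = setNames(rep(1e-6, length(WBE_SUBSTANCES)), WBE_SUBSTANCES),
    seed = seed
  )
}

#' @rdname trend_scenario_config
#' @export
censoring_scenario_config <- function(seed = 1L) {
  heavy_gm <- default_baseline_gm()["north_europe", , drop = FALSE]
  heavy_loq <- heavy_gm[1, c(
    "benzoylecgonine", "amphetamine", "methamphetamine", "mdma", "thc_cooh"
  )] / 0.3
  heavy_loq <- c(heavy_loq,
    cocaine = unname(heavy_loq["benzoylecgonine"]) * 0.4
  )
  scenario_config(
    n_cities = 20L, n_sites = 20L, n_core_cities = 20L,
    baseline_gm = heavy_gm,
    region_weights = c(north_europe = 1),
    city_gsd = 1, noise_sd = 0.3,
    weekend_uplift = setNames(rep(1, 6), WBE_SUBSTANCES),
    flow_per_capita_range = c(300, 300),
    loq = heavy_loq, dumping_rate = 0,
    seed = seed
  )
}
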