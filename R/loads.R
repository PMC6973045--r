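#' Population-normalized daily mass load
#'
#' Converts an influent concentration to the daily residue mass excreted per
#' 1000 inhabitants: concentration (ng/L) times daily flow (L/day) gives
#' ng/day; dividing by the population served and rescaling to mg per 1000
#' people yields the combined factor `1e-3 / population`.
#'
#' @param concentration Concentration in ng/L (>= 0). Vectorised.
#' @param flow Daily wastewater flow in L/day (> 0).
#' @param population Catchment population served (> 0).
#' @return Load in mg/1000 people/day.
#' @export
#' @examples
#' daily_load(1000, 1e7, 1e5) # 100 mg/1000 people/day
daily_load <- function(concentration, flow, population) {
  if (any(is.na(flow)) || any(flow <= 0)) {
    stop("flow must be > 0", call. = FALSE)
  }
  if (any(is.na(population)) || any(population <= 0)) {
    stop("population must be > 0", call. = FALSE)
  }
  if (any(!is.na(concentration) & concentration < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  concentration * flow * 1e-3 / population
}

#' Apply the below-LOQ policy to one sampling week
#'
#' A monitoring week is dropped entirely when every day is censored
#' (all concentrations < LOQ); otherwise censored days are substituted with
#' 0.5 x LOQ and flagged as imputed, and uncensored days pass through.
#'
#' @param week Tibble of measurements for one site, substance and sampling
#'   week (1-7 rows) with columns `date`, `concentration`, `loq`,
#'   `censored`, `flow`.
#' @param population Catchment population of the site.
#' @return List with elements `loads` (tibble `date`, `load`, `imputed`;
#'   zero rows when the week is excluded) and `included` (logical).
#' @export
apply_loq_policy <- function(week, population) {
  if (NROW(week) == 0L) {
    stop("apply_loq_policy: empty week", call. = FALSE)
  }
  if (all(week$censored)) {
    return(list(
      loads = tibble::tibble(
        date = as.Date(character()), load = numeric(), imputed = logical()
      ),
      included = FALSE
    ))
  }
  conc <- ifelse(week$censored, 0.5 * week$loq, week$concentration)
  list(
    loads = tibble::tibble(
      date = week$date,
      load = daily_load(conc, week$flow, population),
      imputed = week$censored
    ),
    included = TRUE
  )
}

year_of <- function(date) as.integer(format(date, "%Y"))

#' Compute daily loads for a whole dataset
#'
#' Joins measurements with catchment populations, averages duplicate
#' (site, date, substance) rows with a warning, groups samples into
#' site/substance/year campaign weeks and applies [apply_loq_policy()] to
#' each.
#'
#' @param ds A [wbe_dataset()].
#' @return List with `daily` (tibble `site_id`, `city`, `year`, `date`,
#'   `substance`, `load`, `imputed`) and `excluded_weeks` (tibble
#'   `site_id`, `city`, `year`, `substance`, `n_days`, `reason`).
#' @export
compute_daily_loads <- function(ds) {
  m <- dplyr::inner_join(
    ds$measurements,
    dplyr::select(ds$catchments, "site_id", "city", "population"),
    by = "site_id"
  )
  key <- paste(m$site_id, m$date, m$substance, sep = "|")
  if (anyDuplicated(key)) {
    warning(
      sum(duplicated(key)),
      " duplicate (site_id, date, substance) row(s) averaged",
      call. = FALSE
    )
    m <- m |>
      dplyr::group_by(
        .data$site_id, .data$city, .data$date, .data$substance,
        .data$population
      ) |>
      dplyr::summarise(
        concentration = mean(.data$concentration),
        loq = mean(.data$loq),
        censored = all(.data$censored),
        flow = mean(.data$flow),
        .groups = "drop"
      )
  }
  m$year <- year_of(m$date)

  daily <- list()
  excluded <- list()
  for (grp in split(
    m, list(m$site_id, m$substance, m$year), drop = TRUE, sep = "\r"
  )) {
    res <- apply_loq_policy(grp, grp$population[1])
    if (res$included) {
      daily[[length(daily) + 1L]] <- tibble::tibble(
        site_id = grp$site_id[1], city = grp$city[1], year = grp$year[1],
        date = res$loads$date, substance = grp$substance[1],
        load = res$loads$load, imputed = res$loads$imputed
      )
    } else {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        site_id = grp$site_id[1], city = grp$city[1], year = grp$year[1],
        substance = grp$substance[1], n_days = nrow(grp),
        reason = "all_below_loq"
      )
    }
  }
  daily <- if (length(daily)) {
    dplyr::arrange(
      dplyr::bind_rows(daily),
      .data$site_id, .data$substance, .data$date
    )
  } else {
    tibble::tibble(
      site_id = character(), city = character(), year = integer(),
      date = as.Date(character()), substance = character(),
      load = numeric(), imputed = logical()
    )
  }
  excluded <- if (length(excluded)) {
    dplyr::arrange(
      dplyr::bind_rows(excluded), .data$site_id, .data$substance, .data$year
    )
  } else {
    tibble::tibble(
      site_id = character(), city = character(), year = integer(),
      substance = character(), n_days = integer(), reason = character()
    )
  }
  list(daily = daily, excluded_weeks = excluded)
}

#' Summarise one campaign week of daily loads
#'
#' @param loads Numeric vector of daily loads (mg/1000 people/day) from one
#'   site, substance and year; 1-7 values.
#' @return List with `mean`, `sd` (sample SD, n-1 denominator; 0 when a
#'   single day is available), `min`, `max`, `n_days`.
#' @export
weekly_summary <- function(loads) {
  if (length(loads) == 0L) {
    stop("weekly_summary: empty input", call. = FALSE)
  }
  list(
    mean = mean(loads),
    sd = if (length(loads) > 1L) sd(loads) else 0,
    min = min(loads),
    max = max(loads),
    n_days = length(loads)
  )
}

#' Weekly load summaries for a whole dataset
#'
#' One row per site, substance and year: summary statistics over the
#' campaign days for included weeks, and a stub row carrying the exclusion
#' reason for weeks dropped by the all-below-LOQ rule.
#'
#' @param ds A [wbe_dataset()].
#' @param daily Optional precomputed result of [compute_daily_loads()].
#' @return Tibble `site_id`, `city`, `year`, `substance`, `mean`, `sd`,
#'   `min`, `max`, `n_days`, `included`, `exclusion_reason` (units
#'   mg/1000 people/day).
#' @export
weekly_summaries <- function(ds, daily = NULL) {
  if (is.null(daily)) daily <- compute_daily_loads(ds)
  sums <- daily$daily |>
    dplyr::group_by(.data$site_id, .data$city, .data$year, .data$substance) |>
    dplyr::summarise(
      mean = mean(.data$load),
      sd = if (dplyr::n() > 1L) sd(.data$load) else 0,
      min = min(.data$load),
      max = max(.data$load),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(included = TRUE, exclusion_reason = "")
  excl <- daily$excluded_weeks |>
    dplyr::transmute(
      .data$site_id, .data$city, .data$year, .data$substance,
      mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
      n_days = .data$n_days, included = FALSE,
      exclusion_reason = .data$reason
    )
  dplyr::arrange(
    dplyr::bind_rows(sums, excl),
    .data$city, .data$site_id, .data$substance, .data$year
  )
}

#' City-level load from site summaries
#'
#' Cities served by several treatment plants are aggregated as the
#' population-weighted mean of the included site weekly means.
#'
#' @param site_means Numeric vector of site weekly-mean loads.
#' @param populations Populations served by the corresponding sites.
#' @return Weighted mean load, or `NA_real_` ("no city value") when no site
#'   is available.
#' @export
city_load <- function(site_means, populations) {
  keep <- !is.na(site_means)
  if (!any(keep)) {
    return(NA_real_)
  }
  weighted.mean(site_means[keep], populations[keep])
}

#' City/year/substance load table
#'
#' Aggregates weekly site summaries to one load per city, year and
#' substance (population-weighted across a city's treatment plants). A city
#' whose sites were all excluded in a year keeps a row with `included =
#' FALSE` and `load = NA`.
#'
#' @param ds A [wbe_dataset()].
#' @param summaries Optional precomputed [weekly_summaries()] table.
#' @return Tibble `city`, `year`, `substance`, `load`, `n_sites`,
#'   `included`.
#' @export
city_year_loads <- function(ds, summaries = NULL) {
  if (is.null(summaries)) summaries <- weekly_summaries(ds)
  pops <- setNames(ds$catchments$population, ds$catchments$site_id)
  summaries |>
    dplyr::group_by(.data$city, .data$year, .data$substance) |>
    dplyr::summarise(
      load = city_load(.data$mean, pops[.data$site_id]),
      n_sites = sum(.data$included),
      included = any(.data$included),
      .groups = "drop"
    )
}
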