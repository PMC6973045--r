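#' Classify a multi-year load trend
#'
#' Fits ordinary least squares of annual mean load on calendar year and
#' tests the slope against zero (two-sided t-test). A trend is called
#' `increase` or `decrease` when P < `alpha` (default 0.2) and at least
#' three annual observations are available; exactly two observations give
#' `no_trend`, fewer than two give `insufficient`. A perfectly flat series
#' (zero slope, zero residual) is `no_trend`; P exactly equal to `alpha`
#' is treated conservatively as `no_trend`.
#'
#' @param years Integer vector of distinct calendar years.
#' @param values Annual mean loads (mg/1000 people/day), same length.
#' @param alpha Significance level for the slope test (default 0.2).
#' @return List of class `wbe_trend`: `slope` (mg/1000 people/day per
#'   year), `p_value` (`NA` when undefined), `call` (one of `"increase"`,
#'   `"decrease"`, `"no_trend"`, `"insufficient"`), `n_years`.
#' @export
#' @examples
#' classify_trend(2014:2017, c(10, 20, 30, 40))$call # "increase"
classify_trend <- function(years, values, alpha = 0.2) {
  stopifnot(length(years) == length(values), alpha > 0, alpha < 1)
  keep <- !is.na(values)
  years <- years[keep]
  values <- values[keep]
  if (anyDuplicated(years)) {
    stop("classify_trend: duplicate years", call. = FALSE)
  }
  n <- length(years)
  out <- function(slope, p, call) {
    structure(
      list(slope = slope, p_value = p, call = call, n_years = n),
      class = "wbe_trend"
    )
  }
  if (n < 2L) {
    return(out(NA_real_, NA_real_, "insufficient"))
  }
  fit <- stats::lm(values ~ years)
  slope <- unname(stats::coef(fit)[2])
  if (n == 2L) {
    return(out(slope, NA_real_, "no_trend"))
  }
  # vcov warns on an essentially perfect fit; that case is legitimate here
  # (zero residual, P ~ 0) and handled by the call logic below
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[2])
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df = n - 2L)
  if (is.nan(p) || is.na(p) || p >= alpha || slope == 0) {
    return(out(slope, p, "no_trend"))
  }
  out(slope, p, if (slope > 0) "increase" else "decrease")
}

#' @export
print.wbe_trend <- function(x, ...) {
  cat(sprintf(
    "<wbe_trend> %s (slope %.4g, P %s, %d year(s))\n",
    x$call, x$slope,
    if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
    x$n_years
  ))
  invisible(x)
}

#' Trend calls for every city and substance within periods
#'
#' @param ds A [wbe_dataset()].
#' @param periods List of 2-vectors `c(first_year, last_year)`;
#'   default the reporting periods 2011-2013 and 2014-2017.
#' @param alpha Significance level passed to [classify_trend()].
#' @param city_loads Optional precomputed [city_year_loads()] table.
#' @return Tibble `city`, `substance`, `period`, `slope`, `p_value`,
#'   `call`, `n_years`.
#' @export
trend_calls <- function(ds, periods = list(c(2011, 2013), c(2014, 2017)),
                        alpha = 0.2, city_loads = NULL) {
  if (is.null(city_loads)) city_loads <- city_year_loads(ds)
  inc <- city_loads[city_loads$included & !is.na(city_loads$load), ]
  out <- list()
  for (period in periods) {
    label <- paste0(period[1], "-", period[2])
    sub <- inc[inc$year >= period[1] & inc$year <= period[2], ]
    if (nrow(sub) == 0L) next
    out[[label]] <- sub |>
      dplyr::group_by(.data$city, .data$substance) |>
      dplyr::group_map(function(g, key) {
        tc <- classify_trend(g$year, g$load, alpha = alpha)
        tibble::tibble(
          city = key$city, substance = key$substance, period = label,
          slope = tc$slope, p_value = tc$p_value, call = tc$call,
          n_years = tc$n_years
        )
      }) |>
      dplyr::bind_rows()
  }
  dplyr::bind_rows(out)
}

#' Mean annual load within a reporting period
#'
#' @param years,values Annual means as in [classify_trend()].
#' @param period 2-vector `c(first_year, last_year)`.
#' @return Unweighted mean of the annual means falling inside the period,
#'   or `NA_real_` ("no value") when none do.
#' @export
period_mean <- function(years, values, period) {
  keep <- years >= period[1] & years <= period[2] & !is.na(values)
  if (!any(keep)) {
    return(NA_real_)
  }
  mean(values[keep])
}

#' Select the core cities monitored in many years
#'
#' Core cities are those with included weekly summaries in at least
#' `min_years` distinct years (for any substance unless one is given);
#' they anchor the temporal-trend assessment.
#'
#' @param ds A [wbe_dataset()].
#' @param min_years Minimum number of distinct monitored years (default 5).
#' @param substance Optional substance filter.
#' @param summaries Optional precomputed [weekly_summaries()] table.
#' @return Character vector of city names, sorted.
#' @export
core_city_selection <- function(ds, min_years = 5L, substance = NULL,
                                summaries = NULL) {
  stopifnot(min_years >= 1L)
  if (is.null(summaries)) summaries <- weekly_summaries(ds)
  s <- summaries[summaries$included, ]
  if (!is.null(substance)) s <- s[s$substance == substance, ]
  tab <- s |>
    dplyr::group_by(.data$city) |>
    dplyr::summarise(n_years = dplyr::n_distinct(.data$year))
  sort(tab$city[tab$n_years >= min_years])
}

apply_exclusions <- function(city_loads, exclusions, catchments = NULL) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(city_loads)
  }
  ex <- exclusions
  if (!is.null(catchments) && any(ex$scope == "site")) {
    # map excluded sites to their city so city-level tables can honour them
    map <- setNames(catchments$city, catchments$site_id)
    ex$name[ex$scope == "site"] <- map[ex$name[ex$scope == "site"]]
  }
  drop <- rep(FALSE, nrow(city_loads))
  for (i in seq_len(nrow(ex))) {
    hit <- city_loads$city == ex$name[i] &
      (ex$substance[i] == "ALL" | city_loads$substance == ex$substance[i])
    drop <- drop | hit
  }
  city_loads[!drop, , drop = FALSE]
}

#' Overall mean load across cities
#'
#' Computes the two overall-mean variants for one year and substance:
#' the unweighted mean over all eligible cities, or over the core cities
#' with `min_years` or more monitored years. Cities on the manual
#' exclusion list for the substance (or for `ALL`) are dropped first;
#' all-below-LOQ weeks are already excluded at the weekly stage.
#'
#' @param ds A [wbe_dataset()].
#' @param year Calendar year.
#' @param substance Substance token.
#' @param variant `"all_cities"` or `"core_cities"`.
#' @param min_years Core-city threshold (default 5).
#' @param city_loads Optional precomputed [city_year_loads()] table.
#' @param core_cities Optional precomputed core-city vector (avoids
#'   re-deriving it on every call).
#' @return List `mean` (mg/1000 people/day; `NA_real_` when no eligible
#'   city) and `n_cities`.
#' @export
overall_mean <- function(ds, year, substance,
                         variant = c("all_cities", "core_cities"),
                         min_years = 5L, city_loads = NULL,
                         core_cities = NULL) {
  variant <- match.arg(variant)
  if (is.null(city_loads)) city_loads <- city_year_loads(ds)
  cl <- apply_exclusions(city_loads, ds$exclusions, ds$catchments)
  cl <- cl[
    cl$year == year & cl$substance == substance &
      cl$included & !is.na(cl$load),
  ]
  if (variant == "core_cities") {
    core <- if (is.null(core_cities)) {
      core_city_selection(ds, min_years = min_years)
    } else {
      core_cities
    }
    cl <- cl[cl$city %in% core, ]
  }
  if (nrow(cl) == 0L) {
    return(list(mean = NA_real_, n_cities = 0L))
  }
  list(mean = mean(cl$load), n_cities = nrow(cl))
}

#' Overall-mean table for all years and substances
#'
#' @param ds A [wbe_dataset()].
#' @param variants Overall-mean variants to compute.
#' @param min_years Core-city threshold.
#' @param city_loads Optional precomputed [city_year_loads()] table.
#' @return Tibble `year`, `substance`, `variant`, `mean`, `n_cities`
#'   (units mg/1000 people/day).
#' @export
overall_means_table <- function(ds, variants = c("all_cities", "core_cities"),
                                min_years = 5L, city_loads = NULL) {
  if (is.null(city_loads)) city_loads <- city_year_loads(ds)
  core <- if ("core_cities" %in% variants) {
    inc <- city_loads[city_loads$included, ]
    tab <- inc |>
      dplyr::group_by(.data$city) |>
      dplyr::summarise(n_years = dplyr::n_distinct(.data$year))
    sort(tab$city[tab$n_years >= min_years])
  } else {
    character()
  }
  years <- sort(unique(city_loads$year))
  subs <- sort(unique(city_loads$substance))
  grid <- expand.grid(
    year = years, substance = subs, variant = variants,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    om <- overall_mean(
      ds, grid$year[i], grid$substance[i],
      variant = grid$variant[i], min_years = min_years,
      city_loads = city_loads, core_cities = core
    )
    tibble::tibble(
      year = grid$year[i], substance = grid$substance[i],
      variant = grid$variant[i], mean = om$mean, n_cities = om$n_cities
    )
  })
  dplyr::bind_rows(rows)
}
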