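#' Back-calculate consumed parent-drug mass from a residue load
#'
#' The residue load is scaled by the parent/residue molar-mass ratio and
#' divided by the excretion fraction (the share of a consumed parent dose
#' excreted as the measured residue).
#'
#' @param load Residue load in mg/1000 people/day (>= 0). Vectorised.
#' @param params A one-row list/tibble with `excretion_fraction` and
#'   `molar_mass_ratio` (e.g. one row of [default_drug_params()]).
#' @return Consumed parent mass in mg/1000 people/day.
#' @export
#' @examples
#' p <- list(excretion_fraction = 0.29, molar_mass_ratio = 1.0485)
#' consumption_mass(300, p) # ~1084.66 mg cocaine/1000 people/day
consumption_mass <- function(load, params) {
  stopifnot(
    params$excretion_fraction > 0, params$excretion_fraction <= 1,
    params$molar_mass_ratio > 0
  )
  if (any(load < 0, na.rm = TRUE)) stop("load must be >= 0", call. = FALSE)
  load * params$molar_mass_ratio / params$excretion_fraction
}

#' Back-calculate average daily doses from a residue load
#'
#' @inheritParams consumption_mass
#' @param params As in [consumption_mass()], additionally with `dose_mg`
#'   (mg of pure parent per average dose).
#' @return Doses per 1000 people per day.
#' @export
dose_count <- function(load, params) {
  stopifnot(params$dose_mg > 0)
  consumption_mass(load, params) / params$dose_mg
}

params_row <- function(params, substance) {
  row <- params[params$substance == substance, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no back-calculation parameters for substance: ", substance,
      call. = FALSE
    )
  }
  row
}

#' Combined stimulant doses for one city-year
#'
#' Sums the back-calculated doses of the four stimulant channels: cocaine
#' (from its metabolite benzoylecgonine), amphetamine, methamphetamine and
#' MDMA. Cannabis (THC-COOH) never contributes; a THC-COOH entry in
#' `city_loads` is silently ignored. Channels without a load contribute 0
#' with a warning.
#'
#' @param city_loads Named numeric vector or list mapping substance tokens
#'   to weekly-mean loads (mg/1000 people/day).
#' @param params Parameter table as from [default_drug_params()].
#' @return Combined doses per 1000 people per day.
#' @export
#' @examples
#' combined_doses(c(benzoylecgonine = 300), default_drug_params())
combined_doses <- function(city_loads, params = default_drug_params()) {
  loads <- unlist(city_loads)
  total <- 0
  for (chan in DOSE_CHANNELS) {
    if (!chan %in% names(loads) || is.na(loads[[chan]])) {
      warning("no load for dose channel '", chan, "'; contributing 0 doses",
        call. = FALSE
      )
      next
    }
    total <- total + dose_count(loads[[chan]], params_row(params, chan))
  }
  total
}

#' Per-city dose table
#'
#' Back-calculates per-substance consumption and doses plus the combined
#' stimulant dose for every city and year with at least one included
#' weekly summary.
#'
#' @param ds A [wbe_dataset()].
#' @param city_loads Optional precomputed [city_year_loads()] table.
#' @param quiet Suppress missing-channel warnings when summing combined
#'   doses (default `TRUE`: absent substances are common in real campaigns
#'   and are reported once in the returned table instead).
#' @return Tibble `city`, `year`, `substance` (a token or `"combined"`),
#'   `consumption_mg_1000p_d`, `doses_1000p_d`, `n_channels` (combined rows
#'   only: channels with data).
#' @export
city_dose_table <- function(ds, city_loads = NULL, quiet = TRUE) {
  if (is.null(city_loads)) city_loads <- city_year_loads(ds)
  params <- ds$params
  inc <- city_loads[city_loads$included & !is.na(city_loads$load), ]
  per_sub <- inc[inc$substance %in% params$substance, ]
  rows <- lapply(seq_len(nrow(per_sub)), function(i) {
    p <- params_row(params, per_sub$substance[i])
    tibble::tibble(
      city = per_sub$city[i], year = per_sub$year[i],
      substance = per_sub$substance[i],
      consumption_mg_1000p_d = consumption_mass(per_sub$load[i], p),
      doses_1000p_d = dose_count(per_sub$load[i], p),
      n_channels = NA_integer_
    )
  })
  combined <- inc |>
    dplyr::group_by(.data$city, .data$year) |>
    dplyr::group_map(function(g, key) {
      lds <- setNames(g$load, g$substance)
      present <- sum(DOSE_CHANNELS %in% names(lds))
      doses <- if (quiet) {
        suppressWarnings(combined_doses(lds, params))
      } else {
        combined_doses(lds, params)
      }
      tibble::tibble(
        city = key$city, year = key$year, substance = "combined",
        consumption_mg_1000p_d = NA_real_,
        doses_1000p_d = doses,
        n_channels = present
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(
    dplyr::bind_rows(dplyr::bind_rows(rows), combined),
    .data$city, .data$year, .data$substance
  )
}

#' Period-average combined doses for a city
#'
#' Unweighted mean over the available years of a city's combined doses;
#' years without an included value are skipped.
#'
#' @param city City name.
#' @param years Years of the reporting period (e.g. `2011:2017`).
#' @param dose_table Result of [city_dose_table()].
#' @return Doses per 1000 people per day, or `NA_real_` ("no value") when
#'   no year of the period has data.
#' @export
period_average_doses <- function(city, years, dose_table) {
  rows <- dose_table[
    dose_table$city == city & dose_table$substance == "combined" &
      dose_table$year %in% years & !is.na(dose_table$doses_1000p_d),
  ]
  if (nrow(rows) == 0L) {
    return(NA_real_)
  }
  mean(rows$doses_1000p_d)
}
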