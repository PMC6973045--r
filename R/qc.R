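#' Flag a cocaine disposal (dumping) event
#'
#' Unconsumed cocaine dumped into a sewer arrives unmetabolised, so the
#' cocaine:benzoylecgonine load ratio rises well above the physiological
#' range. A day is flagged when the ratio exceeds `threshold`; a positive
#' cocaine load with zero benzoylecgonine is flagged with an infinite
#' metric.
#'
#' @param cocaine_load,bze_load Daily loads (mg/1000 people/day, >= 0).
#' @param threshold Ratio above which a day is flagged (default 0.75; the
#'   physiological ratio is well below 1 because most cocaine is excreted
#'   as metabolites). A documented heuristic, not a published constant.
#' @return List `flagged` (logical) and `metric` (the ratio; `Inf` in the
#'   degenerate zero-metabolite case, `NA` when both loads are zero).
#' @export
#' @examples
#' flag_dumping(900, 300) # ratio 3: flagged
flag_dumping <- function(cocaine_load, bze_load, threshold = 0.75) {
  stopifnot(cocaine_load >= 0, bze_load >= 0, threshold > 0)
  if (cocaine_load == 0) {
    return(list(flagged = FALSE, metric = if (bze_load == 0) NA_real_ else 0))
  }
  if (bze_load == 0) {
    return(list(flagged = TRUE, metric = Inf))
  }
  metric <- cocaine_load / bze_load
  list(flagged = metric > threshold, metric = metric)
}

#' Scan daily loads for cocaine disposal days
#'
#' Pairs cocaine and benzoylecgonine loads per site and day and applies
#' [flag_dumping()] to each pair.
#'
#' @param daily Daily-load tibble from [compute_daily_loads()]`$daily`.
#' @param threshold As in [flag_dumping()].
#' @return Tibble `site_id`, `date`, `kind` (`"dumping_cocaine"`),
#'   `metric`, `threshold`; zero rows when nothing is flagged.
#' @export
flag_dumping_days <- function(daily, threshold = 0.75) {
  coc <- daily[daily$substance == "cocaine", c("site_id", "date", "load")]
  bze <- daily[daily$substance == "benzoylecgonine", c("site_id", "date", "load")]
  pair <- dplyr::inner_join(
    coc, bze,
    by = c("site_id", "date"), suffix = c("_coc", "_bze")
  )
  if (nrow(pair) == 0L) {
    return(tibble::tibble(
      site_id = character(), date = as.Date(character()),
      kind = character(), metric = numeric(), threshold = numeric()
    ))
  }
  res <- lapply(seq_len(nrow(pair)), function(i) {
    f <- flag_dumping(pair$load_coc[i], pair$load_bze[i], threshold)
    if (!f$flagged) {
      return(NULL)
    }
    tibble::tibble(
      site_id = pair$site_id[i], date = pair$date[i],
      kind = "dumping_cocaine", metric = f$metric, threshold = threshold
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      site_id = character(), date = as.Date(character()),
      kind = character(), metric = numeric(), threshold = numeric()
    ))
  }
  out
}

#' Correct amphetamine loads for methamphetamine metabolism
#'
#' A few percent of a methamphetamine dose is excreted as amphetamine, so
#' in high-methamphetamine catchments part of the amphetamine load is not
#' amphetamine use. The metabolic contribution is estimated as
#' `meth_load * e_amph_from_meth / e_meth` and subtracted, floored at zero.
#' This correction is opt-in: the headline pipeline reports uncorrected
#' amphetamine loads.
#'
#' @param amph_load,meth_load Loads in mg/1000 people/day (>= 0).
#' @param e_amph_from_meth Fraction of a methamphetamine dose excreted as
#'   amphetamine; default 0.055, midpoint of the reported 4-7% range.
#' @param e_meth Excretion fraction of methamphetamine itself (parent in
#'   urine); default taken from the parameter table in use.
#' @return Corrected amphetamine load in `[0, amph_load]`.
#' @export
#' @examples
#' correct_amphetamine(200, 1000, 0.055, 0.43) # ~72.09
correct_amphetamine <- function(amph_load, meth_load,
                                e_amph_from_meth = 0.055, e_meth = 0.43) {
  stopifnot(
    amph_load >= 0, meth_load >= 0,
    e_amph_from_meth >= 0, e_meth > e_amph_from_meth, e_meth <= 1
  )
  pmax(0, amph_load - meth_load * e_amph_from_meth / e_meth)
}

#' Correct a load for in-sewer transformation losses
#'
#' Biomarker degradation between excretion and the treatment-plant intake
#' underestimates the true load; for benzoylecgonine, methamphetamine and
#' MDMA the loss is below 10% at typical hydraulic residence times
#' (< 12 h), so correction factors above 0.10 are rejected for those
#' substances. Amphetamine can transform more strongly, but the loss is
#' site-specific, so larger factors are accepted with a warning.
#'
#' @param load Load in mg/1000 people/day.
#' @param substance Substance token.
#' @param enabled Apply the correction (default `FALSE`: identity).
#' @param factor Fractional in-sewer loss in `[0, 1)`; the corrected load
#'   is `load / (1 - factor)`.
#' @return Adjusted load.
#' @export
in_sewer_correction <- function(load, substance, enabled = FALSE,
                                factor = 0) {
  if (factor >= 1 || factor < 0) {
    stop("in-sewer correction factor must be in [0, 1)", call. = FALSE)
  }
  if (!enabled) {
    return(load)
  }
  if (substance %in% c("benzoylecgonine", "methamphetamine", "mdma") &&
    factor > 0.10) {
    stop(
      "in-sewer losses for ", substance,
      " are below 10% at typical residence times; factor ", factor,
      " rejected",
      call. = FALSE
    )
  }
  if (substance == "amphetamine" && factor > 0.10) {
    warning(
      "amphetamine in-sewer transformation is site-specific; ",
      "a global factor of ", factor, " may misstate loads",
      call. = FALSE
    )
  }
  load / (1 - factor)
}

#' Screen for outlier city-years
#'
#' Flags city-years whose annual mean load is abnormally high or low
#' relative to the cross-city median for the same substance and year
#' (above `k` times the median or below median/`k`). Flags are proposals
#' for the manual exclusion list, never applied automatically: abnormal
#' values such as manufacturing-waste discharges were excluded from
#' published overall means by expert judgement, which a fixed rule can
#' only approximate.
#'
#' @param city_loads A [city_year_loads()] table.
#' @param k Median multiplier (> 1; default 10).
#' @return Tibble `city`, `year`, `substance`, `kind`
#'   (`"outlier_city_year"`), `metric` (load / median), `threshold` (`k`).
#' @export
screen_outlier_city <- function(city_loads, k = 10) {
  stopifnot(k > 1)
  inc <- city_loads[city_loads$included & !is.na(city_loads$load), ]
  out <- inc |>
    dplyr::group_by(.data$year, .data$substance) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 3L) {
        return(NULL)
      }
      med <- median(g$load)
      if (med <= 0) {
        return(NULL)
      }
      ratio <- g$load / med
      hit <- ratio > k | ratio < 1 / k
      if (!any(hit)) {
        return(NULL)
      }
      tibble::tibble(
        city = g$city[hit], year = key$year, substance = key$substance,
        kind = "outlier_city_year", metric = ratio[hit], threshold = k
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      city = character(), year = integer(), substance = character(),
      kind = character(), metric = numeric(), threshold = numeric()
    ))
  }
  dplyr::arrange(out, .data$substance, .data$year, .data$city)
}
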