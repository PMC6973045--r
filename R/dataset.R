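#' Construct a WBE dataset
#'
#' Bundles the three core tables of a monitoring campaign — per-sample
#' measurements, catchment metadata and per-substance back-calculation
#' parameters — plus an optional manual exclusion list, into a single
#' validated object.
#'
#' @param measurements Tibble with columns `site_id`, `date` (Date),
#'   `substance`, `concentration` (ng/L; `NA` allowed when censored),
#'   `loq` (ng/L, > 0), `censored` (logical), `flow` (L/day, > 0).
#' @param catchments Tibble with columns `site_id`, `city`, `country`
#'   (ISO 3166-1 alpha-2), `region`, `population` (> 0), `city_coverage`
#'   (fraction in (0, 1]).
#' @param params Tibble with columns `substance`, `excretion_fraction`
#'   (mass fraction of the consumed parent excreted as the measured residue,
#'   in (0, 1]), `molar_mass_ratio` (parent molar mass / residue molar mass,
#'   > 0; 1 when the parent itself is measured), `dose_mg` (mg of pure
#'   parent per average dose, > 0). Defaults to [default_drug_params()].
#' @param exclusions Tibble with columns `scope` (`"city"` or `"site"`),
#'   `name`, `substance` (a token or `"ALL"`), `reason`. Default: empty.
#' @param check Validate invariants and fail on errors (default `TRUE`).
#'
#' @return An object of class `wbe_dataset`: a list with elements
#'   `measurements`, `catchments`, `params`, `exclusions`.
#' @seealso [read_dataset()], [validate_dataset()]
#' @export
#' @examples
#' ds <- wbe_dataset(
#'   measurements = tibble::tibble(
#'     site_id = "s1", date = as.Date("2015-03-04"),
#'     substance = "benzoylecgonine", concentration = 800,
#'     loq = 10, censored = FALSE, flow = 2e7
#'   ),
#'   catchments = tibble::tibble(
#'     site_id = "s1", city = "Demo", country = "CH",
#'     region = "south_west_europe", population = 1e5, city_coverage = 1
#'   )
#' )
#' ds
wbe_dataset <- function(measurements, catchments,
                        params = default_drug_params(),
                        exclusions = empty_exclusions(),
                        check = TRUE) {
  ds <- structure(
    list(
      measurements = tibble::as_tibble(measurements),
      catchments = tibble::as_tibble(catchments),
      params = tibble::as_tibble(params),
      exclusions = tibble::as_tibble(exclusions)
    ),
    class = "wbe_dataset"
  )
  if (check) {
    rep <- validate_dataset(ds)
    if (rep$n_errors > 0L) {
      stop("invalid wbe_dataset:\n  ",
        paste(rep$errors, collapse = "\n  "),
        call. = FALSE
      )
    }
    for (w in rep$warnings) warning(w, call. = FALSE)
  }
  ds
}

#' @export
print.wbe_dataset <- function(x, ...) {
  m <- x$measurements
  cat("<wbe_dataset>\n")
  cat(sprintf(
    "  %d measurements | %d sites | %d cities | %d substances\n",
    nrow(m), nrow(x$catchments),
    length(unique(x$catchments$city)),
    length(unique(m$substance))
  ))
  if (nrow(m) > 0) {
    cat(sprintf(
      "  dates %s .. %s | %.1f%% censored (< LOQ)\n",
      min(m$date), max(m$date), 100 * mean(m$censored)
    ))
  }
  if (nrow(x$exclusions) > 0) {
    cat(sprintf("  %d manual exclusion(s)\n", nrow(x$exclusions)))
  }
  invisible(x)
}

#' Accessors for the component tables of a `wbe_dataset`
#'
#' @param ds A [wbe_dataset()].
#' @return The requested tibble.
#' @export
measurements <- function(ds) ds$measurements

#' @rdname measurements
#' @export
catchments <- function(ds) ds$catchments

#' @rdname measurements
#' @export
drug_params <- function(ds) ds$params

#' @rdname measurements
#' @export
exclusions <- function(ds) ds$exclusions

#' An empty exclusion table
#' @return Zero-row tibble with the exclusion-list columns.
#' @export
empty_exclusions <- function() {
  tibble::tibble(
    scope = character(), name = character(),
    substance = character(), reason = character()
  )
}

required_measurement_cols <- c(
  "site_id", "date", "substance", "concentration", "loq", "censored", "flow"
)
required_catchment_cols <- c(
  "site_id", "city", "country", "region", "population", "city_coverage"
)
required_params_cols <- c(
  "substance", "excretion_fraction", "molar_mass_ratio", "dose_mg"
)

#' Validate a WBE dataset
#'
#' Checks every dataset invariant and reports violations without modifying
#' the dataset. Errors are conditions that make downstream computation
#' meaningless (non-positive population or flow, unknown substances,
#' measurements referencing unknown sites, duplicate parameter rows);
#' warnings flag suspect but usable data (uncensored concentrations between
#' 0 and the LOQ, duplicate site/date/substance rows).
#'
#' @param ds A [wbe_dataset()] (or an unclassed list with the same elements).
#' @return A list of class `wbe_validation` with elements `n_errors`,
#'   `n_warnings`, `errors`, `warnings`.
#' @export
validate_dataset <- function(ds) {
  errors <- character()
  warnings <- character()
  m <- ds$measurements
  ct <- ds$catchments
  p <- ds$params

  miss <- setdiff(required_measurement_cols, names(m))
  if (length(miss)) {
    errors <- c(errors, paste0(
      "measurements: missing mandatory column(s): ", paste(miss, collapse = ", ")
    ))
  }
  miss <- setdiff(required_catchment_cols, names(ct))
  if (length(miss)) {
    errors <- c(errors, paste0(
      "catchments: missing mandatory column(s): ", paste(miss, collapse = ", ")
    ))
  }
  miss <- setdiff(required_params_cols, names(p))
  if (length(miss)) {
    errors <- c(errors, paste0(
      "params: missing mandatory column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (length(errors)) {
    return(new_validation(errors, warnings))
  }

  bad <- unique(ct$site_id[!is.na(ct$population) & ct$population <= 0])
  if (length(bad)) {
    errors <- c(errors, paste0(
      "catchments: population must be > 0 for site(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  bad <- unique(ct$site_id[
    is.na(ct$city_coverage) | ct$city_coverage <= 0 | ct$city_coverage > 1
  ])
  if (length(bad)) {
    errors <- c(errors, paste0(
      "catchments: city_coverage must be in (0, 1] for site(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  dup <- unique(ct$site_id[duplicated(ct$site_id)])
  if (length(dup)) {
    errors <- c(errors, paste0(
      "catchments: duplicated site_id(s): ", paste(dup, collapse = ", ")
    ))
  }

  unknown <- setdiff(unique(m$substance), WBE_SUBSTANCES)
  if (length(unknown)) {
    errors <- c(errors, paste0(
      "measurements: unknown substance token(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  orphans <- setdiff(unique(m$site_id), ct$site_id)
  if (length(orphans)) {
    errors <- c(errors, paste0(
      "measurements: site_id(s) not present in catchments: ",
      paste(orphans, collapse = ", ")
    ))
  }
  if (any(!is.na(m$flow) & m$flow <= 0) || anyNA(m$flow)) {
    errors <- c(errors, "measurements: flow must be > 0 for every sample")
  }
  if (any(!is.na(m$loq) & m$loq <= 0) || anyNA(m$loq)) {
    errors <- c(errors, "measurements: loq must be > 0 for every sample")
  }
  if (any(!m$censored & (is.na(m$concentration) | m$concentration < 0))) {
    errors <- c(errors,
      "measurements: uncensored rows must report a concentration >= 0"
    )
  }

  sub_loq <- !m$censored & !is.na(m$concentration) &
    m$concentration >= 0 & m$concentration < m$loq
  if (any(sub_loq)) {
    warnings <- c(warnings, sprintf(
      "measurements: %d uncensored concentration(s) between 0 and the LOQ; kept as reported",
      sum(sub_loq)
    ))
  }
  key <- paste(m$site_id, m$date, m$substance, sep = "|")
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    warnings <- c(warnings, paste0(
      "measurements: duplicate rows for (site_id, date, substance) = (",
      gsub("\\|", ", ", k), ")"
    ))
  }

  dup <- unique(p$substance[duplicated(p$substance)])
  if (length(dup)) {
    errors <- c(errors, paste0(
      "params: more than one row for substance(s): ",
      paste(dup, collapse = ", ")
    ))
  }
  bad <- p$substance[
    is.na(p$excretion_fraction) | p$excretion_fraction <= 0 |
      p$excretion_fraction > 1 |
      is.na(p$molar_mass_ratio) | p$molar_mass_ratio <= 0 |
      is.na(p$dose_mg) | p$dose_mg <= 0
  ]
  if (length(bad)) {
    errors <- c(errors, paste0(
      "params: invalid back-calculation constants for: ",
      paste(bad, collapse = ", ")
    ))
  }

  ex <- ds$exclusions
  if (nrow(ex)) {
    bad <- !ex$scope %in% c("city", "site")
    if (any(bad)) {
      errors <- c(errors, "exclusions: scope must be 'city' or 'site'")
    }
  }

  new_validation(errors, warnings)
}

new_validation <- function(errors, warnings) {
  structure(
    list(
      n_errors = length(errors), n_warnings = length(warnings),
      errors = errors, warnings = warnings
    ),
    class = "wbe_validation"
  )
}

#' @export
print.wbe_validation <- function(x, ...) {
  cat(sprintf(
    "<wbe_validation> %d error(s), %d warning(s)\n", x$n_errors, x$n_warnings
  ))
  for (e in x$errors) cat("  error:   ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
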