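#' Example back-calculation parameters for the six substances
#'
#' EXAMPLE-ONLY defaults assembled from commonly used values in the WBE
#' literature; campaign-specific parameter tables should be supplied via
#' `params.csv`/`params.yaml` when benchmarking against published dose
#' figures. Cocaine consumption is back-calculated from its urinary
#' metabolite benzoylecgonine, hence the molar-mass ratio above 1 on that
#' row; the parent substances use ratio 1. THC-COOH carries no dose
#' parameters (cannabis is excluded from dose totals), so it has no row.
#'
#' @return Tibble with columns `substance`, `excretion_fraction`,
#'   `molar_mass_ratio`, `dose_mg`.
#' @export
default_drug_params <- function() {
  tibble::tibble(
    substance = c("benzoylecgonine", "amphetamine", "methamphetamine", "mdma"),
    excretion_fraction = c(0.29, 0.36, 0.43, 0.20),
    molar_mass_ratio = c(1.0485, 1.0, 1.0, 1.0),
    dose_mg = c(100, 30, 30, 100)
  )
}

parse_censored_concentration <- function(x) {
  if (is.numeric(x)) {
    return(list(concentration = as.numeric(x), token = rep(FALSE, length(x))))
  }
  x_chr <- trimws(as.character(x))
  token <- grepl("^<\\s*LOQ$", x_chr, ignore.case = TRUE)
  conc <- suppressWarnings(as.numeric(x_chr))
  conc[token] <- NA_real_
  bad <- !token & is.na(conc) & !is.na(x_chr) & nzchar(x_chr)
  if (any(bad)) {
    stop(
      "measurements: unparseable concentration value(s): ",
      paste(unique(x_chr[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  list(concentration = conc, token = token)
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(
      what, ": missing mandatory column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

#' Read a measurements table
#'
#' Expected columns: `site_id`, `date` (ISO-8601), `substance`,
#' `concentration_ng_l`, `loq_ng_l`, `censored`, `flow_l_d`. Censoring may
#' be encoded either in the logical `censored` column or as the token
#' `"<LOQ"` in `concentration_ng_l`; both are normalised to the logical flag
#' on read. An optional `flow_unit` column (`"L/day"` or `"m3/day"`)
#' converts flows to the canonical L/day.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator (default comma).
#' @return Tibble in the internal measurement layout.
#' @export
read_measurements <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  require_cols(
    df,
    c("site_id", "date", "substance", "concentration_ng_l", "loq_ng_l", "flow_l_d"),
    "measurements"
  )
  parsed <- parse_censored_concentration(df$concentration_ng_l)
  censored <- if ("censored" %in% names(df)) {
    as.logical(df$censored) | parsed$token
  } else {
    parsed$token
  }
  flow <- as.numeric(df$flow_l_d)
  if ("flow_unit" %in% names(df)) {
    unit <- trimws(tolower(df$flow_unit))
    known <- unit %in% c("l/day", "m3/day")
    if (any(!known)) {
      stop("measurements: unknown flow_unit value(s): ",
        paste(unique(df$flow_unit[!known]), collapse = ", "),
        call. = FALSE
      )
    }
    flow <- ifelse(unit == "m3/day", flow * 1000, flow)
  }
  tibble::tibble(
    site_id = as.character(df$site_id),
    date = as.Date(df$date),
    substance = as.character(df$substance),
    concentration = parsed$concentration,
    loq = as.numeric(df$loq_ng_l),
    censored = censored,
    flow = flow
  )
}

#' Read a sites (catchment) table
#'
#' Expected columns: `site_id`, `city`, `country`, `region`, `population`,
#' `city_coverage`.
#'
#' @inheritParams read_measurements
#' @return Tibble in the internal catchment layout.
#' @export
read_sites <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  require_cols(df, required_catchment_cols, "sites")
  tibble::tibble(
    site_id = as.character(df$site_id),
    city = as.character(df$city),
    country = as.character(df$country),
    region = as.character(df$region),
    population = as.numeric(df$population),
    city_coverage = as.numeric(df$city_coverage)
  )
}

#' Read a back-calculation parameter table (CSV or YAML)
#'
#' CSV columns: `substance`, `excretion_fraction`, `molar_mass_ratio`,
#' `dose_mg`. A YAML file (extension `.yml`/`.yaml`) is read as a map
#' substance -> {excretion_fraction, molar_mass_ratio, dose_mg}.
#'
#' @inheritParams read_measurements
#' @return Tibble in the internal parameter layout.
#' @export
read_drug_params <- function(path, sep = ",") {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML parameter files requires the 'yaml' package",
        call. = FALSE
      )
    }
    lst <- yaml::read_yaml(path)
    df <- tibble::tibble(
      substance = names(lst),
      excretion_fraction = vapply(
        lst, function(x) as.numeric(x$excretion_fraction), 0,
        USE.NAMES = FALSE
      ),
      molar_mass_ratio = vapply(
        lst, function(x) as.numeric(x$molar_mass_ratio), 0,
        USE.NAMES = FALSE
      ),
      dose_mg = vapply(
        lst, function(x) as.numeric(x$dose_mg), 0,
        USE.NAMES = FALSE
      )
    )
    return(df)
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  require_cols(df, required_params_cols, "params")
  tibble::tibble(
    substance = as.character(df$substance),
    excretion_fraction = as.numeric(df$excretion_fraction),
    molar_mass_ratio = as.numeric(df$molar_mass_ratio),
    dose_mg = as.numeric(df$dose_mg)
  )
}

#' Read a manual exclusion list
#'
#' Expected columns: `scope` (`city` or `site`), `name`, `substance` (a
#' substance token or `ALL`), `reason`. Exclusions remove (city, substance)
#' or (site, substance) pairs from overall means; per-city outputs keep
#' them.
#'
#' @inheritParams read_measurements
#' @return Tibble in the internal exclusion layout.
#' @export
read_exclusions <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  require_cols(df, c("scope", "name", "substance", "reason"), "exclusions")
  tibble::tibble(
    scope = as.character(df$scope),
    name = as.character(df$name),
    substance = as.character(df$substance),
    reason = as.character(df$reason)
  )
}

#' Read a complete WBE dataset from delimited files
#'
#' @param measurements_path,sites_path Paths to the measurement and site
#'   tables (see [read_measurements()] and [read_sites()]).
#' @param params_path Optional path to a parameter table; defaults to
#'   [default_drug_params()] when `NULL`.
#' @param exclusions_path Optional path to an exclusion list.
#' @param sep Field separator.
#' @return A validated [wbe_dataset()]. Validation warnings (e.g. uncensored
#'   concentrations below the LOQ) are raised as R warnings; validation
#'   errors abort.
#' @export
read_dataset <- function(measurements_path, sites_path,
                         params_path = NULL, exclusions_path = NULL,
                         sep = ",") {
  wbe_dataset(
    measurements = read_measurements(measurements_path, sep = sep),
    catchments = read_sites(sites_path, sep = sep),
    params = if (is.null(params_path)) default_drug_params() else read_drug_params(params_path, sep = sep),
    exclusions = if (is.null(exclusions_path)) empty_exclusions() else read_exclusions(exclusions_path, sep = sep)
  )
}

#' Write a WBE dataset to delimited files
#'
#' Writes `measurements.csv`, `sites.csv`, `params.csv` and, when
#' non-empty, `exclusions.csv` into `dir` using the same external column
#' layout the readers accept, so that a write/read cycle reproduces all
#' numeric fields and censoring flags exactly. Censored concentrations are
#' written as the token `"<LOQ"`.
#'
#' @param ds A [wbe_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- ds$measurements
  out_m <- data.frame(
    site_id = m$site_id,
    date = format(m$date, "%Y-%m-%d"),
    substance = m$substance,
    concentration_ng_l = ifelse(
      m$censored, "<LOQ",
      format_full(m$concentration)
    ),
    loq_ng_l = format_full(m$loq),
    censored = m$censored,
    flow_l_d = format_full(m$flow),
    stringsAsFactors = FALSE
  )
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    sites = file.path(dir, "sites.csv"),
    params = file.path(dir, "params.csv")
  )
  write.csv(out_m, paths[["measurements"]], row.names = FALSE, quote = FALSE)
  ct <- ds$catchments
  ct$population <- format_full(ct$population)
  ct$city_coverage <- format_full(ct$city_coverage)
  write.csv(ct, paths[["sites"]], row.names = FALSE, quote = FALSE)
  p <- ds$params
  p$excretion_fraction <- format_full(p$excretion_fraction)
  p$molar_mass_ratio <- format_full(p$molar_mass_ratio)
  p$dose_mg <- format_full(p$dose_mg)
  write.csv(p, paths[["params"]], row.names = FALSE, quote = FALSE)
  if (nrow(ds$exclusions)) {
    paths <- c(paths, exclusions = file.path(dir, "exclusions.csv"))
    write.csv(ds$exclusions, paths[["exclusions"]],
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(paths)
}

# full double precision so the round-trip is bit-exact
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, "")
  out
}
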