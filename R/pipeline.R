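#' Configuration for an end-to-end pipeline run
#'
#' @param measurements,sites Paths to the input tables, or `NULL` when a
#'   ready-made dataset is passed to [run_pipeline()] directly.
#' @param params,exclusions Optional paths to the parameter table and
#'   manual exclusion list.
#' @param periods List of reporting periods (2-vectors of years); must not
#'   overlap.
#' @param alpha Significance level for trend classification, in (0, 1).
#' @param min_core_years Core-city threshold (distinct monitored years).
#' @param dumping_threshold Cocaine:benzoylecgonine ratio above which a
#'   day is flagged as a disposal event.
#' @param outlier_k Median multiplier for outlier-city screening.
#' @param with_uncertainty Append Monte-Carlo uncertainty columns
#'   (`rel_sd`, `lo95`, `hi95`) to the overall-mean table.
#' @param uncertainty_budget Named component budget (see
#'   [default_uncertainty_budget()]).
#' @param n_draws Monte-Carlo draws for the uncertainty columns.
#' @param out_dir Output directory for the CSV bundle and manifest.
#' @param seed Integer seed used for the stochastic stages.
#' @return A list of class `wbe_run_config`.
#' @export
pipeline_config <- function(measurements = NULL, sites = NULL,
                            params = NULL, exclusions = NULL,
                            periods = list(c(2011, 2013), c(2014, 2017)),
                            alpha = 0.2,
                            min_core_years = 5L,
                            dumping_threshold = 0.75,
                            outlier_k = 10,
                            with_uncertainty = FALSE,
                            uncertainty_budget = default_uncertainty_budget(),
                            n_draws = 10000L,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(periods) > 1L) {
    spans <- do.call(rbind, periods)
    ord <- order(spans[, 1])
    spans <- spans[ord, , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
      stop("reporting periods must not overlap", call. = FALSE)
    }
  }
  structure(
    list(
      measurements = measurements, sites = sites, params = params,
      exclusions = exclusions, periods = periods, alpha = alpha,
      min_core_years = as.integer(min_core_years),
      dumping_threshold = dumping_threshold, outlier_k = outlier_k,
      with_uncertainty = with_uncertainty,
      uncertainty_budget = uncertainty_budget,
      n_draws = as.integer(n_draws),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "wbe_run_config"
  )
}

#' Run the full WBE pipeline
#'
#' Executes ingest, the below-LOQ policy, load computation, QC screening,
#' dose back-calculation, trend classification and overall means; when an
#' output directory is configured, writes the report bundle (one CSV per
#' stage, units in the headers) plus a JSON run manifest with the echoed
#' configuration, seed and row counts. Deterministic under a fixed
#' configuration and seed.
#'
#' @param cfg A [pipeline_config()].
#' @param dataset Optional [wbe_dataset()]; when `NULL` the input paths in
#'   `cfg` are read.
#' @return Invisibly, a list with `dataset`, `validation`, `daily`,
#'   `weekly`, `city_year`, `doses`, `trends`, `overall_means`,
#'   `qc_flags`, and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), dataset = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  ds <- stage("ingest", {
    if (!is.null(dataset)) {
      dataset
    } else {
      if (is.null(cfg$measurements) || is.null(cfg$sites)) {
        stop("no dataset given and no input paths configured")
      }
      read_dataset(cfg$measurements, cfg$sites, cfg$params, cfg$exclusions)
    }
  })
  validation <- stage("validate", validate_dataset(ds))
  if (validation$n_errors > 0L) {
    stop(
      "[validate] dataset has errors:\n  ",
      paste(validation$errors, collapse = "\n  "),
      call. = FALSE
    )
  }
  set.seed(cfg$seed)
  daily <- stage("loads", compute_daily_loads(ds))
  weekly <- stage("loads", weekly_summaries(ds, daily = daily))
  cyl <- stage("loads", city_year_loads(ds, summaries = weekly))
  qc_flags <- stage("qc", {
    dump <- flag_dumping_days(daily$daily, threshold = cfg$dumping_threshold)
    outl <- screen_outlier_city(cyl, k = cfg$outlier_k)
    list(dumping = dump, outliers = outl)
  })
  doses <- stage("doses", city_dose_table(ds, city_loads = cyl))
  trends <- stage(
    "trends",
    trend_calls(ds, periods = cfg$periods, alpha = cfg$alpha, city_loads = cyl)
  )
  om <- stage(
    "overall_means",
    overall_means_table(ds, min_years = cfg$min_core_years, city_loads = cyl)
  )
  if (isTRUE(cfg$with_uncertainty)) {
    om <- stage("uncertainty", {
      res <- lapply(om$mean, function(v) {
        if (is.na(v)) {
          list(rel_sd = NA_real_, lo95 = NA_real_, hi95 = NA_real_)
        } else {
          propagate_mc(v, cfg$uncertainty_budget,
            scope = "load",
            n_draws = cfg$n_draws
          )
        }
      })
      om$rel_sd <- vapply(res, `[[`, 0, "rel_sd")
      om$lo95 <- vapply(res, `[[`, 0, "lo95")
      om$hi95 <- vapply(res, `[[`, 0, "hi95")
      om
    })
  }
  manifest <- list(
    package = "wbepi",
    version = as.character(utils::packageVersion("wbepi")),
    seed = cfg$seed,
    alpha = cfg$alpha,
    periods = lapply(cfg$periods, as.integer),
    dumping_threshold = cfg$dumping_threshold,
    outlier_k = cfg$outlier_k,
    with_uncertainty = isTRUE(cfg$with_uncertainty),
    row_counts = list(
      measurements = nrow(ds$measurements),
      catchments = nrow(ds$catchments),
      daily_loads = nrow(daily$daily),
      excluded_weeks = nrow(daily$excluded_weeks),
      weekly_summaries = nrow(weekly),
      city_year_loads = nrow(cyl),
      doses = nrow(doses),
      trends = nrow(trends),
      overall_means = nrow(om),
      dumping_flags = nrow(qc_flags$dumping),
      outlier_flags = nrow(qc_flags$outliers)
    )
  )
  result <- list(
    dataset = ds, validation = validation, daily = daily, weekly = weekly,
    city_year = cyl, doses = doses, trends = trends, overall_means = om,
    qc_flags = qc_flags, manifest = manifest
  )
  if (!is.null(cfg$out_dir)) {
    stage("report", write_report_bundle(result, cfg$out_dir))
  }
  invisible(result)
}

unit_header <- function(df, note) {
  # a '# units: ...' comment line above the header keeps every table
  # self-describing without breaking read.csv(comment.char = "#")
  attr(df, "units_note") <- note
  df
}

write_table <- function(df, path, note) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# units: ", note), con)
  write.csv(df, con, row.names = FALSE)
}

write_report_bundle <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  daily <- result$daily$daily
  write_table(
    daily, file.path(out_dir, "daily_loads.csv"),
    "load in mg/1000 people/day"
  )
  write_table(
    result$daily$excluded_weeks, file.path(out_dir, "excluded_weeks.csv"),
    "none (all-below-LOQ campaign weeks)"
  )
  write_table(
    result$weekly, file.path(out_dir, "weekly_summaries.csv"),
    "mean/sd/min/max in mg/1000 people/day"
  )
  write_table(
    result$city_year, file.path(out_dir, "city_year_loads.csv"),
    "load in mg/1000 people/day"
  )
  write_table(
    result$doses, file.path(out_dir, "doses.csv"),
    "consumption in mg/1000 people/day; doses in doses/1000 people/day"
  )
  write_table(
    result$trends, file.path(out_dir, "trends.csv"),
    "slope in mg/1000 people/day per year"
  )
  write_table(
    result$overall_means, file.path(out_dir, "overall_means.csv"),
    "mean in mg/1000 people/day"
  )
  write_table(
    dplyr::bind_rows(
      result$qc_flags$dumping |>
        dplyr::mutate(scope = "site_day", .before = 1),
      result$qc_flags$outliers |>
        dplyr::mutate(scope = "city_year", .before = 1)
    ),
    file.path(out_dir, "qc_flags.csv"),
    "metric is a dimensionless ratio"
  )
  jsonlite::write_json(
    result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
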