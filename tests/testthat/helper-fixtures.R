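# Shared fixtures: small hand-written tables and a lazily built benchmark
# suite (generated once per test run, reused across files).

write_fixture_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

fixture_sites_lines <- c(
  "site_id,city,country,region,population,city_coverage",
  "s1,Alpha,CH,south_west_europe,100000,0.95",
  "s2,Beta,NO,north_europe,300000,0.90"
)

fixture_measurement_lines <- c(
  "site_id,date,substance,concentration_ng_l,loq_ng_l,censored,flow_l_d",
  "s1,2015-03-04,benzoylecgonine,800,10,FALSE,20000000",
  "s1,2015-03-05,benzoylecgonine,<LOQ,10,FALSE,20000000",
  "s2,2015-03-04,mdma,55,5,FALSE,60000000"
)

make_tiny_dataset <- function() {
  wbe_dataset(
    measurements = tibble::tibble(
      site_id = c("s1", "s1", "s2"),
      date = as.Date(c("2015-03-04", "2015-03-05", "2015-03-04")),
      substance = c("benzoylecgonine", "benzoylecgonine", "mdma"),
      concentration = c(800, NA, 55),
      loq = c(10, 10, 5),
      censored = c(FALSE, TRUE, FALSE),
      flow = c(2e7, 2e7, 6e7)
    ),
    catchments = tibble::tibble(
      site_id = c("s1", "s2"),
      city = c("Alpha", "Beta"),
      country = c("CH", "NO"),
      region = c("south_west_europe", "north_europe"),
      population = c(1e5, 3e5),
      city_coverage = c(0.95, 0.9)
    )
  )
}

# weekly-summary-shaped table built directly, for unit tests that do not
# need a full dataset
make_summaries <- function(df) {
  defaults <- tibble::tibble(
    site_id = "s", city = "c", year = 2011L, substance = "benzoylecgonine",
    mean = 1, sd = 0, min = 1, max = 1, n_days = 7L,
    included = TRUE, exclusion_reason = ""
  )
  out <- df
  for (col in setdiff(names(defaults), names(out))) {
    out[[col]] <- defaults[[col]]
  }
  out
}

.bench_cache <- new.env(parent = emptyenv())

bench_suite <- function(seed = 20260901L) {
  key <- paste0("suite_", seed)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- make_benchmark_suite(seed)
  }
  .bench_cache[[key]]
}
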