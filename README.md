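# wbepi

Wastewater-based epidemiology (WBE) of illicit stimulant use.

A city's raw sewage carries the residues its population excretes, so
24-hour composite samples of treatment-plant influent provide an
objective, near real-time indicator of community drug consumption. This
package implements the full WBE computation chain for multi-city,
multi-year monitoring campaigns (one sampling week per site and year),
for epidemiologists and environmental chemists who need reproducible,
auditable estimates rather than spreadsheet arithmetic:

* **Loads** — influent concentrations (ng/L) × daily flow (L/day) ÷
  population, giving population-normalized loads
  `L = C·Q·10⁻³/P` in mg/1000 people/day, with the standard policy for
  censored values: weeks entirely below the limit of quantification (LOQ)
  are excluded; otherwise censored days are substituted with 0.5×LOQ and
  flagged.
* **Doses** — back-calculation of consumed pure parent mass,
  `L·r/e` (molar-mass ratio `r`, excretion fraction `e`), and average
  daily doses `L·r/(e·d)`; the cocaine, amphetamine, methamphetamine and
  MDMA channels sum to **combined doses** per 1000 people/day (cannabis
  is excluded from dose totals; cocaine is estimated from its metabolite
  benzoylecgonine).
* **Trends** — per city and substance, ordinary least squares of annual
  mean load on year with a two-sided slope test at α = 0.2; `increase` /
  `decrease` / `no_trend` / `insufficient` calls, period means, and
  overall means over all cities or the ≥5-year "core city" subset.
* **QC** — disposal-event detection via anomalous
  cocaine:benzoylecgonine ratios, outlier city-year screening,
  opt-in corrections for methamphetamine-derived amphetamine and
  in-sewer transformation losses.
* **Uncertainty** — a component budget (sampling, analysis, flow,
  population, excretion, dose mass) combined in quadrature, with a
  Monte-Carlo twin for empirical intervals.
* **Synthetic campaigns** — a generator that emulates the structure of a
  large international campaign (120 cities / 143 plants / 7 years, >2
  orders of magnitude spatial span, censoring, disposal spikes) and
  exports ground truth, so the whole pipeline is testable without access
  to deposited monitoring data.

The shipped back-calculation parameters and uncertainty budget are
**example-only** defaults from the open literature; supply your
campaign's own tables for benchmarking. See the methods vignette
(`vignettes/wbe-methods.Rmd`) for the models, assumptions and design
choices.

## Worked example

```r
library(wbepi)

# a synthetic 120-city campaign with known ground truth
g  <- generate_scenario(scenario_config(seed = 42))
ds <- g$dataset
ds
#> <wbe_dataset>
#>   20916 measurements | 143 sites | 120 cities | 6 substances
#>   dates 2011-03-02 .. 2017-03-07 | 6.4% censored (< LOQ)

weekly <- weekly_summaries(ds)            # per site/substance/year stats
cyl    <- city_year_loads(ds, summaries = weekly)

length(core_city_selection(ds, summaries = weekly))
#> [1] 26      # cities with >= 5 monitored years

overall_mean(ds, 2017, "benzoylecgonine",
             variant = "core_cities", city_loads = cyl)$mean
#> [1] 239.1   # mg BZE/1000 people/day, mean over the 26 core cities

# combined stimulant doses, top cities in 2017
doses <- city_dose_table(ds, city_loads = cyl)
head(doses[doses$substance == "combined" & doses$year == 2017, ])
#>       city doses_1000p_d
#> 1 city_118         100.8
#> 2 city_095          72.5   # doses/1000 people/day

# trend call for a rising 4-year series of annual mean loads
classify_trend(2014:2017, c(310, 340, 365, 401))
#> <wbe_trend> increase (slope 29.8, P 0.00245, 4 year(s))

# dose arithmetic: 300 mg BZE/1000p/day with example cocaine parameters
p <- default_drug_params()
dose_count(300, p[p$substance == "benzoylecgonine", ])
#> [1] 10.84655  # doses/1000 people/day
```

A load of 300 mg benzoylecgonine per 1000 people per day therefore
corresponds to roughly 11 average 100-mg cocaine doses per 1000
inhabitants daily under the example excretion fraction (0.29) and
molar-mass ratio (1.0485). `run_pipeline()` executes every stage on a
dataset (or input CSVs) and writes a report bundle — daily and weekly
loads, city-year loads, doses, trend calls, overall means, QC flags and a
JSON manifest — with units declared in every table header;
`inst/scripts/wbe-run.R` wraps it for shell use.

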