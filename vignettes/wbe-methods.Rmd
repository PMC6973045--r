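---
title: "Methods: from influent concentrations to drug-use estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from influent concentrations to drug-use estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbepi)
```

## The problem

Wastewater-based epidemiology (WBE) treats a city's sewer as a pooled urine
sample. People who consume a drug excrete the parent substance and/or its
metabolites; 24-hour composite samples of raw influent at the wastewater
treatment plant (WWTP) therefore carry a chemical record of the community's
aggregate consumption on that day. Measured residue concentrations can be
turned into comparable, population-normalized mass loads and — with
pharmacokinetic correction factors — into estimates of the number of average
doses consumed per day. `wbepi` implements this computation chain for
multi-city, multi-year monitoring campaigns in which each site is sampled
for about one week per year.

The biomarkers handled are benzoylecgonine (BZE, the principal urinary
metabolite of cocaine), the parent substances amphetamine, methamphetamine
and MDMA, cocaine itself (carried for quality control, see below), and
THC-COOH (the cannabis metabolite, supported as a load pass-through but
never converted to doses, because its quantification in wastewater is too
uncertain for comparable consumption figures).

## Population-normalized loads

The elementary quantity is the daily mass load per 1000 inhabitants:

$$ L \;=\; \frac{C \cdot Q \cdot 10^{-3}}{P} \quad
   \left[\frac{\text{mg}}{1000\,\text{people}\cdot\text{day}}\right] $$

with concentration $C$ in ng/L, daily flow $Q$ in L/day and catchment
population $P$. The factor $10^{-3}$ collects the ng-to-mg conversion
($10^{-6}$) and the per-1000-people scaling ($10^{3}$). `daily_load()` is
this formula and nothing else; flows reported in m³/day are converted at
ingest so the canonical unit is always L/day.

### Censored values (the LOQ policy)

Concentrations below the limit of quantification (LOQ) are censored. The
pipeline applies a week-level policy via `apply_loq_policy()`:

* if **every** day of a site's campaign week is below the LOQ for a
  substance, that site/substance/year week is excluded entirely (it would
  otherwise contribute a value that is pure imputation);
* otherwise censored days are substituted with $0.5 \times$ LOQ — the
  conventional midpoint substitution for left-censored environmental data —
  and flagged `imputed` so downstream users can audit their influence.

Substitution is applied per day; the exclusion test uses only the censoring
flags. Values reported *uncensored* but numerically below the LOQ are kept
as reported with an ingest warning: the data are suspect but discarding or
re-censoring them would second-guess the reporting laboratory. Whether a
value exactly equal to the LOQ counts as censored is left to the data
producer's flag — the reader never re-derives censoring from the numbers.

Weeks with 1–6 sampled days are summarized over the available days
(`n_days` is recorded); missing days are not imputed. Weekly summaries use
the sample standard deviation ($n-1$; defined as 0 for a single day).
Cities served by several WWTPs are aggregated as the population-weighted
mean of their sites' weekly means — the sites sample disjoint
sub-populations of one city, so weighting by population served is the
natural city-level estimate.

## Dose back-calculation

For a residue with excretion fraction $e$ (mass fraction of the consumed
parent excreted as that residue), parent/residue molar-mass ratio $r$ and
average pure dose $d$ (mg), a load $L$ converts to

$$ \text{consumed parent mass} = L \cdot r / e, \qquad
   \text{doses} = L \cdot r / (e \cdot d). $$

Cocaine consumption is estimated from BZE (hence $r > 1$ on that channel);
amphetamine, methamphetamine and MDMA are measured as parents ($r = 1$).
The four stimulant channels are summed into **combined doses** per 1000
people per day; THC-COOH never contributes. Amphetamine doses are computed
from the *entire* amphetamine load by default — the correction for the few
percent of methamphetamine doses excreted as amphetamine
(`correct_amphetamine()`) is deliberately opt-in, since licit prescription
use and disposal also contribute and a global correction cannot be
defended. Purity is not modelled: doses are pure-drug doses.

The shipped parameter table (`default_drug_params()`) is **example-only**:
excretion fractions, molar-mass ratios and dose masses vary across the
pharmacokinetic literature, and any benchmarking against published dose
figures must transcribe the campaign's own parameter table. The defaults
(BZE 0.29/1.0485/100 mg; amphetamine 0.36/1.0/30 mg; methamphetamine
0.43/1.0/30 mg; MDMA 0.20/1.0/100 mg) are round, commonly used literature
values, and every function takes the table as data, never as constants.

Period averages (e.g. a 2011–17 city profile) weight available years
equally rather than by number of sampled days: campaign weeks are designed
to be comparable one-week snapshots, so a year with five sampled days is
still one year of evidence.

## Trend classification

Temporal change per city and substance is assessed on annual weekly-mean
loads — one point per year, not pooled daily values, since within-week
variation reflects day-of-week behaviour rather than trend. For a period's
series, `classify_trend()` fits ordinary least squares of load on year and
performs a two-sided t-test of zero slope:

* fewer than 2 annual observations → `insufficient`;
* exactly 2 observations → `no_trend` (a two-point slope is always exact);
* $P \ge 0.2$ or zero slope → `no_trend`;
* otherwise `increase` or `decrease` by the sign of the slope.

The deliberately liberal $\alpha = 0.2$ (configurable) reflects the
screening character of the call: with at most seven annual points, a
conventional 0.05 level would have almost no power. $P$ exactly equal to
$\alpha$ is conservatively `no_trend`. Regressions are unweighted; no
multiple-testing correction is applied across cities, matching the
screening (not confirmatory) use of the calls.

Two overall-mean variants summarize each year: the unweighted mean over all
eligible cities, and over the **core cities** — those with data in at least
5 distinct years — whose stability makes them the anchor for temporal
statements. Cities on the manual exclusion list for a substance (for
example a city whose loads are dominated by manufacturing-waste discharges)
are removed from overall means while remaining visible in all per-city
tables.

## Quality control

**Disposal (dumping) detection.** Cocaine dumped unconsumed into a sewer
arrives unmetabolised, so the cocaine:BZE load ratio rises far above the
physiological range. `flag_dumping()` flags days whose ratio exceeds a
threshold (default 0.75). The threshold is a documented heuristic — the
physiological ratio is well below 1 but no published constant exists — and
every flag carries its metric for audit. A positive cocaine load with zero
BZE is flagged with an infinite metric.

**Outlier city-years.** `screen_outlier_city()` flags city-years whose
annual mean is more than $k$ times the cross-city median (or below
median$/k$; default $k = 10$) for the same substance-year. Flags are
*proposals* for the manual exclusion list, never applied automatically:
published campaigns excluded such values by expert judgement, which a fixed
rule can only approximate.

**In-sewer transformation.** Biomarker losses between excretion and the
WWTP intake underestimate loads. For BZE, methamphetamine and MDMA the loss
is below 10% at typical hydraulic residence times, so
`in_sewer_correction()` rejects factors above 0.10 for those substances;
amphetamine can transform more strongly but only site-specifically, so
larger factors are accepted with a warning. The correction (division by
$1-\text{factor}$) is opt-in; the headline pipeline reports uncorrected
loads.

## Uncertainty propagation

Every factor in the load and dose formulas is positive and multiplicative,
so the error model is multiplicative: independent lognormal factors per
component. The recognised components are sampling, analysis, flow and
population (load scope), plus excretion fraction and dose mass (dose
scope). Under independence the combined relative SD is the root sum of
squares of the component relative SDs
(`combined_relative_uncertainty()`); `propagate_mc()` is its Monte-Carlo
twin, drawing median-1 lognormal multipliers with
$\sigma_{\log} = \sqrt{\log(1 + \text{cv}^2)}$ so each multiplier's
relative SD equals its component value exactly, which keeps the numerical
and closed-form routes mutually checkable. The shipped budget is
example-only (5/10/10/10% for the load scope, combining to ≈18%, plus
15/20% for the dose scope); distributional shapes and correlations between
components are not modelled.

## The synthetic-data generator

Real deposited campaign data cannot ship with the package, so
`generate_scenario()` produces campaigns with the same statistical
structure *plus exported ground truth*, making every pipeline stage
testable end-to-end. The default scenario emulates a large international
campaign:

* 120 cities, 143 WWTPs (the extra plants are second sites of randomly
  chosen cities, each covering part of its city), 2011–2017, one 7-day
  week per site-year starting the first Wednesday of March;
* 26 core cities monitored in all years; the rest participate in 1–4
  years, biased toward later years (participation grew over time);
* city baseline loads drawn lognormally around region-specific geometric
  means (cocaine-dominant south-west Europe, amphetamine-leaning north,
  methamphetamine-leaning east and non-European sites) with geometric SD
  3.2, sized so a 120-city campaign spans more than two orders of
  magnitude between its 2.5th and 97.5th city percentiles — the spatial
  span reported by large monitoring studies;
* per-substance annual trend multipliers, weekend uplift (default 1.3 on
  the cocaine and MDMA channels, a well-documented recreational-use
  pattern), and day-to-day lognormal noise (default $\sigma_{\log}$ 0.25);
* concentrations obtained by inverting the load formula
  ($C = L \cdot P / (Q \cdot 10^{-3})$) with per-site-day flows from a
  per-capita range of 200–400 L/person/day, then censored below the LOQ;
* occasional disposal days (2% of site-years) multiplying the cocaine
  *parent* by 5 while leaving BZE untouched, and optional
  manufacturing-discharge cities with persistently multiplied amphetamine
  and MDMA.

One modelling choice deserves emphasis: cocaine and BZE share each
site-day's noise factor, because both derive from the same consumption
events. This keeps the clean-day cocaine:BZE ratio at its configured
constant (0.4), which is what makes disposal-day ground truth well defined.
The other substances draw independent noise.

`make_benchmark_suite()` fixes six scenarios used throughout the tests:
a stationary null for calibrating the trend rule (26 core cities × 7
years; the type-I rate of the $\alpha=0.2$ rule is checked against a
binomial 99% interval on 520 independent series — cocaine is excluded from
the tally precisely because it duplicates the BZE signal); ±10%/yr trend
scenarios for power; a heavy-censoring scenario; a disposal-rich scenario;
and a manufacturing-discharge scenario. Two of these deviate from the
default spatial structure by design:

* the **heavy-censoring** scenario uses one region, identical city
  baselines and a fixed per-capita flow, with the LOQ set at the median
  concentration — each sampling day is then censored independently with
  probability one half, so the realized censoring fraction is a sharp
  check (±2 percentage points) and all-censored weeks occur at a known
  rate ($2^{-7}$ per week);
* the **manufacturing-discharge** scenario uses a single region with
  moderate spread (geometric SD 1.8), so that every flag raised by the
  median-multiplier rule is attributable to the injected discharge rather
  than to natural heavy-tail spatial variation.

### What the generator does not emulate

Passing tests on synthetic data demonstrate that the *computation chain*
is correct and calibrated under the stated statistical model; they do not
validate the model against real sewers. Not represented: analytical
inter-laboratory variation, flow-measurement error correlated with rain
events, population dynamics (de-facto population, commuting, tourism),
in-sewer transformation, within-day concentration dynamics, holidays or
festival weeks, and reporting conventions that differ between
laboratories. Parameter recovery at zero noise shows invertibility of the
dose arithmetic, not correctness of any particular excretion fraction.

## Numerical choices and degenerate inputs

* Perfectly collinear trend series (zero residual) give $P \approx 0$ and
  a trend call by slope sign; perfectly flat series give an undefined
  t-statistic and are classified `no_trend`.
* Duplicate (site, date, substance) measurement rows are averaged with a
  warning; duplicate years within one trend series are a hard error.
* Weighted city means ignore excluded sites; a city with all sites
  excluded yields the explicit "no value" result (`NA`), never silently 0.
* The write/read round-trip serialises numerics at full double precision
  (`%.17g`), so a written dataset re-reads bit-exactly.
* Monte-Carlo summaries are reproducible under a fixed seed; the
  convergence check at $10^5$ draws tolerates 10% relative deviation,
  generous relative to the Monte-Carlo standard error.

## Problem sizes used in the validation

The test-suite and acceptance computations run on: one default 120-city
campaign (~20 000 measurements), four 26-city null campaigns for trend
calibration (520 independent series), single 26-city campaigns per trend
effect size, a 20-city heavy-censoring campaign (~5 900 measurements), a
20-city disposal-rich campaign, a 12-city discharge-outlier campaign, a
12-city noiseless campaign for dose round-trips, and $10^5$ Monte-Carlo
draws — sizes at which every stochastic check has comfortable margins
around its tolerance.

## Known limitations

* Thresholds for "abnormal" ratios (disposal flagging, outlier screening)
  are documented heuristics standing in for expert judgement.
* The package estimates use, not users: no prevalence, purity adjustment
  or per-user quantities.
* One monitoring week per year is a snapshot; the trend rule is a screen,
  and short apparent trends deserve caution — which is exactly why calls
  carry their slope and P-value rather than a bare label.
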