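---
title: "Multi-stressor suitability timelines for reef sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stressor suitability timelines for reef sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefhorizon)
```

## The question the pipeline answers

For an ecosystem with known tolerance limits, the time it has left to adapt
is set by the year after which an environmental stressor moves permanently
outside those limits. `reefhorizon` computes that date for reef sites under
five co-occurring anthropogenic stressors — marine heatwaves (degree heating
weeks, DHW), ocean acidification (aragonite saturation state, Omega_arag),
major storms, local human pressure (population density as a proxy) and
land-based pollution (agricultural/urban land use as a proxy) — and combines
them into an overall environmental unsuitability date: the earliest year at
which *any* stressor permanently crosses its threshold at a site.

The central quantity is deliberately simple. Each stressor metric is reduced
to binary suitability per 5-year window (1 = within tolerance, 0 = outside),
and the *permanent exceedance year* is the label of the first window of the
terminal unsuitable run, i.e. the first window after which the site never
recovers through 2100. Because different stressors become limiting in
different places (spatial complementarity), the overall curve — the
cumulative fraction of sites unsuitable by year — always dominates every
single-stressor curve, and the combined timeline is shorter than any
individual one. That dominance is an exact, testable property of the
definition and is asserted in the test suite.

## Thresholds

Suitability limits, applied strictly (a value exactly at the limit is
unsuitable, following the printed inequality direction):

| stressor | suitable when | units |
|---|---|---|
| DHW | `< 8` | deg C-weeks (window maximum) |
| Omega_arag | `> 3.3` | saturation state |
| storms | not (worst category >= 4 and return period <= 5) | Saffir-Simpson; years |
| population density | `< 100` | persons/km^2, 50-km neighborhood mean |
| land use | `< 0.5` | ag + urban fraction, 50-km neighborhood mean |

Two of these need commentary. The population criterion is stated in the
literature as log10 density below 2; the package compares in linear space
(density below 100 persons/km^2), which is equivalent and avoids log(0) on
empty cells. The storm criterion pairs two limits whose logical combination
is ambiguous when read in isolation; the default is the conjunction reading
(conditions become unsuitable only when major storms occur *and* recur
faster than reefs recover), with `default_thresholds(storm_rule =
"disjunction")` exposing the alternative. The whole set ships as
`inst/extdata/thresholds.yaml` and loads with `read_threshold_yaml()`.

## From raw inputs to per-window metrics

Gridded inputs at monthly-to-decadal cadence are bilinearly regridded to a
common 1-degree grid (`regrid_bilinear()`) and averaged into 5-year windows
(`average_windows()`). Windows tile 1850-2100 labeled by their start year:
`[1850-1854], ..., [2095-2099]`, with the lone terminal year 2100 folded
into the final window (so 50 windows; any other consistent tiling would
shift dates by at most one window). The historical period (1850-2005) and a
scenario (2005-2100) concatenate into one series per site, so pre-2005
exceedance dates are detectable.

Stressor-specific reductions:

- **Thermal stress.** `compute_mmm_climatology()` builds the maximum monthly
  mean (MMM) from weekly SST over a baseline (default 1850-2005);
  `compute_dhw()` accumulates hotspots of at least 1 deg C above MMM over a
  trailing 12-week window (the NOAA Coral Reef Watch convention — sustained
  +1.5 deg C for 12 weeks yields the textbook 18 deg C-weeks);
  `window_dhw_metric()` takes the within-window maximum, the value the
  8 deg C-weeks limit applies to. Trailing sums are computed directly rather
  than as cumulative-sum differences, so they agree exactly with an explicit
  sliding-window oracle.
- **Storms.** `storm_metric()` summarizes a catalog of events (year,
  position, category) into the worst category and the major-storm return
  period over a trailing 20-year span per window. Twenty years is four times
  the 5-year return-period limit — long enough to estimate it, short enough
  to track scenario trends; it is a configurable estimation choice, not a
  literature constant. Events are attributed to a site by shared 1-degree
  cell by default, or by an impact radius.
- **Local stressors.** `neighborhood_population_metric()` and
  `neighborhood_landuse_metric()` take area-weighted (cos-latitude) means
  over raster cells whose centers lie within 50 great-circle km of the site;
  land-use averages run over land cells only, and an open-ocean neighborhood
  scores 0 rather than erroring.
- **Acidification** needs no reduction: Omega_arag fields pass through
  `average_windows()` directly.

Reef locations enter either as point tables or as polygons, which are
projected to a cylindrical equal-area grid (standard parallel 30 deg, a
Behrmann-style choice made here for its simplicity; no specific projection
is canonical for this step) and rasterized to one site per occupied 1-km
cell (`rasterize_reef_polygons()`). Gridded values are then collected at
each site's 1-degree cell center (`sample_at_sites()`), with nearest-center
assignment and ties broken toward the smaller cell index.

## Bias correction

Threshold analyses are sensitive to additive model bias: a model running
0.5 deg C warm crosses a fixed limit decades early for that reason alone.
`compute_bias()` takes the per-pixel difference between empirical and
modeled means over their common historical period, and `apply_bias()` adds
that delta to every projection step. After correction the model's
common-period mean equals the empirical mean at every pixel to floating
tolerance — the closure property that motivates the correction, asserted at
1e-10 in the tests. The delta uses period means rather than month-wise
climatology deltas (a month-wise variant would matter for sub-annual
metrics, but all thresholded metrics here are 5-year statistics); it applies
to climatic variables only, never to population or land use. Pixels with no
empirical record stay missing after correction rather than passing through
uncorrected. `ensemble_mean()` provides a simple missing-aware multi-model
combination of corrected fields.

## Degenerate inputs and numerical choices

- Missing values propagate as missing through regridding (any missing
  bilinear neighbor makes the result missing — conservative near coasts),
  window averaging (all-missing windows stay missing) and sampling.
- Missing suitability flags inherit the previous window's state; leading
  gaps default to suitable. A series that is unsuitable in its only observed
  windows therefore still dates its exceedance correctly.
- Comparisons are strict; ties in nearest-cell assignment break toward the
  smaller (lat, lon) index; return periods are infinite when no major storm
  occurred, which compares correctly against the 5-year limit.
- Weeks are a fixed 52-week calendar with months assigned by mid-week
  day-of-year; incomplete climatology months raise an error naming them.

## The synthetic generator: what it emulates and what it does not

Real inputs for this analysis are multi-gigabyte Earth System Model archives
and global reef/population/land-use products. To make every pipeline stage
testable at desk scale, `generate_world()` builds a 20 x 20 one-degree reef
region (0-20 N, 120-140 E — a compact tropical-to-subtropical band) with 200
sites, 50 windows and three scenarios, in which every cell's crossing year
is *planted*: each stressor series is a monotone trend crossing its
threshold at a chosen window, plus truncated-normal noise bounded below half
the margin between trend and threshold (`plant_crossing_series()`). Bounded
noise trades realism for a crisp guarantee: classification recovers the
planted year *exactly*, so full-pipeline truth recovery is a sharp
pass/fail parameter-recovery test rather than a statistical one.

The planted geography mirrors the projected spatial structure of the real
stressors: heat stress arrives first near the equator and spreads poleward;
acidification first at the highest latitudes of the domain; population
pressure spreads from the western edge and land-use conversion from the
eastern edge; major storms radiate outward from a pantropical band, with
category >= 4 events scheduled annually from each cell's planted year (plus
Poisson background storms of category 1-3, which cannot affect the compound
criterion). Worse scenarios shift every climatic crossing earlier and
steepen its spread, so scenario curves are pointwise ordered by
construction; under strong mitigation (RCP2.6-SSP1) a mid-latitude interior
band of the domain remains suitable through 2100, while under RCP8.5-SSP5 no
cell does. Trend magnitudes are clamped to plausible ranges (DHW in
[2, 14] deg C-weeks around the limit, Omega_arag in [2.7, 3.9], density in
[40, 160] persons/km^2, land use in [0.2, 0.8]).

What the generator does *not* emulate: CMIP5 spatial covariance, real reef
geography and bathymetry, ENSO-like interannual variability, unbounded
observation noise, storm tracks with spatial footprints, or model bias
structure beyond an additive offset. Passing the recovery and dominance
tests therefore demonstrates that the pipeline's logic is exact under its
own definitions — not that the package reproduces any particular published
global percentage, which requires assembling the real archives the pipeline
is built to accept. Neighborhood metrics are unit-tested separately; the
synthetic population and land-use fields carry the 50-km metric values
directly.

Problem sizes used throughout (chosen to keep the full suite in well under a
minute of compute per scenario): 200 sites, 400 cells, 50 windows, 10,000
random flag vectors and 1,000 random SST series for the oracle
cross-checks.

## Worked example

```{r example}
world <- generate_world(scenario_config("RCP8.5-SSP5"), n_sites = 200, seed = 1)
res <- run_world(world)
rec <- truth_recovery(world, res$years)
rec$n_match / rec$n

res$outcomes

curve <- cumulative_fraction(res$outcomes, "overall")
year_reaching_fraction(curve, 0.75)

cohort_mean_year(res$outcomes, viable_after = 2005)

stressor_count_shares(res$outcomes)
```

Threshold sensitivity: loosening every limit can only delay exceedance,
tightening can only advance it — `sensitivity_sweep()` re-runs the
classification under perturbed threshold sets and returns the per-site
years, cumulative curves and summaries for each.

```{r sweep}
base <- default_thresholds()
sw <- sensitivity_sweep(
  world_metrics(world), world$windows,
  list(baseline = base,
       loose = perturb_thresholds(base, list(dhw = 1, arag = -0.05)),
       tight = perturb_thresholds(base, list(dhw = -1, arag = 0.05))),
  baseline = base
)
sw$summary
```

## Limitations

Thresholds are applied independently and combined only by the "any stressor"
rule; no stressor interactions, cumulative-impact weighting, adaptation,
acclimatization or refugia dynamics are modeled — exceedance marks the onset
of permanently out-of-tolerance conditions, not extinction. Cohort averages
("mean date of unsuitability for sites still viable in 2005") are reported
as both mean and median of window label years, since either convention is
defensible; all dates carry 5-year granularity. Percentages are unweighted
shares of reef sites (1-km cells); a latitude-area weighting is available
for gridded strata via the cos-latitude weights used in the neighborhood
metrics. The command-line surface is intentionally thin: the exported
functions compose the whole pipeline, and `scripts/acceptance.R` shows the
end-to-end recipe.
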