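Package: reefhorizon
Title: Multi-Stressor Environmental Suitability Timelines for Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the year after which environmental conditions become
    permanently unsuitable for reef sites under multiple co-occurring
    anthropogenic stressors. From gridded stressor time series (sea-surface
    temperature and degree heating weeks, aragonite saturation state, storm
    catalogs, population density, land use) the pipeline regrids to a common
    one-degree grid, averages into five-year windows, applies per-pixel delta
    bias correction of model output against empirical baselines, thresholds
    each stressor into binary suitability, and derives per-site permanent
    exceedance years, overall unsuitability dates, co-occurring stressor
    counts, cumulative exposure curves and threshold-sensitivity sweeps.
    Includes a synthetic-data generator that plants known threshold-crossing
    years for exact recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
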