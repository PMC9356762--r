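Package: exmort
Title: Excess and Exiguous Mortality Estimation from Weekly Death Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of weekly excess and exiguous mortality from death
    counts stratified by cause of death, place of death, and region. The
    baseline is a modified Farrington algorithm: a quasi-Poisson regression
    with linear trend and a 9+1-level seasonal factor fitted to up to b years
    of history around the target week's seasonal position, with Anscombe
    residual downweighting of past aberrations and two-sided prediction
    intervals computed on the 2/3-power scale. Includes ICD-10 underlying
    cause grouping (respiratory, circulatory, malignant neoplasms, senility,
    COVID-19 exclusion), Monday-start epidemiological week aggregation of
    record-level data, a reporting-delay adjustment for provisional counts
    based on an empirical reporting triangle, a negative-binomial synthetic
    data generator for end-to-end testing without restricted vital
    statistics, and a pipeline that emits weekly and cumulative excess tables
    per stratum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
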