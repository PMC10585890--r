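Package: aqhia
Title: Small-Area Air Pollution Mortality Analysis and Health Impact
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-area studies of long-term air pollution and
    cause-specific mortality in cities with a dominant point source such as
    a harbour. Generates calibrated synthetic cities (census-tract
    geometry, demographic strata, deprivation, pollutant surfaces and
    Poisson death counts), assigns tract exposure as the exact
    area-weighted mean of overlapping raster cells, stratifies tracts by
    distance from the source, fits aggregated Poisson regressions with a
    crude/demographic/socioeconomic adjustment ladder reporting percent
    change per concentration increment, and computes attributable
    fractions and annual attributable deaths against the 2021 WHO air
    quality guideline counterfactuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
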