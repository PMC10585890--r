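# aqhia

Small-area analysis of long-term air pollution and cause-specific
mortality, for cities dominated by a single emission point source such as
a commercial harbour. The package is aimed at environmental
epidemiologists who want a fully testable version of the standard
tract-level workflow: because registry death records and dispersion-model
surfaces are rarely shareable, it couples the analysis machinery with a
calibrated synthetic-city generator in which every true effect is known,
so bias, confidence-interval coverage and type-I error of the whole
pipeline can be measured rather than assumed.

## What it computes

For census tracts indexed by *t* with age–sex strata *s*:

- **Exposure assignment** — the area-weighted mean of a concentration
  raster over each tract polygon,
  `x_t = Σ_c v_c·A(c∩t) / Σ_c A(c∩t)`, with intersection areas computed
  exactly (Sutherland–Hodgman clipping + shoelace areas) and validated
  against an independent point-sampling oracle.
- **Harbour stratification** — tracts within a buffer radius (default
  800 m, centroid rule) of the port centroid versus the rest of the city,
  with 600/800/1000 m sensitivity classification and a descriptive
  summary table by stratum.
- **Aggregated Poisson regression** — deaths(t, s) ~ Poisson with
  log person-years offset and log-linear predictor
  `α + β·x_t (+ age/sex indicators) (+ deprivation indicators)`, the
  three-level adjustment ladder, fit by Fisher scoring with a strict
  convergence contract; effects reported as percent change
  `(e^{5β} − 1)·100` per 5 µg/m³ with Wald 95% intervals.
- **Health impact assessment** — attributable fraction
  `AF = 1 − e^{−β(x − AQG)}` (clamped at zero below the guideline) from
  literature relative risks per 10 µg/m³, and annual attributable deaths
  `AD = Σ_t TD_t·AF_t / years` against the 2021 WHO air quality
  guidelines (PM2.5 5, PM10 15, NO2 10 µg/m³).
- **Synthetic city** — seeded Voronoi tract geometry, exact
  largest-remainder demographic allocation, exponential-decay + smooth
  noise pollutant surfaces calibrated in closed form to target
  harbour/rest means, and hierarchy-consistent Poisson death counts.

## Worked example

```r
library(aqhia)

cfg  <- ancona_preset(seed = 20130L)   # calibrated 722-tract port city
city <- build_city(cfg)
city
#> <city> 722 tracts, 100,343 residents, 5-year window
#>   harbour stratum: 12 tracts, 10.2% of population
#>   deaths: natural 5674, cardiovascular 2133, respiratory 425, cancer 1505, lung_cancer 261

# adjusted association: cardiovascular mortality vs PM2.5, model level 3
sp  <- model_spec("cardiovascular", "pm25", adjustment_level = 3)
des <- build_design(city$tracts, city$deaths, city$exposures,
                    city$stratum, sp, study_years = 5)
percent_change(fit_poisson(des$X, des$y, des$offset), "exposure", 5)
#>   estimate     lower    upper increment
#> 1 5.735427 0.8923514 10.81098         5
```

The estimate is the percent change in cardiovascular mortality per
5 µg/m³ PM2.5 with its Wald 95% interval; this draw's 5.7% (0.9, 10.8)
sits around the generator's true +6.5%, and over replicate cities the
estimator recovers the truth without bias (the test suite measures this).

```r
# annual deaths attributable to exposure above the WHO guidelines
hia <- attributable_deaths(city$deaths, city$exposures, default_crf(),
                           study_years = 5)
hia_report(hia, csv_path = "hia.csv", plot_path = "hia.png")
head(as.data.frame(hia)[, c("cause", "pollutant", "af", "ad")])
#>            cause pollutant         af        ad
#> 1        natural      pm25 0.09908079 112.43688
#> 2 cardiovascular      pm25 0.13140276  56.05642
#> 3    respiratory      pm25 0.12160508  10.33643
#> 4    lung_cancer      pm25 0.15035031   7.84829
#> 5        natural       no2 0.01843449  20.91946
```

`af` is the death-weighted attributable fraction and `ad` the annual
attributable deaths with tract-specific exposure; ~112 natural deaths per
year in this synthetic city would be prevented under PM2.5 guideline
compliance.

`run_pipeline(cfg, "out/")` executes the whole chain — simulate, assign,
stratify, fit the full cause × pollutant × level grid, HIA, figure — and
writes a manifest with md5 digests; identical config and seed reproduce
every data output digest exactly. A thin command-line wrapper with the
same stages ships in `inst/cli/aqhia`.

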