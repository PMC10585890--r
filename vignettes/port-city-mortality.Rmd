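---
title: "Small-area air pollution mortality analysis with a harbour point source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area air pollution mortality analysis with a harbour point source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqhia)
```

## The problem

Port cities concentrate shipping and cargo-handling emissions in a small,
densely populated area. Quantifying the mortality burden of that exposure at
the census-tract level requires four linked pieces of machinery: assigning a
gridded annual-mean concentration surface to irregular tract polygons,
stratifying tracts by distance from the source, relating tract-level death
counts to exposure with aggregated Poisson regression, and translating
exposure above the WHO air quality guidelines (AQG, 2021 annual means:
PM2.5 5, PM10 15, NO2 10 µg/m³) into annual attributable deaths. Registry
death records and proprietary dispersion-model output are rarely public, so
the package pairs the analysis machinery with a synthetic-city generator
whose statistical structure matches what the analysis assumes. That makes
every stage testable end to end: effects are known by construction, and the
estimators can be audited for bias, interval coverage and type-I error.

## The synthetic city

`scenario_config()` collects every knob; `build_city()` assembles the city.

**Geometry.** Census tracts are a seeded Voronoi tessellation of uniform
random points, clipped to the city rectangle. Voronoi cells are computed by
half-plane clipping (each cell starts as the extent and is cut by
perpendicular bisectors, scanned by increasing distance with a circumradius
pruning rule), which reuses the same Sutherland–Hodgman primitive as the
zonal statistics and keeps the tessellation an exact partition: summed cell
areas equal the extent area to machine precision. A rectangular
`grid_tracts` mode provides exact-answer geometry for tests.

**Population.** Stratum populations (five age classes × two sexes) are
apportioned deterministically by largest-remainder allocation, so the
configured margins are hit exactly in integer counts. When
`harbour_pop_share` is set, that share of residents is placed in tracts
whose centroid lies within the harbour radius, proportionally to tract
area within each side — the mechanism by which the calibrated preset puts
exactly 10,258 of 100,343 residents (10.2%) inside the 800 m buffer. Each
tract draws one deprivation category from the configured distribution
(harbour/rest-specific when supplied); the "missing" category is kept as
its own level throughout. The joint age × sex distribution within tracts is
the product of the margins, a deliberate simplification: small-area
age-by-sex cross-tables are rarely published.

**Exposure surfaces.** Cell value = background + amplitude ·
exp(−d/decay_length) + smooth noise, with d the distance to the harbour
centroid. The exponential point-source decay reproduces the harbour/rest
contrast with two interpretable knobs. The noise term is a seeded white
field smoothed with a 7 × 7 box kernel and standardised, giving spatial
correlation at roughly tract scale; its amplitude (`noise_sd`) is chosen in
the preset so the between-tract spread matches the observed
population-weighted SDs (≈4.7 µg/m³ PM2.5, ≈6.3 µg/m³ NO2 outside the
harbour). Without it a pure decay surface would carry far less exposure
variance than a realistic dispersion field and overstate the uncertainty
of any regression run on it. Negative cells under strong noise are clamped
to zero; at the preset's signal-to-background ratio clamping affects well
under 1% of cells and shifts tract means by far less than the ±0.3 µg/m³
calibration check.

**Calibration.** Because the area-weighted tract mean is linear in the
grid values, the tract-mean surface of background + amplitude · decay +
noise decomposes into background + amplitude · (decay tract means) +
(noise tract means). `calibrate_exposure()` first projects the harbour and
rest stratum means out of the noise field (orthogonalising it against the
constant and decay fields in the population-weighted tract-mean metric),
so noise contributes within-stratum spread but cannot move either stratum
mean — with a handful of harbour tracts and spatially correlated noise, an
unprojected field could otherwise demand a negative source amplitude for
some seeds. Matching the two target means is then a 2 × 2 linear system in
(background, amplitude), solved exactly — no search is needed, and
the preset's targets (21 vs 18.1 µg/m³ PM2.5, 25.5 vs 18.4 µg/m³ NO2) are
met by construction up to the zero-clamp. Baseline mortality rates are
rescaled analogously: the expected study-window total per cause is linear
in the cause's rate scale, so `calibrate_rates()` rescales each cause to
its target total (5,584 natural; 2,051 cardiovascular; 395 respiratory;
1,594 cancer; 278 lung cancer over five years) given the realised
population, deprivation and exposure.

**Deaths.** Natural deaths per (tract, stratum) cell are Poisson with mean
person-years × baseline rate × exp(β·x + γ_ses), person-years = population
× 5 with a static population (the simplest reading of a fixed five-year
denominator). Sub-causes are drawn by multinomial thinning of the natural
count (lung cancer as a further binomial thinning of cancer), so the cause
hierarchy — cardiovascular + respiratory + cancer ≤ natural, lung cancer ≤
cancer — holds in every draw while each sub-cause count remains marginally
Poisson with its own rate. Extreme configurations whose implied thinning
probabilities exceed one are rejected with an explanatory error rather
than silently truncated. The preset's true effects are log-linear in PM2.5:
+2.5% (natural), +6.5% (cardiovascular) and +15.3% (lung cancer) per
5 µg/m³, zero for respiratory and total cancer, plus a modest deprivation
gradient (up to +12% for the most deprived category). All randomness flows
from a single master seed through fixed per-stage offsets, so a config and
seed determine the city bit for bit.

## Zonal statistics

`assign_exposure()` implements the area-weighted mean exactly: the tract
polygon is clipped to each candidate cell rectangle with
Sutherland–Hodgman half-plane clipping and the intersection area computed
by the shoelace formula, giving x_t = Σ v_c·A(c∩t) / Σ A(c∩t). Cells that
merely touch the boundary have zero intersection area and contribute
nothing, so cell-ownership conventions are irrelevant. NODATA cells are
excluded from numerator and denominator (renormalising over valid area),
with a warning when valid coverage drops below 99%. Polygons must be
simple (self-intersections are rejected; holes are unsupported), and all
coordinates are planar metres — the package performs no CRS
transformations, which is the documented input contract.
`rasterized_mean_oracle()` is an intentionally independent check: it
subdivides each cell into subcells and point-in-polygon-tests their
centres, converging to the clipped result as the subdivision grows. Tests
require 1% agreement at 32 subdivisions over random convex tracts, plus
exact linearity in the grid and translation equivariance at 1e-10.

## Harbour stratification

A tract belongs to the harbour stratum iff its polygon centroid lies within
the buffer radius of the harbour centroid — the simplest whole-tract rule,
used by default with an 800 m radius. Because a buffer radius alone does
not determine a whole-tract membership rule, two alternatives are provided: fractional-area overlap ≥ 50% (evaluated on a
deterministic point lattice) and a square buffer (some workflows describe
an 800 × 800 m box rather than a circular radius). `sensitivity_radii()`
re-runs the classification over 600/800/1000 m, with harbour population
necessarily monotone in the radius. `descriptive_table()` reproduces the
descriptive margins — population, age/sex, deprivation, population-weighted
exposure mean and SD (SDs weighted across tracts by population), and
cause-specific deaths — by stratum and total.

## Regression

Adjustment for age and sex with aggregated outcomes is implemented the
standard way for rate data: one analysis row per tract × age-sex stratum,
a log person-years offset, and indicator covariates; the exposure is
constant within tract. The ladder is: level 1, intercept + exposure only;
level 2, + age-class and sex indicators; level 3, + deprivation indicators
(reference very_high, missing kept as a level). Defaults for reference
categories are age 35–64, male, very_high — changing them must not move
the exposure estimate, and a test enforces that. `fit_poisson()` is a
Fisher-scoring (IRLS) maximiser with a deliberately strict convergence
contract — score max-norm < 1e-8 and relative deviance change < 1e-10
within 100 iterations — and covariance from the inverse Fisher information;
divergence and rank deficiency are flagged errors, never silent output.
Intervals are Wald on the log scale, reported as percent change
(exp(increment·β) − 1)·100 per 5 µg/m³ by default (the increment is always
stated in the output). No overdispersion adjustment is applied by default;
with the generator's exactly-Poisson counts the scale is 1, and real
aggregated registry data should be checked before trusting the intervals.

At the preset's scale the design is validated by simulation: over 500
replicate cities the mean recovered cardiovascular percent change is
required to fall within ±0.5 points of the true 6.5 per 5 µg/m³, 95%
interval coverage within [92.5%, 97.5%], and the type-I error of a
null-effect city inside a 99% binomial band around 5%.

## Health impact assessment

`beta_from_rr()` converts literature relative risks per 10 µg/m³ to
log-linear coefficients (β = ln RR / 10). The attributable fraction for
excess exposure Δ = exposure − AQG is AF = (e^{βΔ} − 1)/e^{βΔ} =
1 − e^{−βΔ}, the standard (RR − 1)/RR form evaluated at the excess; the
two algebraically distinct forms are compared to 1e-12 in tests. Negative
excess is clamped to AF = 0: the counterfactual is guideline compliance,
and deaths "prevented" below the guideline are not credited. Annual
attributable deaths are AD = Σ_t TD_t·AF(β, x_t)/years with tract-specific
exposures by default; a citywide population-weighted-mean mode supports
aggregate diagnostics, and the two coincide exactly when exposure is
spatially constant. Uncertainty substitutes the RR confidence bounds
deterministically. The bundled `default_crf()` carries PM2.5 risks of 1.08
(1.06–1.09) for natural, 1.11 (1.09–1.14) cardiovascular, 1.10 (1.03–1.18)
respiratory and 1.12 (1.07–1.16) lung-cancer mortality per 10 µg/m³; the
NO2 natural-mortality entry (1.02, 1.01–1.04) is a placeholder from the
broader NO2 literature and should be reviewed for any substantive use.
On the calibrated preset the citywide-mean PM2.5/natural diagnostic is
checked against a deliberately wide plausibility band of 60–130 deaths per
year, not a point value: with a population-weighted mean near 18.4 µg/m³,
AF ≈ 1 − exp(−ln(1.08)/10 · 13.4) ≈ 0.098 of ~1,117 annual natural deaths.

## Numerical and design notes

- Geometry tolerances: consecutive duplicate vertices from clipping are
  dropped at 1e-12; the Voronoi neighbour scan stops once the next seed is
  beyond twice the current cell circumradius, which provably cannot cut.
- Ties in largest-remainder apportionment break by index order, keeping
  allocation deterministic.
- The grid is stored lower-left-row-first internally; the ESRI ASCII
  boundary flips to the format's north-first rows. Grid values and GeoJSON
  coordinates are written at 17 significant digits so round trips are
  bitwise exact; determinism tests compare md5 digests of outputs.
- The PNG figure is presentation output and sits outside the determinism
  contract (encoders may embed environment-dependent metadata); every
  data output is digest-checked.
- Problem sizes used by the test suite: the full 722-tract, 100,343-resident
  preset for calibration, recovery (500 replicates) and pipeline checks;
  a 9-tract grid city and 200 replicates for the per-cell Poisson
  mean-variance property; 50 random tract/grid pairs for the zonal oracle.

## What passing tests do and do not show

The generator draws exactly the model the regression fits (log-linear
rates, multiplicative stratum effects, spatially smooth exposure,
deprivation independent of exposure). Passing recovery and coverage
checks therefore validates the estimator and its implementation, not the
model's adequacy for real registry data, where exposure error, residual
confounding (smoking, occupation), spatial autocorrelation of mortality,
population mobility and within-tract heterogeneity all operate. The
harbour contrast in the synthetic city flows entirely through the
calibrated exposure surfaces; any excess found by the harbour-indicator
analysis beyond that is sampling noise. Known limitations: no
overdispersion in the generator; static population (no migration or
demographic projection); no dispersion modelling or meteorology —
surfaces are parametric stand-ins; centroid-based buffer membership as
the default whole-tract rule; holes in tract polygons unsupported.
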