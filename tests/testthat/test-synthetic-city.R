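test_that("grid tiling mode produces the forced exact tiling", {
  cfg <- scenario_config(n_tracts = 4, extent = c(0, 0, 2000, 2000),
                         harbour_centroid = c(1000, 1000),
                         tract_mode = "grid_tracts", seed = 3)
  tr <- generate_tracts(cfg)
  expect_equal(nrow(tr), 4)
  areas <- vapply(tr$geometry, polygon_area, numeric(1))
  expect_equal(areas, rep(1e6, 4))  # four 1 x 1 km squares
  widths <- vapply(tr$geometry, function(g) diff(range(g[, 1])), numeric(1))
  expect_equal(widths, rep(1000, 4))
})

test_that("voronoi tracts partition the extent and are seed-deterministic", {
  cfg <- ancona_preset()
  tr1 <- suppressMessages(generate_tracts(cfg))
  expect_equal(nrow(tr1), 722)
  areas <- vapply(tr1$geometry, polygon_area, numeric(1))
  ext_area <- (cfg$extent[3] - cfg$extent[1]) * (cfg$extent[4] - cfg$extent[2])
  expect_lt(abs(sum(areas) / ext_area - 1), 1e-6)
  tr2 <- suppressMessages(generate_tracts(cfg))
  expect_identical(tr1$geometry, tr2$geometry)
  expect_identical(tr1$ses_category, tr2$ses_category)
  # a different seed moves the tessellation
  cfg2 <- ancona_preset(seed = 999L)
  tr3 <- generate_tracts(cfg2)
  expect_false(identical(tr1$geometry, tr3$geometry))
})

test_that("tract generation rejects degenerate densities and extents", {
  expect_error(scenario_config(n_tracts = 4, extent = c(0, 0, 0, 2000),
                               harbour_centroid = c(0, 0)),
               "degenerate")
  cfg <- scenario_config(n_tracts = 1000, extent = c(0, 0, 1000, 1000),
                         harbour_centroid = c(500, 500), grid_cell_size = 500)
  expect_error(generate_tracts(cfg), "16 tracts per grid cell")
})

test_that("exposure surface: constant field, monotone decay, non-negativity", {
  cfg <- scenario_config(
    n_tracts = 4, extent = c(0, 0, 4000, 4000), harbour_centroid = c(2100, 1900),
    pollutants = list(pm25 = list(background = 18.1, amplitude = 0, noise_sd = 0)),
    tract_mode = "grid_tracts", seed = 5)
  g0 <- generate_exposure_surface(cfg, "pm25")
  expect_true(all(g0$values == 18.1))
  cfg$pollutants$pm25$amplitude <- 5
  g1 <- generate_exposure_surface(cfg, "pm25")
  # without noise the cell containing the source attains the maximum
  ci <- floor((1900 - 0) / 500) + 1
  cj <- floor((2100 - 0) / 500) + 1
  expect_equal(g1$values[ci, cj], max(g1$values))
  expect_true(all(g1$values >= 0))
  # noise field is seeded and reproducible
  cfg$pollutants$pm25$noise_sd <- 2
  expect_identical(generate_exposure_surface(cfg, "pm25")$values,
                   generate_exposure_surface(cfg, "pm25")$values)
})

test_that("death simulation matches its Poisson expectation oracle", {
  cfg <- small_scenario()
  tr <- generate_tracts(cfg)
  ex <- data.frame(tract_id = tr$tract_id, pollutant = "pm25",
                   mean = 18, coverage_fraction = 1)
  # all baseline rates zero -> no deaths
  cfg0 <- cfg; cfg0$baseline_rates[] <- 0
  expect_equal(sum(simulate_deaths(tr, ex, cfg0)$deaths), 0)
  # beta = 0, uniform rates: E[total] = sum person-years x rate, exactly
  expected <- sum(tract_populations(tr)) * cfg$study_years *
    cfg$baseline_rates["natural", 1]
  d <- simulate_deaths(tr, ex, cfg)
  obs <- sum(d$deaths[d$cause == "natural"])
  expect_lt(abs(obs - expected), 4 * sqrt(expected))
  # determinism of the deaths stream
  expect_identical(simulate_deaths(tr, ex, cfg)$deaths,
                   simulate_deaths(tr, ex, cfg)$deaths)
  expect_false(identical(simulate_deaths(tr, ex, cfg, seed = 1)$deaths,
                         simulate_deaths(tr, ex, cfg, seed = 2)$deaths))
})

test_that("cause hierarchy holds in every simulated draw", {
  cfg <- small_scenario()
  tr <- generate_tracts(cfg)
  ex <- data.frame(tract_id = tr$tract_id, pollutant = "pm25",
                   mean = 20, coverage_fraction = 1)
  for (s in 1:5) {
    d <- simulate_deaths(tr, ex, cfg, seed = s)
    expect_silent(validate_death_table(d))
    w <- tapply(d$deaths, d$cause, sum)
    expect_lte(w["cardiovascular"] + w["respiratory"] + w["cancer"], w["natural"])
    expect_lte(w["lung_cancer"], w["cancer"])
  }
  # an extreme effect size that breaks the hierarchy is rejected, not drawn
  cfg_bad <- cfg
  cfg_bad$true_beta["cardiovascular"] <- 0.2
  expect_error(simulate_deaths(tr, ex, cfg_bad), "hierarchy")
})

test_that("per-cell death counts are Poisson with the analytic mean", {
  # 200 replicates at a fixed small scenario; z-test per (tract, stratum)
  # cell with a Bonferroni-controlled family alpha of 0.001
  cfg <- small_scenario(seed = 11L)
  tr <- generate_tracts(cfg)
  ex <- data.frame(tract_id = tr$tract_id, pollutant = "pm25",
                   mean = 19, coverage_fraction = 1)
  lam <- aqhia:::expected_rates(tr, ex, cfg)$natural
  reps <- 200
  acc <- 0
  for (r in seq_len(reps)) {
    d <- simulate_deaths(tr, ex, cfg, seed = 5000 + r)
    dn <- d[d$cause == "natural", ]
    m <- matrix(dn$deaths, nrow(tr), 10)
    acc <- acc + m
  }
  keep <- lam > 0
  z <- (acc[keep] / reps - lam[keep]) / sqrt(lam[keep] / reps)
  crit <- qnorm(1 - 0.001 / (2 * sum(keep)))
  expect_lt(max(abs(z)), crit)
})

test_that("calibrated preset reproduces the reference-population margins", {
  city <- ancona_city_cached()
  pops <- tract_populations(city$tracts)
  pop <- rowSums(pops)
  expect_equal(sum(pop), 100343)
  expect_equal(nrow(city$tracts), 722)
  # 10.2% of residents within 800 m of the harbour centroid
  expect_equal(attr(city$stratum, "harbour_pop_share"), 10258 / 100343,
               tolerance = 1e-6)
  # expected study-window cause totals equal the calibration targets
  expect_equal(unname(city$expected_deaths[causes()]),
               c(5584, 2051, 395, 1594, 278), tolerance = 1e-8)
  # observed totals are a Poisson draw around them
  obs <- tapply(city$deaths$deaths, city$deaths$cause, sum)[causes()]
  expect_true(all(abs(obs - city$expected_deaths[causes()]) <
                    4 * sqrt(city$expected_deaths[causes()])))
  # population-weighted exposure means by stratum hit the surface targets
  h <- city$stratum$harbour
  for (p in c("pm25", "no2")) {
    ex <- city$exposures[city$exposures$pollutant == p, ]
    x <- ex$mean[match(city$tracts$tract_id, ex$tract_id)]
    tgt <- city$config$exposure_targets[[p]]
    expect_lt(abs(weighted.mean(x[h], pop[h]) - tgt[["harbour"]]), 0.3)
    expect_lt(abs(weighted.mean(x[!h], pop[!h]) - tgt[["rest"]]), 0.3)
  }
})
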