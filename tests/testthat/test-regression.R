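test_that("design matrix has the level-specific structure", {
  cfg <- small_scenario(n_tracts = 2L, seed = 21L)
  cfg$extent <- c(0, 0, 1000, 2000)
  tr <- generate_tracts(cfg)
  ex <- data.frame(tract_id = tr$tract_id, pollutant = "pm25",
                   mean = c(18, 21), coverage_fraction = 1)
  d <- simulate_deaths(tr, ex, cfg)
  st <- classify_harbour(tr, c(500, 500), 800)
  d1 <- build_design(tr, d, ex, st, model_spec("natural", "pm25", 1), 5)
  expect_equal(colnames(d1$X), c("(Intercept)", "exposure"))
  expect_equal(nrow(d1$X), 20)  # 2 tracts x 10 strata, none empty
  d2 <- build_design(tr, d, ex, st, model_spec("natural", "pm25", 2), 5)
  expect_equal(ncol(d2$X), 2 + 4 + 1)
  d3 <- build_design(tr, d, ex, st, model_spec("natural", "pm25", 3), 5)
  # two tracts carry at most two deprivation categories
  expect_lte(ncol(d3$X), 2 + 5 + 2)
  # exposure is constant within tract and offsets are log person-years
  expect_equal(sort(unique(d1$X[, "exposure"])), c(18, 21))
  expect_equal(d1$offset, log(d1$meta$py))
  # all-zero outcome refused
  d0 <- d; d0$deaths <- 0L
  expect_error(build_design(tr, d0, ex, st, model_spec("natural", "pm25", 1), 5),
               "all-zero outcome")
})

test_that("IRLS matches closed-form Poisson MLEs exactly", {
  # intercept-only: beta0 = log(sum y / sum exp(offset))
  fit <- fit_poisson(matrix(1, 2, 1), c(3, 7), log(c(10, 10)))
  expect_equal(unname(fit$coefficients), log(0.5), tolerance = 1e-12)
  expect_true(fit$converged)
  # two-group model: exp(beta) is the exact ratio of group rates; counts
  # follow the harbour/rest natural-mortality margins over 5 years
  X <- cbind(1, c(1, 0))
  y <- c(581, 5003)
  off <- log(5 * c(10258, 90085))
  fit2 <- fit_poisson(X, y, off)
  rr_closed <- (581 / (5 * 10258)) / (5003 / (5 * 90085))
  expect_equal(exp(fit2$coefficients[2]), rr_closed,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(round(rr_closed, 4), 1.0198)
  # covariance is symmetric positive definite at the optimum
  expect_equal(fit2$vcov, t(fit2$vcov))
  expect_true(all(eigen(fit2$vcov, only.values = TRUE)$values > 0))
})

test_that("IRLS agrees with glm() on 20 seeded random datasets", {
  set.seed(4242)
  for (i in 1:20) {
    n <- 60
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    off <- log(runif(n, 50, 500))
    eta <- -4 + 0.1 * X[, 2] + 0.3 * X[, 3] + off
    y <- rpois(n, exp(eta))
    if (sum(y) == 0) next
    fit <- fit_poisson(X, y, off)
    g <- suppressWarnings(glm.fit(X, y, offset = off, family = poisson()))
    expect_lt(max(abs(fit$coefficients - g$coefficients)), 1e-6)
  }
})

test_that("rank deficiency is reported with the aliased column", {
  X <- cbind(`(Intercept)` = 1, a = c(1, 0, 1, 0), b = c(1, 0, 1, 0))
  expect_error(fit_poisson(X, c(1, 2, 3, 4)), "aliased column")
})

test_that("percent change transforms and bounds are coherent", {
  fit <- list(coefficients = c(exposure = 0),
              vcov = matrix(0.0001, 1, 1, dimnames = list("exposure", "exposure")),
              converged = TRUE)
  pc0 <- percent_change(fit, "exposure", 5)
  expect_equal(pc0$estimate, 0)
  expect_lt(pc0$lower, 0); expect_gt(pc0$upper, 0)
  # RR 1.08 per 10 reported per 5: (1.08^0.5 - 1) * 100
  fit$coefficients <- c(exposure = log(1.08) / 10)
  pc5 <- percent_change(fit, "exposure", 5)
  expect_equal(pc5$estimate, (sqrt(1.08) - 1) * 100, tolerance = 1e-10)
  expect_equal(pc5$estimate, 3.923048, tolerance = 1e-6)
  # algebraic consistency: per-10 change = (per-5 RR)^2 - 1
  pc10 <- percent_change(fit, "exposure", 10)
  expect_equal(pc10$estimate / 100, (pc5$estimate / 100 + 1)^2 - 1,
               tolerance = 1e-12)
  expect_true(pc5$lower <= pc5$estimate && pc5$estimate <= pc5$upper)
  fit$converged <- FALSE
  expect_error(percent_change(fit, "exposure", 5), "converge")
})

test_that("exposure shift moves only the intercept; rescaling scales beta", {
  city <- ancona_city_cached()
  sp <- model_spec("cardiovascular", "pm25", 2)
  des <- suppressMessages(build_design(city$tracts, city$deaths, city$exposures,
                                       city$stratum, sp, 5))
  fit <- fit_poisson(des$X, des$y, des$offset)
  Xs <- des$X; Xs[, "exposure"] <- Xs[, "exposure"] + 7
  fit_s <- fit_poisson(Xs, des$y, des$offset)
  expect_equal(fit_s$coefficients["exposure"], fit$coefficients["exposure"],
               tolerance = 1e-10)
  expect_equal(fit_s$coefficients["(Intercept)"],
               fit$coefficients["(Intercept)"] - 7 * fit$coefficients["exposure"],
               tolerance = 1e-8)
  Xk <- des$X; Xk[, "exposure"] <- Xk[, "exposure"] * 4
  fit_k <- fit_poisson(Xk, des$y, des$offset)
  expect_equal(fit_k$coefficients["exposure"] * 4, fit$coefficients["exposure"],
               tolerance = 1e-10)
})

test_that("reference-category choice does not move the exposure estimate", {
  city <- ancona_city_cached()
  sp_a <- model_spec("natural", "pm25", 3)
  sp_b <- model_spec("natural", "pm25", 3, age_reference = "75+",
                     sex_reference = "female", ses_reference = "low")
  fa <- suppressMessages(build_design(city$tracts, city$deaths, city$exposures,
                                      city$stratum, sp_a, 5))
  fb <- suppressMessages(build_design(city$tracts, city$deaths, city$exposures,
                                      city$stratum, sp_b, 5))
  fit_a <- fit_poisson(fa$X, fa$y, fa$offset)
  fit_b <- fit_poisson(fb$X, fb$y, fb$offset)
  expect_equal(fit_a$coefficients["exposure"], fit_b$coefficients["exposure"],
               tolerance = 1e-8)
})

test_that("crude and demographically adjusted estimates agree without confounding", {
  # demographics are allocated independently of exposure, so model levels
  # 1 and 2 estimate the same quantity
  city <- ancona_city_cached()
  out <- suppressMessages(run_association_suite(
    city, causes_run = "cardiovascular", pollutants = "pm25",
    levels = 1:2, harbour = FALSE))
  expect_equal(nrow(out), 2)
  expect_true(all(out$converged))
  expect_lt(abs(out$estimate[1] - out$estimate[2]), 2)
})

test_that("association suite covers the requested grid and survives failures", {
  city <- ancona_city_cached()
  out <- suppressMessages(run_association_suite(
    city, causes_run = "lung_cancer", pollutants = c("pm25", "no2")))
  expect_equal(nrow(out), 3 * 3)  # (2 pollutants + harbour) x 3 levels
  expect_setequal(unique(out$pollutant), c("pm25", "no2", "harbour"))
  # a cause with no deaths yields flagged rows, not an abort
  d0 <- city$deaths
  d0$deaths[d0$cause == "respiratory"] <- 0L
  city0 <- city; city0$deaths <- d0
  out0 <- suppressMessages(run_association_suite(
    city0, causes_run = c("respiratory", "natural"), pollutants = "pm25",
    levels = 1, harbour = FALSE))
  expect_false(out0$converged[out0$cause == "respiratory"])
  expect_true(out0$converged[out0$cause == "natural"])
})
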