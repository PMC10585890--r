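test_that("beta from RR and its round trip", {
  expect_equal(beta_from_rr(1.0, 10), 0)
  expect_equal(beta_from_rr(1.08, 10), 0.0076961, tolerance = 1e-5)
  expect_equal(exp(10 * beta_from_rr(1.08, 10)), 1.08, tolerance = 1e-12)
  expect_error(beta_from_rr(0, 10), "positive")
  expect_error(beta_from_rr(1.1, -1), "positive")
})

test_that("attributable fraction: clamping, worked value, algebraic identity", {
  b <- beta_from_rr(1.08, 10)
  expect_equal(attributable_fraction(b, 5, 5), 0)
  expect_equal(attributable_fraction(b, 3, 5), 0)  # below guideline clamps to 0
  expect_lt(abs(attributable_fraction(b, 18.1, 5) - 0.0959), 1e-4)
  # two algebraically independent forms agree
  af1 <- attributable_fraction(b, 18.1, 5)
  rr_d <- exp(b * (18.1 - 5))
  expect_equal(af1, (rr_d - 1) / rr_d, tolerance = 1e-12)
  # AF = 1 - RR^(-delta/increment) for random (RR, delta)
  set.seed(55)
  for (i in 1:100) {
    rr <- runif(1, 1.0, 1.6); d <- runif(1, 0, 30)
    expect_lt(abs(attributable_fraction(beta_from_rr(rr, 10), d, 0) -
                  (1 - rr^(-d / 10))), 1e-12)
  }
  # AF vanishes at the null and approaches (without crossing) 1
  expect_equal(attributable_fraction(0, 50, 5), 0)
  expect_lt(attributable_fraction(0.05, 60, 0), 1)
  expect_lte(attributable_fraction(0.5, 1000, 0), 1)  # float saturation
})

test_that("CRF set validation enforces ordering and positivity", {
  crf <- default_crf()
  expect_s3_class(crf, "crf_set")
  bad <- crf; bad$rr_lower[1] <- bad$rr[1] + 0.1
  expect_error(validate_crf_set(bad), "lower <= central <= upper")
  bad2 <- crf; bad2$aqg[1] <- -1
  expect_error(validate_crf_set(bad2), "AQG")
})

mini_deaths <- function(td, tract = "A", cause = "natural") {
  data.frame(tract_id = tract, cause = cause, age_class = "75+",
             sex = "female", deaths = td, stringsAsFactors = FALSE)
}

test_that("attributable deaths: direct product, zero at guideline, bounds", {
  crf <- default_crf()[1, ]  # PM2.5, natural
  ex <- function(x) data.frame(tract_id = "A", pollutant = "pm25", mean = x,
                               coverage_fraction = 1)
  # uniform exposure at the guideline -> zero attributable deaths
  expect_equal(attributable_deaths(mini_deaths(500), ex(5), crf, 5)$ad, 0)
  # single tract, TD = 500 over 5 years at the worked AF
  res <- attributable_deaths(mini_deaths(500), ex(18.1), crf, 5)
  expect_equal(res$ad, 500 * 0.0959 / 5, tolerance = 1e-3)
  expect_equal(res$annual_deaths, 100)
  expect_true(res$ad_lower <= res$ad && res$ad <= res$ad_upper)
  # AD never exceeds annual deaths for the cause
  expect_lt(res$ad, res$annual_deaths)
  # strict monotonicity under a uniform +1 shift above the guideline
  res2 <- attributable_deaths(mini_deaths(500), ex(19.1), crf, 5)
  expect_gt(res2$ad, res$ad)
})

test_that("tract-level and citywide AD coincide under constant exposure", {
  crf <- default_crf()[1:2, ]
  d <- rbind(mini_deaths(80, "A"), mini_deaths(120, "B"),
             mini_deaths(30, "A", "cardiovascular"),
             mini_deaths(50, "B", "cardiovascular"))
  ex <- data.frame(tract_id = c("A", "B"), pollutant = "pm25", mean = 17,
                   coverage_fraction = 1)
  pop <- c(A = 1000, B = 3000)
  r_t <- attributable_deaths(d, ex, crf, 5)
  r_c <- attributable_deaths(d, ex, crf, 5, mode = "citywide", population = pop)
  expect_equal(r_t$ad, r_c$ad, tolerance = 1e-10)
  # per-tract breakdown sums to the total
  bt <- attr(r_t, "by_tract")
  expect_equal(sum(bt$ad_annual[bt$cause == "natural"]),
               r_t$ad[r_t$cause == "natural"], tolerance = 1e-12)
})

test_that("missing exposure for a tract with deaths is a hard failure", {
  crf <- default_crf()[1, ]
  d <- rbind(mini_deaths(10, "A"), mini_deaths(10, "B"))
  ex <- data.frame(tract_id = "A", pollutant = "pm25", mean = 20,
                   coverage_fraction = 1)
  expect_error(attributable_deaths(d, ex, crf, 5), "lacks a pm25 exposure")
})

test_that("HIA report writes the CSV/figure and keeps zero scenarios at zero", {
  crf <- default_crf()
  d <- do.call(rbind, lapply(unique(crf$cause), function(cz) mini_deaths(100, cause = cz)))
  ex <- rbind(
    data.frame(tract_id = "A", pollutant = "pm25", mean = 5, coverage_fraction = 1),
    data.frame(tract_id = "A", pollutant = "no2", mean = 10, coverage_fraction = 1))
  res <- attributable_deaths(d, ex, crf, 5)
  expect_equal(nrow(res), nrow(crf))  # one row per requested cause x pollutant
  expect_true(all(res$ad == 0))      # compliant exposures: all bars at zero
  csv <- tempfile(fileext = ".csv"); png <- tempfile(fileext = ".png")
  hia_report(res, csv_path = csv, plot_path = png)
  expect_true(file.exists(csv) && file.exists(png))
  expect_equal(nrow(read.csv(csv)), nrow(crf))
  expect_error(hia_report(res[0, ]), "empty")
})
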