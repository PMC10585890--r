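# Simulation of cause-specific death counts and city assembly.

# linear predictor components shared by simulation and calibration:
# expected natural/cause rates per (tract, stratum) cell
expected_rates <- function(tracts, exposures, config) {
  pops <- tract_populations(tracts)
  py <- pops * config$study_years
  sim_p <- config$sim_pollutant
  ex <- exposures[exposures$pollutant == sim_p, ]
  if (nrow(ex) == 0) stop("no exposure values for simulation pollutant ", sim_p, call. = FALSE)
  x <- ex$mean[match(tracts$tract_id, ex$tract_id)]
  if (any(is.na(x) & rowSums(pops) > 0)) {
    stop("populated tract without an exposure value", call. = FALSE)
  }
  gam <- config$ses_effects[tracts$ses_category]
  lam <- lapply(causes(), function(cz) {
    tract_mult <- exp(config$true_beta[[cz]] * x + gam)  # n_tracts
    sweep(py, 1, tract_mult, `*`) *
      matrix(config$baseline_rates[cz, strata_ids()], nrow(py), 10, byrow = TRUE)
  })
  names(lam) <- causes()
  if (any(vapply(lam, function(m) any(!is.finite(m) | m < 0), logical(1)))) {
    stop("non-finite or negative expected death rate: check true_beta, ",
         "ses_effects and baseline_rates", call. = FALSE)
  }
  lam
}

#' Rescale baseline rates so expected cause totals hit configured targets
#'
#' With the multiplicative model the expected study-window total per cause
#' is linear in the cause's baseline-rate scale, so each cause is rescaled
#' by target / expected, evaluated against the realised tract populations,
#' deprivation categories and exposure surface.
#'
#' @param tracts A `tract_table`.
#' @param exposures Exposure data.frame (must include the simulation
#'   pollutant).
#' @param config A [scenario_config()] with `cause_totals` set.
#' @return The config with `baseline_rates` rescaled.
#' @export
calibrate_rates <- function(tracts, exposures, config) {
  if (is.null(config$cause_totals)) return(config)
  lam <- expected_rates(tracts, exposures, config)
  for (cz in names(config$cause_totals)) {
    tot <- sum(lam[[cz]])
    if (tot <= 0) stop("cannot calibrate cause with zero expected deaths: ", cz, call. = FALSE)
    config$baseline_rates[cz, ] <- config$baseline_rates[cz, ] *
      config$cause_totals[[cz]] / tot
  }
  config
}

#' Simulate cause-specific death counts
#'
#' Natural deaths per (tract, stratum) cell are Poisson with mean
#' person-years x baseline rate x exp(beta * exposure + gamma_ses), with
#' person-years = population x study_years. Cardiovascular, respiratory and
#' cancer deaths are drawn as a multinomial thinning of the natural count
#' (so sub-cause counts can never exceed the natural count) and lung cancer
#' as a binomial thinning of cancer; the thinning probabilities are the
#' ratios of cause-specific to natural expected rates, which makes each
#' sub-cause count marginally Poisson with its own expected rate.
#'
#' @param tracts A `tract_table`.
#' @param exposures Exposure data.frame as from [assign_exposure()],
#'   containing the configured simulation pollutant.
#' @param config A [scenario_config()].
#' @param seed Optional integer overriding the config-derived deaths
#'   stream; used for replicate draws at fixed scenario.
#' @return A `death_table`: long data.frame (tract_id, cause, age_class,
#'   sex, deaths) over the study window.
#' @export
simulate_deaths <- function(tracts, exposures, config, seed = NULL) {
  lam <- expected_rates(tracts, exposures, config)
  p_cv <- lam$cardiovascular / lam$natural
  p_rs <- lam$respiratory / lam$natural
  p_ca <- lam$cancer / lam$natural
  p_lc <- lam$lung_cancer / lam$cancer
  zero <- lam$natural == 0
  p_cv[zero] <- p_rs[zero] <- p_ca[zero] <- 0
  p_lc[lam$cancer == 0] <- 0
  if (any(p_cv + p_rs + p_ca > 1 + 1e-12) || any(p_lc > 1 + 1e-12)) {
    stop("cause hierarchy violated: sub-cause expected rates exceed the ",
         "natural (or cancer) rate in some cell; lower true_beta or adjust ",
         "baseline_rates", call. = FALSE)
  }
  draw <- function() {
    n_nat <- stats::rpois(length(lam$natural), lam$natural)
    # multinomial via sequential conditional binomials, vectorised
    n_cv <- stats::rbinom(length(n_nat), n_nat, pmin(p_cv, 1))
    p2 <- ifelse(p_cv < 1, p_rs / (1 - p_cv), 0)
    n_rs <- stats::rbinom(length(n_nat), n_nat - n_cv, pmin(p2, 1))
    p3 <- ifelse(p_cv + p_rs < 1, p_ca / (1 - p_cv - p_rs), 0)
    n_ca <- stats::rbinom(length(n_nat), n_nat - n_cv - n_rs, pmin(p3, 1))
    n_lc <- stats::rbinom(length(n_nat), n_ca, pmin(p_lc, 1))
    list(natural = n_nat, cardiovascular = n_cv, respiratory = n_rs,
         cancer = n_ca, lung_cancer = n_lc)
  }
  counts <- if (is.null(seed)) {
    with_stream(config$seed, "deaths", draw())
  } else {
    with_stream(seed, "deaths", draw())
  }
  n_t <- nrow(tracts)
  cells <- expand.grid(tract = seq_len(n_t), stratum = strata_ids(),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(causes(), function(cz) {
    m <- matrix(counts[[cz]], n_t, 10)
    data.frame(tract_id = tracts$tract_id[cells$tract], cause = cz,
               age_class = stratum_age(cells$stratum),
               sex = stratum_sex(cells$stratum),
               deaths = as.integer(m), stringsAsFactors = FALSE)
  }))
  class(out) <- c("death_table", "data.frame")
  out
}

#' Validate a death table on ingest
#'
#' Checks non-negative integer counts, known cause/age/sex labels, and the
#' cause hierarchy: per tract and stratum, cardiovascular + respiratory +
#' cancer <= natural and lung cancer <= cancer.
#'
#' @param deaths A long-format death data.frame.
#' @return The input, invisibly, or an error.
#' @export
validate_death_table <- function(deaths) {
  need <- c("tract_id", "cause", "age_class", "sex", "deaths")
  if (!all(need %in% names(deaths))) {
    stop("death table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(deaths$deaths < 0) || any(deaths$deaths != round(deaths$deaths))) {
    stop("death counts must be non-negative integers", call. = FALSE)
  }
  if (!all(deaths$cause %in% causes())) stop("unknown cause label", call. = FALSE)
  if (!all(deaths$age_class %in% age_classes())) stop("unknown age class", call. = FALSE)
  if (!all(deaths$sex %in% sexes())) stop("unknown sex label", call. = FALSE)
  key <- interaction(deaths$tract_id, deaths$age_class, deaths$sex, drop = TRUE)
  by_cause <- function(cz) {
    v <- tapply(deaths$deaths[deaths$cause == cz], key[deaths$cause == cz], sum)
    full <- stats::setNames(rep(0, nlevels(key)), levels(key))
    full[names(v)] <- v
    full
  }
  nat <- by_cause("natural")
  sub <- by_cause("cardiovascular") + by_cause("respiratory") + by_cause("cancer")
  if (any(sub > nat)) stop("cause hierarchy violated: sub-causes exceed natural", call. = FALSE)
  if (any(by_cause("lung_cancer") > by_cause("cancer"))) {
    stop("cause hierarchy violated: lung cancer exceeds cancer", call. = FALSE)
  }
  invisible(deaths)
}

#' Assemble a complete synthetic city
#'
#' Runs the full generator: tracts (geometry, deprivation, population),
#' surface calibration against the configured harbour/rest mean targets,
#' pollutant grids, tract exposure assignment, harbour stratification,
#' baseline-rate calibration against configured cause totals, and the death
#' simulation. Everything is deterministic given the config seed.
#'
#' @param config A [scenario_config()].
#' @return A `city` list: config (with calibrated parameters), tracts,
#'   grids (named list of `exposure_grid`), exposures (stacked data.frame),
#'   stratum, deaths, expected_deaths (named per-cause expected totals).
#' @export
build_city <- function(config) {
  tracts <- generate_tracts(config)
  config <- calibrate_exposure(config, tracts)
  grids <- lapply(names(config$pollutants), function(p) {
    generate_exposure_surface(config, p)
  })
  names(grids) <- names(config$pollutants)
  exposures <- do.call(rbind, lapply(grids, assign_exposure, tracts = tracts))
  rownames(exposures) <- NULL
  stratum <- classify_harbour(tracts, config$harbour_centroid, config$harbour_radius)
  config <- calibrate_rates(tracts, exposures, config)
  deaths <- simulate_deaths(tracts, exposures, config)
  lam <- expected_rates(tracts, exposures, config)
  structure(list(config = config, tracts = tracts, grids = grids,
                 exposures = exposures, stratum = stratum, deaths = deaths,
                 expected_deaths = vapply(lam, sum, numeric(1))),
            class = "city")
}

#' @export
print.city <- function(x, ...) {
  cat(sprintf("<city> %d tracts, %s residents, %d-year window\n",
              nrow(x$tracts), format(sum(tract_populations(x$tracts)), big.mark = ","),
              x$config$study_years))
  cat(sprintf("  harbour stratum: %d tracts, %.1f%% of population\n",
              sum(x$stratum$harbour), 100 * attr(x$stratum, "harbour_pop_share")))
  tot <- tapply(x$deaths$deaths, x$deaths$cause, sum)[causes()]
  cat("  deaths:", paste(sprintf("%s %d", causes(), tot), collapse = ", "), "\n")
  invisible(x)
}
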