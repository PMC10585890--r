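# Poisson regression of tract-level death counts on exposure with the
# three-level adjustment ladder.

#' Specify a mortality regression model
#'
#' @param outcome_cause One of [causes()].
#' @param exposure_variable Pollutant name (continuous concentration) or
#'   "harbour" (binary residence indicator).
#' @param adjustment_level 1 = exposure only (crude); 2 = + age-class and
#'   sex indicators; 3 = + deprivation category indicators.
#' @param increment Reporting increment in ug/m3 (default 5); ignored for
#'   the harbour indicator (reported per category).
#' @param age_reference,sex_reference,ses_reference Reference categories
#'   for the indicator codings.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome_cause, exposure_variable, adjustment_level = 3,
                       increment = 5, age_reference = "35-64",
                       sex_reference = "male", ses_reference = "very_high") {
  stopifnot(outcome_cause %in% causes(), adjustment_level %in% 1:3)
  structure(list(outcome_cause = outcome_cause,
                 exposure_variable = exposure_variable,
                 adjustment_level = adjustment_level, increment = increment,
                 age_reference = age_reference, sex_reference = sex_reference,
                 ses_reference = ses_reference),
            class = "model_spec")
}

#' Build the aggregated-Poisson analysis data set
#'
#' One analysis row per (tract x age-sex stratum) with the study-window
#' death count for the outcome cause, offset log(person-years)
#' (person-years = stratum population x study years), the exposure value
#' (constant within tract), and - depending on the adjustment level -
#' age-class/sex indicators and deprivation-category indicators (missing
#' deprivation kept as its own level). Rows with zero person-years are
#' dropped with a message.
#'
#' @param tracts A `tract_table`.
#' @param deaths A `death_table`.
#' @param exposures Exposure data.frame from [assign_exposure()].
#' @param stratum A `harbour_stratum` (needed when the exposure variable is
#'   "harbour"; may be NULL otherwise).
#' @param spec A [model_spec()].
#' @param study_years Follow-up years for the person-year offset.
#' @return List with X (design matrix, intercept first), y (counts),
#'   offset (log person-years), and row metadata.
#' @export
build_design <- function(tracts, deaths, exposures, stratum, spec,
                         study_years = 5) {
  pops <- tract_populations(tracts)
  py <- pops * study_years

  if (identical(spec$exposure_variable, "harbour")) {
    if (is.null(stratum)) stop("harbour analysis requires a stratum table", call. = FALSE)
    xv <- as.numeric(stratum$harbour[match(tracts$tract_id, stratum$tract_id)])
  } else {
    ex <- exposures[exposures$pollutant == spec$exposure_variable, ]
    if (nrow(ex) == 0) {
      stop("no exposure values for pollutant ", spec$exposure_variable, call. = FALSE)
    }
    xv <- ex$mean[match(tracts$tract_id, ex$tract_id)]
  }

  dd <- deaths[deaths$cause == spec$outcome_cause, ]
  if (nrow(dd) == 0) stop("no deaths rows for cause ", spec$outcome_cause, call. = FALSE)
  key_d <- paste(dd$tract_id, paste(dd$sex, dd$age_class, sep = "_"))
  cnt <- tapply(dd$deaths, key_d, sum)

  n_t <- nrow(tracts)
  rows <- expand.grid(tract = seq_len(n_t), stratum = strata_ids(),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows$tract_id <- tracts$tract_id[rows$tract]
  rows$py <- as.vector(py)
  key_r <- paste(rows$tract_id, rows$stratum)
  rows$y <- as.vector(cnt[key_r])
  rows$y[is.na(rows$y)] <- 0
  rows$x <- xv[rows$tract]

  drop <- rows$py <= 0
  if (any(drop)) {
    message(sum(drop), " rows with zero person-years dropped")
    rows <- rows[!drop, , drop = FALSE]
  }
  if (sum(rows$y) == 0) {
    stop("all-zero outcome for cause ", spec$outcome_cause, ": fit refused", call. = FALSE)
  }
  if (any(is.na(rows$x))) stop("missing exposure for a populated tract", call. = FALSE)

  X <- cbind(`(Intercept)` = 1, exposure = rows$x)
  if (spec$adjustment_level >= 2) {
    age <- stratum_age(rows$stratum)
    for (a in setdiff(age_classes(), spec$age_reference)) {
      X <- cbind(X, as.numeric(age == a))
      colnames(X)[ncol(X)] <- paste0("age_", a)
    }
    sx <- stratum_sex(rows$stratum)
    for (s in setdiff(sexes(), spec$sex_reference)) {
      X <- cbind(X, as.numeric(sx == s))
      colnames(X)[ncol(X)] <- paste0("sex_", s)
    }
  }
  if (spec$adjustment_level >= 3) {
    ses <- tracts$ses_category[rows$tract]
    present <- unique(ses)
    if (length(present) < 2) {
      warning("deprivation constant across tracts: indicators dropped", call. = FALSE)
    } else {
      for (lv in setdiff(intersect(ses_levels(), present), spec$ses_reference)) {
        X <- cbind(X, as.numeric(ses == lv))
        colnames(X)[ncol(X)] <- paste0("ses_", lv)
      }
    }
  }
  list(X = X, y = rows$y, offset = log(rows$py), meta = rows, spec = spec)
}

#' Fit a Poisson log-linear model by Fisher scoring (IRLS)
#'
#' Maximises the Poisson log-likelihood with log link and offset.
#' Convergence requires max |score| < `tol` and a relative deviance change
#' below `dev_tol`; the covariance is the inverse Fisher information at the
#' optimum. Non-convergence or diverging coefficients give a flagged
#' (converged = FALSE) fit, never silent estimates.
#'
#' @param X Design matrix (full column rank; checked).
#' @param y Non-negative integer counts.
#' @param offset Log person-years, same length as y.
#' @param tol Score max-norm tolerance (default 1e-8).
#' @param dev_tol Relative deviance-change tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return A `poisson_fit`: coefficients, vcov, deviance, iterations,
#'   converged flag.
#' @export
fit_poisson <- function(X, y, offset = rep(0, length(y)), tol = 1e-8,
                        dev_tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- numeric(ncol(X))
  # deviance-friendly start: intercept at the overall log rate
  beta[1] <- log(max(sum(y), 0.5) / sum(exp(offset)))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  poisson_dev <- function(y, mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    if (any(!is.finite(mu)) || max(mu) > 1e12) break  # divergence guard
    score <- drop(crossprod(X, y - mu))
    dev <- poisson_dev(y, mu)
    if (max(abs(score)) < tol &&
        abs(dev_old - dev) < dev_tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    w <- sqrt(mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- qr(X * w)
    beta <- qr.coef(fit, w * z)
    dev_old <- dev
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  info <- crossprod(X * sqrt(mu))
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = vcov, deviance = poisson_dev(y, mu),
                 iterations = iter, converged = converged),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> %s after %d iterations, deviance %.3f\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations, x$deviance))
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, se = se))
  invisible(x)
}

#' Percent change in mortality per exposure increment
#'
#' estimate = (exp(increment * beta) - 1) * 100, with Wald 95% bounds from
#' beta +/- 1.96 se transformed the same way.
#'
#' @param fit A converged `poisson_fit`.
#' @param variable Coefficient name (default "exposure").
#' @param increment Increment on the exposure scale (default 5).
#' @return data.frame with estimate, lower, upper (percent), increment.
#' @export
percent_change <- function(fit, variable = "exposure", increment = 5) {
  if (!fit$converged) stop("fit did not converge; no percent change reported", call. = FALSE)
  if (!variable %in% names(fit$coefficients)) {
    stop("no coefficient named ", variable, call. = FALSE)
  }
  b <- fit$coefficients[[variable]]
  se <- sqrt(fit$vcov[variable, variable])
  z <- stats::qnorm(0.975)
  data.frame(estimate = (exp(increment * b) - 1) * 100,
             lower = (exp(increment * (b - z * se)) - 1) * 100,
             upper = (exp(increment * (b + z * se)) - 1) * 100,
             increment = increment)
}

#' Run the full cause x pollutant x adjustment-level association suite
#'
#' Fits the adjustment ladder for every requested cause and pollutant
#' (percent change per `increment` ug/m3) and, when a stratum table is
#' supplied, the harbour-residence indicator analysis per cause (percent
#' change harbour vs rest). Individual fit failures are recorded, they do
#' not abort the suite.
#'
#' @param city A `city` from [build_city()], or a list with elements
#'   tracts, deaths, exposures, stratum, config.
#' @param causes_run,pollutants,levels Grids to cover.
#' @param increment Reporting increment (ug/m3).
#' @param harbour Also run the harbour-indicator analysis (default TRUE).
#' @return data.frame (cause, pollutant, level, estimate, lower, upper,
#'   converged) with pollutant "harbour" marking the indicator analysis.
#' @export
run_association_suite <- function(city, causes_run = causes(),
                                  pollutants = unique(city$exposures$pollutant),
                                  levels = 1:3, increment = 5,
                                  harbour = TRUE) {
  vars <- c(pollutants, if (harbour && !is.null(city$stratum)) "harbour")
  out <- list()
  for (cz in causes_run) {
    for (pv in vars) {
      for (lv in levels) {
        sp <- model_spec(cz, pv, lv, increment = increment)
        res <- tryCatch({
          des <- build_design(city$tracts, city$deaths, city$exposures,
                              city$stratum, sp,
                              study_years = city$config$study_years)
          fit <- fit_poisson(des$X, des$y, des$offset)
          inc <- if (identical(pv, "harbour")) 1 else increment
          pc <- percent_change(fit, "exposure", inc)
          data.frame(cause = cz, pollutant = pv, level = lv,
                     estimate = pc$estimate, lower = pc$lower,
                     upper = pc$upper, converged = fit$converged,
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(cause = cz, pollutant = pv, level = lv,
                     estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                     converged = FALSE, stringsAsFactors = FALSE)
        })
        out[[length(out) + 1L]] <- res
      }
    }
  }
  do.call(rbind, out)
}
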