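# Pollutant concentration surfaces on a regular raster.

#' Construct an exposure grid
#'
#' Regular raster of annual-mean concentration. `values` is an
#' n_rows x n_cols matrix stored bottom-row-first (row 1 is the southmost
#' row), the package-internal convention; the ESRI ASCII writer flips to
#' top-row-first at the I/O boundary.
#'
#' @param pollutant Pollutant name.
#' @param origin c(x, y) of the lower-left corner, metres.
#' @param cell_size Cell edge length, metres.
#' @param values Numeric matrix, bottom-row-first; NA marks NODATA.
#' @return An `exposure_grid`.
#' @export
exposure_grid <- function(pollutant, origin, cell_size, values) {
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0 (or NODATA)", call. = FALSE)
  }
  structure(list(pollutant = pollutant, origin = as.numeric(origin),
                 cell_size = cell_size, n_rows = nrow(values),
                 n_cols = ncol(values), values = values),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf("<exposure_grid> %s: %d x %d cells of %g m, origin (%g, %g)\n",
              x$pollutant, x$n_rows, x$n_cols, x$cell_size,
              x$origin[1], x$origin[2]))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values %.2f - %.2f ug/m3, %d NODATA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

# cell-centre coordinate vectors of a grid covering the config extent
grid_frame <- function(config) {
  ext <- config$extent
  cs <- config$grid_cell_size
  n_cols <- ceiling((ext[3] - ext[1]) / cs)
  n_rows <- ceiling((ext[4] - ext[2]) / cs)
  list(origin = ext[1:2], cell_size = cs, n_rows = n_rows, n_cols = n_cols,
       xc = ext[1] + (seq_len(n_cols) - 0.5) * cs,
       yc = ext[2] + (seq_len(n_rows) - 0.5) * cs)
}

# exponential point-source decay field, unit amplitude, zero background
decay_field <- function(config) {
  f <- grid_frame(config)
  hx <- config$harbour_centroid[1]; hy <- config$harbour_centroid[2]
  d <- sqrt(outer((f$yc - hy)^2, (f$xc - hx)^2, `+`))
  exp(-d / config$decay_length)
}

# smooth unit-variance spatial noise: seeded iid normals smoothed with a
# separable box kernel, then standardised
noise_field <- function(config, pollutant) {
  f <- grid_frame(config)
  p_idx <- match(pollutant, names(config$pollutants))
  z <- with_stream(config$seed + 13L * p_idx, "noise", {
    matrix(stats::rnorm(f$n_rows * f$n_cols), f$n_rows, f$n_cols)
  })
  k <- 3L  # half-width in cells; correlation length ~ tract scale
  sm <- box_smooth(box_smooth(z, k, 1L), k, 2L)
  (sm - mean(sm)) / stats::sd(as.vector(sm))
}

# moving average along one margin with edge replication
box_smooth <- function(m, k, margin) {
  if (margin == 2L) return(t(box_smooth(t(m), k, 1L)))
  n <- nrow(m)
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- m * 0
  for (off in -k:k) out <- out + m[idx(seq_len(n) + off), , drop = FALSE]
  out / (2 * k + 1)
}

#' Generate a synthetic pollutant surface
#'
#' Cell value = background + amplitude * exp(-d / decay_length) + noise,
#' where d is the distance from the cell centre to the harbour centroid and
#' the optional noise term is a seeded smooth spatial field scaled to
#' `noise_sd`. Negative cells (possible under strong noise) are clamped to
#' zero.
#'
#' @param config A [scenario_config()]; `config$pollutants[[pollutant]]`
#'   supplies background, amplitude and noise_sd.
#' @param pollutant Pollutant name, must be configured.
#' @return An `exposure_grid` covering the city extent.
#' @export
generate_exposure_surface <- function(config, pollutant) {
  pp <- config$pollutants[[pollutant]]
  if (is.null(pp)) stop("pollutant not configured: ", pollutant, call. = FALSE)
  f <- grid_frame(config)
  dec <- decay_field(config)
  vals <- pp$background + pp$amplitude * dec
  if (!is.null(pp$noise_sd) && pp$noise_sd > 0) {
    nz <- pp$noise_sd * noise_field(config, pollutant)
    if (!is.null(pp$noise_adjust)) {
      nz <- nz - pp$noise_adjust[["alpha"]] - pp$noise_adjust[["beta"]] * dec
    }
    vals <- vals + nz
  }
  vals <- pmax(vals, 0)
  exposure_grid(pollutant, f$origin, f$cell_size, vals)
}

#' Calibrate surface background and amplitude to harbour/rest mean targets
#'
#' The area-weighted tract mean is linear in the grid values, so the tract
#' mean of `background + amplitude * decay + noise` decomposes as
#' `background + amplitude * m_decay + m_noise` with `m_decay`, `m_noise`
#' the tract means of the component fields. The noise field is first made
#' orthogonal to the calibration basis (its population-weighted harbour and
#' rest stratum means are projected out against the constant and decay
#' fields), after which the target means form a 2 x 2 linear system in
#' (background, amplitude), solved exactly; no search is needed.
#'
#' @param config A [scenario_config()] with `exposure_targets` set.
#' @param tracts Tract table generated from `config`.
#' @return The config with per-pollutant background/amplitude replaced by
#'   calibrated values.
#' @export
calibrate_exposure <- function(config, tracts) {
  if (is.null(config$exposure_targets)) return(config)
  f <- grid_frame(config)
  stratum <- classify_harbour(tracts, config$harbour_centroid, config$harbour_radius)
  pop <- rowSums(tract_populations(tracts))
  wh <- pop * stratum$harbour / sum(pop * stratum$harbour)
  wr <- pop * (!stratum$harbour) / sum(pop * (!stratum$harbour))

  dec_grid <- exposure_grid("decay", f$origin, f$cell_size, decay_field(config))
  m_dec <- assign_exposure(dec_grid, tracts)$mean
  u_h <- sum(wh * m_dec); u_r <- sum(wr * m_dec)

  for (p in names(config$exposure_targets)) {
    tgt <- config$exposure_targets[[p]]
    pp <- config$pollutants[[p]]
    if (!is.null(pp$noise_sd) && pp$noise_sd > 0) {
      # project the stratum means out of the noise field (against the
      # {constant, decay} calibration basis): noise then adds
      # within-stratum spread without moving either stratum mean, so the
      # solve below is exact and the amplitude stays positive for any seed
      nz <- noise_field(config, p) * pp$noise_sd
      nz_grid <- exposure_grid("noise", f$origin, f$cell_size, nz - min(nz))
      m_nz <- assign_exposure(nz_grid, tracts)$mean + min(nz)
      v_h <- sum(wh * m_nz); v_r <- sum(wr * m_nz)
      beta_adj <- (v_h - v_r) / (u_h - u_r)
      alpha_adj <- v_r - beta_adj * u_r
      config$pollutants[[p]]$noise_adjust <- c(alpha = alpha_adj,
                                               beta = beta_adj)
    }
    amplitude <- (tgt[["harbour"]] - tgt[["rest"]]) / (u_h - u_r)
    background <- tgt[["rest"]] - amplitude * u_r
    if (amplitude < 0 || background < 0) {
      stop("calibration produced a negative background or amplitude for ", p,
           call. = FALSE)
    }
    config$pollutants[[p]]$background <- background
    config$pollutants[[p]]$amplitude <- amplitude
  }
  config
}
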