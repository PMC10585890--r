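# File formats: GeoJSON tracts, ESRI ASCII grids, long CSVs, YAML configs.
#
# Internal grid rows are lower-left-first; the ESRI ASCII format is
# top-row-first, so rows are flipped at this boundary only.

#' Write / read a tract table as GeoJSON
#'
#' FeatureCollection of Polygons; properties are tract_id, ses_category and
#' one pop_<stratum> count per demographic stratum. Coordinates are written
#' at full double precision so read(write(x)) round-trips exactly.
#'
#' @param tracts A `tract_table`.
#' @param path Output file.
#' @return `write_tracts`: the path, invisibly. `read_tracts`: a validated
#'   `tract_table`.
#' @export
write_tracts <- function(tracts, path) {
  pops <- tract_populations(tracts)
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- tracts$geometry[[i]]
    ring_closed <- rbind(ring, ring[1, , drop = FALSE])
    props <- c(list(tract_id = tracts$tract_id[i],
                    ses_category = tracts$ses_category[i]),
               as.list(stats::setNames(as.integer(pops[i, ]),
                                       paste0("pop_", colnames(pops)))))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split_rows(ring_closed)))))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

#' @rdname write_tracts
#' @export
read_tracts <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  need <- c("tract_id", "ses_category", paste0("pop_", strata_ids()))
  n <- length(doc$features)
  geoms <- vector("list", n)
  ids <- ses <- character(n)
  pops <- matrix(0L, n, 10, dimnames = list(NULL, strata_ids()))
  for (i in seq_len(n)) {
    f <- doc$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, ": geometry must be Polygon, got ",
           f$geometry$type, call. = FALSE)
    }
    miss <- setdiff(need, names(f$properties))
    if (length(miss)) {
      stop("feature ", i, ": missing property ", miss[1], call. = FALSE)
    }
    if (length(f$geometry$coordinates) != 1L) {
      stop("feature ", i, ": polygons with holes are not supported", call. = FALSE)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], as.numeric))
    nr <- nrow(ring)
    if (nr < 4L || any(ring[1, ] != ring[nr, ])) {
      stop("feature ", i, ": ring must be closed", call. = FALSE)
    }
    geoms[[i]] <- ring[-nr, , drop = FALSE]
    ids[i] <- f$properties$tract_id
    ses[i] <- f$properties$ses_category
    pops[i, ] <- vapply(paste0("pop_", strata_ids()),
                        function(k) as.integer(f$properties[[k]]), integer(1))
  }
  tract_table(ids, geoms, ses, pops)
}

#' Write / read an exposure grid as ESRI ASCII
#'
#' Standard six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows north-to-south. Values are written with
#' 17 significant digits so numeric round trips are exact.
#'
#' @param grid An `exposure_grid`.
#' @param path File path.
#' @param pollutant Pollutant name to attach on read (the format does not
#'   carry one); default from the file name.
#' @return `write_grid`: the path, invisibly. `read_grid`: an
#'   `exposure_grid`.
#' @export
write_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2], digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", -9999)
  ), con)
  v <- grid$values
  v[is.na(v)] <- -9999
  for (i in rev(seq_len(grid$n_rows))) {
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, pollutant = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  hk <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "NODATA_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  miss <- setdiff(tolower(hk), names(hdr))
  if (length(miss)) stop("malformed header: missing ", miss[1], call. = FALSE)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("value count ", length(vals), " does not match ncols*nrows = ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # to lower-left-first
  m[m == hdr$nodata_value] <- NA
  exposure_grid(pollutant, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, m)
}

#' Write / read a death table as long-format CSV
#'
#' Columns tract_id, cause, age_class, sex, deaths; validated on read
#' (hierarchy invariants included).
#'
#' @param deaths A `death_table`.
#' @param path File path.
#' @return `write_deaths`: path invisibly; `read_deaths`: a validated
#'   `death_table`.
#' @export
write_deaths <- function(deaths, path) {
  utils::write.csv(as.data.frame(deaths)[, c("tract_id", "cause", "age_class",
                                             "sex", "deaths")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deaths
#' @export
read_deaths <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(tract_id = "character"))
  validate_death_table(out)
  class(out) <- c("death_table", "data.frame")
  out
}

#' Write / read a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_config`: path invisibly; `read_config`: a validated
#'   `scenario_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$baseline_rates <- list(values = as.vector(config$baseline_rates),
                           causes = rownames(config$baseline_rates),
                           strata = colnames(config$baseline_rates))
  # yaml serialises atomic vectors as plain sequences; named vectors must
  # become lists to survive as maps
  as_map <- function(v) if (!is.null(names(v))) as.list(v) else v
  for (f in c("age_sex_margins", "true_beta", "ses_effects", "cause_totals")) {
    x[[f]] <- as_map(x[[f]])
  }
  x$ses_distribution <- if (is.list(config$ses_distribution)) {
    lapply(config$ses_distribution, as_map)
  } else as_map(config$ses_distribution)
  if (!is.null(x$exposure_targets)) {
    x$exposure_targets <- lapply(x$exposure_targets, as_map)
  }
  x$pollutants <- lapply(x$pollutants, function(pp) {
    if (!is.null(pp$noise_adjust)) pp$noise_adjust <- as.list(pp$noise_adjust)
    pp
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  br <- x$baseline_rates
  rates <- matrix(unlist(br$values), length(br$causes), length(br$strata),
                  dimnames = list(unlist(br$causes), unlist(br$strata)))
  unl <- function(v) if (is.list(v)) unlist(v) else v
  sdist <- x$ses_distribution
  if (is.list(sdist) && all(c("harbour", "rest") %in% names(sdist))) {
    sdist <- list(harbour = unl(sdist$harbour), rest = unl(sdist$rest))
  } else {
    sdist <- unl(sdist)
  }
  scenario_config(
    n_tracts = x$n_tracts, extent = unl(x$extent),
    harbour_centroid = unl(x$harbour_centroid),
    harbour_radius = x$harbour_radius, grid_cell_size = x$grid_cell_size,
    pollutants = lapply(x$pollutants, function(pp) {
      if (!is.null(pp$noise_adjust)) pp$noise_adjust <- unlist(pp$noise_adjust)
      pp
    }),
    decay_length = x$decay_length,
    total_population = x$total_population,
    age_sex_margins = unl(x$age_sex_margins), ses_distribution = sdist,
    harbour_pop_share = x$harbour_pop_share, baseline_rates = rates,
    true_beta = unl(x$true_beta), sim_pollutant = x$sim_pollutant,
    ses_effects = unl(x$ses_effects), study_years = x$study_years,
    tract_mode = x$tract_mode,
    exposure_targets = if (!is.null(x$exposure_targets)) {
      lapply(x$exposure_targets, unl)
    },
    cause_totals = unl(x$cause_totals), seed = x$seed
  )
}

# md5 digest of an in-memory object via its canonical JSON serialisation
object_digest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = I(17), force = TRUE)
  unname(tools::md5sum(tmp))
}
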