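# Census tract generation: geometry, deprivation category, population strata.

#' Construct a tract table
#'
#' A `tract_table` is a data.frame with columns `tract_id`,
#' `ses_category`, one integer population column `pop_<stratum>` per
#' demographic stratum, and a `geometry` list-column of open
#' counter-clockwise rings (n x 2 matrices, metres).
#'
#' @param tract_id Character ids, unique.
#' @param geometry List of rings.
#' @param ses_category Factor/character in [ses_levels()].
#' @param populations Integer matrix n_tracts x 10, columns named by
#'   [strata_ids()].
#' @return A `tract_table`.
#' @export
tract_table <- function(tract_id, geometry, ses_category, populations) {
  df <- data.frame(tract_id = as.character(tract_id),
                   ses_category = as.character(ses_category),
                   stringsAsFactors = FALSE)
  for (s in strata_ids()) df[[paste0("pop_", s)]] <- as.integer(populations[, s])
  df$geometry <- geometry
  class(df) <- c("tract_table", "data.frame")
  validate_tract_table(df)
  df
}

validate_tract_table <- function(x) {
  if (anyDuplicated(x$tract_id)) {
    stop("duplicate tract_id: ", x$tract_id[duplicated(x$tract_id)][1], call. = FALSE)
  }
  if (!all(x$ses_category %in% ses_levels())) {
    stop("unknown ses_category value", call. = FALSE)
  }
  pops <- tract_populations(x)
  if (any(pops < 0) || any(pops != round(pops))) {
    stop("populations must be non-negative integers", call. = FALSE)
  }
  areas <- vapply(x$geometry, polygon_area, numeric(1))
  if (any(areas <= 0 & rowSums(pops) > 0)) {
    stop("populated tract with zero-area polygon", call. = FALSE)
  }
  invisible(x)
}

#' Population matrix of a tract table
#'
#' @param tracts A `tract_table`.
#' @return Integer matrix n_tracts x 10 with stratum column names.
#' @export
tract_populations <- function(tracts) {
  m <- as.matrix(as.data.frame(tracts)[, paste0("pop_", strata_ids())])
  colnames(m) <- strata_ids()
  rownames(m) <- tracts$tract_id
  m
}

#' Tract polygon centroids
#' @param tracts A `tract_table`.
#' @return n x 2 matrix of centroids.
#' @export
tract_centroids <- function(tracts) {
  t(vapply(tracts$geometry, polygon_centroid, numeric(2)))
}

#' @export
print.tract_table <- function(x, ...) {
  cat(sprintf("<tract_table> %d tracts, %s residents\n", nrow(x),
              format(sum(tract_populations(x)), big.mark = ",")))
  invisible(x)
}

# near-square factorisation r x c >= aspect-matched tiling with r*c = n
grid_dims <- function(n, w, h) {
  best <- c(1L, n)
  bestscore <- Inf
  for (r in seq_len(n)) {
    if (n %% r != 0L) next
    cc <- n %/% r
    score <- abs(log((w / cc) / (h / r)))
    if (score < bestscore) { bestscore <- score; best <- c(r, cc) }
  }
  best
}

#' Generate synthetic census tracts
#'
#' Tiles the city extent into `n_tracts` non-overlapping polygons: a seeded
#' Voronoi tessellation of uniform random points (default) or an
#' axis-aligned rectangular tiling (`tract_mode = "grid_tracts"`, used for
#' exact-answer work). Each tract is assigned a deprivation category by
#' sampling the configured distribution and an integer population per
#' demographic stratum by deterministic largest-remainder apportionment:
#' when `harbour_pop_share` is set, that share of the total is allocated to
#' tracts whose centroid lies within `harbour_radius` of the harbour
#' centroid (proportional to tract area within each side), otherwise
#' proportional to area citywide.
#'
#' @param config A [scenario_config()].
#' @return A `tract_table`.
#' @export
generate_tracts <- function(config) {
  ext <- config$extent
  w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
  n_cells <- ceiling(w / config$grid_cell_size) * ceiling(h / config$grid_cell_size)
  if (config$n_tracts > 16 * n_cells) {
    stop("n_tracts exceeds 16 tracts per grid cell: degenerate geometry", call. = FALSE)
  }
  if (config$tract_mode == "grid_tracts") {
    dims <- grid_dims(config$n_tracts, w, h)
    nr <- dims[1]; nc <- dims[2]
    geoms <- vector("list", config$n_tracts)
    k <- 0L
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        k <- k + 1L
        x0 <- ext[1] + (j - 1) * w / nc; x1 <- ext[1] + j * w / nc
        y0 <- ext[2] + (i - 1) * h / nr; y1 <- ext[2] + i * h / nr
        geoms[[k]] <- matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
      }
    }
  } else {
    pts <- with_stream(config$seed, "tracts", {
      cbind(stats::runif(config$n_tracts, ext[1], ext[3]),
            stats::runif(config$n_tracts, ext[2], ext[4]))
    })
    geoms <- voronoi_cells(pts, ext)
  }

  cent <- t(vapply(geoms, polygon_centroid, numeric(2)))
  d <- sqrt((cent[, 1] - config$harbour_centroid[1])^2 +
            (cent[, 2] - config$harbour_centroid[2])^2)
  in_harb <- d <= config$harbour_radius
  areas <- vapply(geoms, polygon_area, numeric(1))

  # deprivation category, harbour/rest-specific distribution when given
  sdist <- config$ses_distribution
  ses <- with_stream(config$seed, "ses", {
    vapply(seq_along(geoms), function(i) {
      p <- if (is.list(sdist)) {
        if (in_harb[i]) sdist$harbour else sdist$rest
      } else sdist
      sample(ses_levels(), 1L, prob = p[ses_levels()])
    }, character(1))
  })

  # stratum populations: exact area-level stratum totals via
  # largest-remainder apportionment over tracts
  total <- config$total_population
  margins <- config$age_sex_margins[strata_ids()]
  pops <- matrix(0L, length(geoms), 10, dimnames = list(NULL, strata_ids()))
  if (!is.null(config$harbour_pop_share) && any(in_harb) && !all(in_harb)) {
    n_harb <- as.integer(round(total * config$harbour_pop_share))
    split_tot <- c(harbour = n_harb, rest = total - n_harb)
    for (side in c("harbour", "rest")) {
      idx <- if (side == "harbour") which(in_harb) else which(!in_harb)
      side_strata <- largest_remainder(margins, split_tot[[side]])
      for (k in seq_along(margins)) {
        pops[idx, k] <- largest_remainder(areas[idx], side_strata[k])
      }
    }
  } else {
    strata_tot <- largest_remainder(margins, total)
    for (k in seq_along(margins)) {
      pops[, k] <- largest_remainder(areas, strata_tot[k])
    }
  }

  tract_table(sprintf("T%04d", seq_along(geoms)), geoms, ses, pops)
}
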