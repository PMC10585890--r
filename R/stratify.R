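# Harbour-buffer stratification and descriptive summaries.

#' Classify tracts into harbour / non-harbour strata
#'
#' Default rule: a tract belongs to the harbour stratum iff its polygon
#' centroid lies within `radius_m` of the harbour centroid (planar
#' Euclidean distance). Alternative whole-tract rules: `"overlap"` assigns
#' tracts with >= 50% of their area inside the circular buffer (area
#' evaluated on a deterministic point lattice inside the tract), and
#' `"square"` uses a square buffer of half-width `radius_m` centred on the
#' harbour (centroid membership).
#'
#' @param tracts A `tract_table`.
#' @param harbour_centroid c(x, y), metres.
#' @param radius_m Buffer radius, metres (> 0).
#' @param rule "centroid" (default), "overlap" or "square".
#' @return A `harbour_stratum` data.frame: tract_id, distance_m, harbour
#'   (logical), with the radius and the harbour population share as
#'   attributes.
#' @export
classify_harbour <- function(tracts, harbour_centroid, radius_m,
                             rule = c("centroid", "overlap", "square")) {
  rule <- match.arg(rule)
  if (radius_m <= 0) stop("radius_m must be > 0", call. = FALSE)
  cent <- tract_centroids(tracts)
  d <- sqrt((cent[, 1] - harbour_centroid[1])^2 +
            (cent[, 2] - harbour_centroid[2])^2)
  harb <- switch(rule,
    centroid = d <= radius_m,
    square = abs(cent[, 1] - harbour_centroid[1]) <= radius_m &
             abs(cent[, 2] - harbour_centroid[2]) <= radius_m,
    overlap = vapply(seq_len(nrow(tracts)), function(i) {
      buffer_overlap_fraction(tracts$geometry[[i]], harbour_centroid, radius_m) >= 0.5
    }, logical(1))
  )
  pop <- rowSums(tract_populations(tracts))
  out <- data.frame(tract_id = tracts$tract_id, distance_m = d,
                    harbour = harb, stringsAsFactors = FALSE)
  attr(out, "radius_m") <- radius_m
  attr(out, "rule") <- rule
  attr(out, "harbour_pop_share") <- sum(pop[harb]) / sum(pop)
  class(out) <- c("harbour_stratum", "data.frame")
  out
}

# fraction of polygon area inside a circle, via a deterministic lattice of
# sample points in the polygon bounding box
buffer_overlap_fraction <- function(ring, centre, radius, n_side = 40L) {
  xs <- seq(min(ring[, 1]), max(ring[, 1]), length.out = n_side)
  ys <- seq(min(ring[, 2]), max(ring[, 2]), length.out = n_side)
  px <- rep(xs, each = n_side); py <- rep(ys, times = n_side)
  inside <- point_in_polygon(px, py, ring)
  if (!any(inside)) return(0)
  within <- (px - centre[1])^2 + (py - centre[2])^2 <= radius^2
  sum(inside & within) / sum(inside)
}

#' Harbour strata across a set of buffer radii (sensitivity analysis)
#'
#' @param tracts A `tract_table`.
#' @param harbour_centroid c(x, y), metres.
#' @param radii Numeric vector of radii, metres, sorted ascending.
#' @param rule Passed to [classify_harbour()].
#' @return data.frame with one row per radius: radius_m, n_tracts_harbour,
#'   population_harbour, population_share; strata list attached as
#'   attribute `strata`.
#' @export
sensitivity_radii <- function(tracts, harbour_centroid, radii,
                              rule = "centroid") {
  if (is.unsorted(radii)) stop("radii must be sorted ascending", call. = FALSE)
  strata <- lapply(radii, function(r) {
    classify_harbour(tracts, harbour_centroid, r, rule = rule)
  })
  pop <- rowSums(tract_populations(tracts))
  out <- data.frame(
    radius_m = radii,
    n_tracts_harbour = vapply(strata, function(s) sum(s$harbour), integer(1)),
    population_harbour = vapply(strata, function(s) sum(pop[s$harbour]), numeric(1))
  )
  out$population_share <- out$population_harbour / sum(pop)
  attr(out, "strata") <- strata
  out
}

#' Descriptive summary table by harbour stratum
#'
#' Population totals, age-class and sex counts with percentages,
#' deprivation distribution, population-weighted exposure mean and SD, and
#' cause-specific death counts, for the harbour stratum, the rest of the
#' city, and the total.
#'
#' @param tracts A `tract_table`.
#' @param deaths A `death_table` (long format).
#' @param exposures Exposure data.frame as from [assign_exposure()]
#'   (stacked over pollutants).
#' @param stratum A `harbour_stratum` from [classify_harbour()].
#' @return Long data.frame: block, item, area in
#'   \{harbour, rest, total\}, value, percent (NA where not applicable).
#' @export
descriptive_table <- function(tracts, deaths, exposures, stratum) {
  if (!setequal(tracts$tract_id, stratum$tract_id) ||
      !all(unique(deaths$tract_id) %in% tracts$tract_id) ||
      !all(unique(exposures$tract_id) %in% tracts$tract_id)) {
    stop("inconsistent tract ids across inputs", call. = FALSE)
  }
  harb <- stratum$harbour[match(tracts$tract_id, stratum$tract_id)]
  pops <- tract_populations(tracts)
  pop_t <- rowSums(pops)
  areas <- list(harbour = harb, rest = !harb, total = rep(TRUE, nrow(tracts)))

  rows <- list()
  add <- function(block, item, vals, pct) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, item = item, area = names(vals),
      value = as.numeric(vals), percent = as.numeric(pct),
      stringsAsFactors = FALSE)
  }

  tot <- vapply(areas, function(m) sum(pop_t[m]), numeric(1))
  add("population", "total", tot, 100 * tot / sum(pop_t))

  for (a in age_classes()) {
    cols <- paste0("pop_", sexes(), "_", a)
    n <- vapply(areas, function(m) sum(pops[m, sub("pop_", "", cols)]), numeric(1))
    add("age_class", a, n, 100 * n / tot)
  }
  for (sx in sexes()) {
    cols <- paste0(sx, "_", age_classes())
    n <- vapply(areas, function(m) sum(pops[m, cols]), numeric(1))
    add("sex", sx, n, 100 * n / tot)
  }
  for (lv in ses_levels()) {
    n <- vapply(areas, function(m) sum(pop_t[m & tracts$ses_category == lv]), numeric(1))
    add("ses", lv, n, 100 * n / tot)
  }
  for (p in unique(exposures$pollutant)) {
    ex <- exposures[exposures$pollutant == p, ]
    x <- ex$mean[match(tracts$tract_id, ex$tract_id)]
    mu <- vapply(areas, function(m) stats::weighted.mean(x[m], pop_t[m]), numeric(1))
    sdv <- vapply(names(areas), function(nm) {
      m <- areas[[nm]]
      sqrt(stats::weighted.mean((x[m] - mu[[nm]])^2, pop_t[m]))
    }, numeric(1))
    add(paste0("exposure_", p), "mean", mu, NA)
    add(paste0("exposure_", p), "sd", sdv, NA)
  }
  dt <- deaths
  dt$harb <- harb[match(dt$tract_id, tracts$tract_id)]
  for (cz in causes()) {
    dd <- dt[dt$cause == cz, ]
    n <- c(harbour = sum(dd$deaths[dd$harb]), rest = sum(dd$deaths[!dd$harb]),
           total = sum(dd$deaths))
    add("mortality", cz, n, 100 * n / tot)
  }
  do.call(rbind, rows)
}
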