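# shared fixtures, built in code

# memoised full preset city: several files exercise it, build it once
ancona_city_cached <- local({
  env <- new.env()
  function() {
    if (is.null(env$city)) {
      env$city <- suppressMessages(suppressWarnings(build_city(ancona_preset())))
    }
    env$city
  }
})

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         ncol = 2, byrow = TRUE)
}

# single-tract table around a given ring
one_tract <- function(ring, id = "A", ses = "medium", pop_each = 10L) {
  pops <- matrix(pop_each, 1, 10, dimnames = list(NULL, strata_ids()))
  tract_table(id, list(ring), ses, pops)
}

# seeded random convex polygon inside [0, w] x [0, h]
random_convex_ring <- function(w, h, n_pts = 9) {
  px <- runif(n_pts, 0.1 * w, 0.9 * w)
  py <- runif(n_pts, 0.1 * h, 0.9 * h)
  hull <- chull(px, py)
  cbind(px[hull], py[hull])[rev(seq_along(hull)), , drop = FALSE]
}

# small grid-mode scenario for fast simulation tests
small_scenario <- function(n_tracts = 9L, seed = 7L, ...) {
  scenario_config(
    n_tracts = n_tracts, extent = c(0, 0, 3000, 3000),
    harbour_centroid = c(1500, 1500), harbour_radius = 800,
    total_population = 9000L, tract_mode = "grid_tracts", seed = seed, ...)
}
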