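# Planar polygon primitives.
#
# A polygon ring is an n x 2 numeric matrix of vertices in metres, open
# (the first vertex is not repeated at the end) and oriented
# counter-clockwise for positive signed area. All geometry in the package
# is planar/projected; no CRS handling.

#' Signed area of a polygon ring (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param ring n x 2 numeric matrix of vertices, open ring.
#' @return Signed area in square metres.
#' @keywords internal
polygon_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon ring
#'
#' @inheritParams polygon_signed_area
#' @return Non-negative area in square metres.
#' @export
polygon_area <- function(ring) abs(polygon_signed_area(ring))

#' Centroid of a polygon ring
#'
#' @inheritParams polygon_signed_area
#' @return Length-2 numeric (x, y) in metres.
#' @export
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Clip a ring to the half-plane a*x + b*y <= c (Sutherland--Hodgman step)
#'
#' @param ring n x 2 matrix, open ring.
#' @param a,b,c Half-plane coefficients.
#' @return Clipped open ring (possibly with 0 rows).
#' @keywords internal
clip_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  v <- a * ring[, 1] + b * ring[, 2] - c
  inside <- v <= 0
  if (all(inside)) return(ring)
  if (!any(inside)) return(ring[0L, , drop = FALSE])
  out <- matrix(NA_real_, n * 2L, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L; out[k, ] <- ring[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- v[i] / (v[i] - v[j])
      k <- k + 1L
      out[k, ] <- ring[i, ] + t * (ring[j, ] - ring[i, ])
    }
  }
  out <- out[seq_len(k), , drop = FALSE]
  dedupe_ring(out)
}

# drop consecutive duplicate vertices (clipping artefacts)
dedupe_ring <- function(ring, tol = 1e-12) {
  n <- nrow(ring)
  if (n < 2L) return(ring)
  nxt <- c(2:n, 1L)
  keep <- abs(ring[, 1] - ring[nxt, 1]) > tol | abs(ring[, 2] - ring[nxt, 2]) > tol
  # keep[i] FALSE means vertex i duplicates its successor; drop i
  ring[keep, , drop = FALSE]
}

#' Clip a ring to an axis-aligned rectangle
#'
#' Four Sutherland--Hodgman half-plane clips.
#'
#' @param ring n x 2 matrix, open ring.
#' @param xmin,xmax,ymin,ymax Rectangle bounds, metres.
#' @return Clipped open ring (possibly empty).
#' @export
clip_rect <- function(ring, xmin, xmax, ymin, ymax) {
  ring <- clip_halfplane(ring, -1, 0, -xmin)
  ring <- clip_halfplane(ring, 1, 0, xmax)
  ring <- clip_halfplane(ring, 0, -1, -ymin)
  clip_halfplane(ring, 0, 1, ymax)
}

#' Even-odd point-in-polygon test, vectorised over points
#'
#' Boundary points may fall on either side; callers that care about
#' boundaries must not rely on a particular convention.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param ring n x 2 matrix, open ring.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test that a ring is a simple (non-self-intersecting) polygon
#'
#' O(e^2) segment pair test; rings here are small.
#'
#' @param ring n x 2 matrix, open ring.
#' @return TRUE if simple.
#' @keywords internal
is_simple_polygon <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  p1 <- ring
  p2 <- ring[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(i, j) {
    d1 <- p2[i, ] - p1[i, ]; d2 <- p2[j, ] - p1[j, ]
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    dp <- p1[j, ] - p1[i, ]
    if (abs(denom) < 1e-14) return(FALSE)  # parallel: treated as non-crossing
    t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
    u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
    eps <- 1e-12
    t > eps && t < 1 - eps && u > eps && u < 1 - eps
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

#' Bounded Voronoi tessellation by half-plane clipping
#'
#' Each cell starts as the extent rectangle and is clipped by the
#' perpendicular bisector against other seed points, scanned in order of
#' increasing distance; the scan stops once the next point is farther than
#' twice the cell's current circumradius, which cannot cut the cell.
#'
#' @param pts n x 2 matrix of seed points inside the extent.
#' @param extent c(xmin, ymin, xmax, ymax) in metres.
#' @return List of n open rings (counter-clockwise).
#' @export
voronoi_cells <- function(pts, extent) {
  n <- nrow(pts)
  base <- matrix(c(extent[1], extent[2],
                   extent[3], extent[2],
                   extent[3], extent[4],
                   extent[1], extent[4]), ncol = 2, byrow = TRUE)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- base
    for (j in ord) {
      dj <- sqrt(d2[j])
      rmax2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
      if (dj * dj > 4 * rmax2) break
      q <- pts[j, ]
      # bisector half-plane closer to p: (q-p) . x <= (q-p).(p+q)/2
      a <- q[1] - p[1]; b <- q[2] - p[2]
      cval <- (a * (p[1] + q[1]) + b * (p[2] + q[2])) / 2
      cell <- clip_halfplane(cell, a, b, cval)
      if (nrow(cell) < 3L) break
    }
    if (polygon_signed_area(cell) < 0) cell <- cell[rev(seq_len(nrow(cell))), , drop = FALSE]
    cells[[i]] <- cell
  }
  cells
}
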