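# Planar geometry helpers for an abstract metric frame (metres). Polygons are
# closed rings given as two-column vertex matrices (first vertex need not be
# repeated). All predicates are vectorised over query points.

#' Point-in-polygon test (even-odd rule)
#'
#' Boundary points count as inside: a point lying within `tol` of any edge is
#' accepted before the crossing test runs.
#'
#' @param x,y Numeric vectors of query coordinates (metres).
#' @param poly Two-column matrix of ring vertices.
#' @param tol Distance below which a point is treated as on the boundary.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- length(x)
  px <- poly[, 1]; py <- poly[, 2]
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  inside <- logical(n)
  for (k in seq_len(nrow(poly))) {
    x1 <- px[k]; y1 <- py[k]; x2 <- px[nxt[k]]; y2 <- py[nxt[k]]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  on_edge <- dist_to_ring(x, y, poly) <= tol
  inside | on_edge
}

#' Distance from points to a polygon ring (its boundary)
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (metres), zero only on the boundary.
#' @export
dist_to_ring <- function(x, y, poly) {
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  d2 <- rep(Inf, length(x))
  for (k in seq_len(nrow(poly))) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    x2 <- poly[nxt[k], 1]; y2 <- poly[nxt[k], 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dk <- (x - x1)^2 + (y - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((x - x1) * vx + (y - y1) * vy) / L2))
      dk <- (x - (x1 + t * vx))^2 + (y - (y1 + t * vy))^2
    }
    d2 <- pmin(d2, dk)
  }
  sqrt(d2)
}

# Rectangle helper: extent is c(xmin, ymin, xmax, ymax).
extent_polygon <- function(extent) {
  matrix(c(extent[1], extent[2],
           extent[3], extent[2],
           extent[3], extent[4],
           extent[1], extent[4]), ncol = 2, byrow = TRUE)
}

in_extent <- function(x, y, extent) {
  x >= extent[1] & x <= extent[3] & y >= extent[2] & y <= extent[4]
}
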