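# Resource landscapes: a flat list of features (points or polygon rings) with
# a resource class and free-form attributes, plus a rectangular extent.

#' Construct a resource map
#'
#' @param features List of features. Each feature is a list with elements
#'   `class` (one of [resource_classes]), `type` ("point" or "polygon"),
#'   `x`,`y` (point) or `coords` (polygon vertex matrix), and optional
#'   `attributes` (e.g. `dbh`, `volume`, `inside_site`, `use_class`).
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @return A `resource_map` object.
#' @export
resource_map <- function(features, extent) {
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent must be c(xmin, ymin, xmax, ymax) with positive area")
  for (f in features) {
    if (!f$class %in% resource_classes)
      stop("unknown resource class: ", f$class)
    if (f$type == "point") {
      if (!in_extent(f$x, f$y, extent)) stop("point feature outside extent")
    } else if (f$type == "polygon") {
      if (!all(in_extent(f$coords[, 1], f$coords[, 2], extent)))
        stop("polygon feature outside extent")
    } else stop("feature type must be 'point' or 'polygon'")
  }
  structure(list(features = features, extent = extent),
            class = "resource_map")
}

#' @export
print.resource_map <- function(x, ...) {
  cls <- vapply(x$features, function(f) f$class, character(1))
  cat("<resource_map>", length(x$features), "features over",
      sprintf("%.1f ha", prod(x$extent[3:4] - x$extent[1:2]) / 1e4), "\n")
  if (length(cls)) print(table(cls))
  invisible(x)
}

#' Generate a random resource landscape
#'
#' Point classes (anthropogenic, fruiting plants, denning trees) are scattered
#' uniformly over the extent; meadows and water bodies are random rectangular
#' polygons. Denning trees get a `dbh` attribute large enough to count as den
#' candidates; water/meadow polygons are kept inside the extent.
#'
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` (metres).
#' @param per_class_counts Named integer vector over [resource_classes]
#'   (missing classes default to 0).
#' @param seed Integer seed; the map is a pure function of
#'   `(extent, counts, seed)`.
#' @param polygon_size Mean side length (m) of generated meadow/water
#'   rectangles.
#' @return A [resource_map].
#' @export
generate_landscape <- function(extent, per_class_counts, seed = NULL,
                               polygon_size = 40) {
  extent <- as.numeric(extent)
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent must have positive area")
  counts <- setNames(rep(0L, length(resource_classes)), resource_classes)
  counts[names(per_class_counts)] <- as.integer(per_class_counts)
  if (any(counts < 0)) stop("per_class_counts must be >= 0")
  with_seed(seed, {
    feats <- list()
    for (cls in resource_classes) {
      n <- counts[[cls]]
      if (n == 0) next
      if (cls %in% c("meadow", "water")) {
        for (i in seq_len(n)) {
          w <- runif(1, 0.5, 1.5) * polygon_size
          h <- runif(1, 0.5, 1.5) * polygon_size
          w <- min(w, (extent[3] - extent[1]) * 0.9)
          h <- min(h, (extent[4] - extent[2]) * 0.9)
          cx <- runif(1, extent[1] + w / 2, extent[3] - w / 2)
          cy <- runif(1, extent[2] + h / 2, extent[4] - h / 2)
          feats[[length(feats) + 1L]] <- list(
            class = cls, type = "polygon",
            coords = matrix(c(cx - w / 2, cy - h / 2,
                              cx + w / 2, cy - h / 2,
                              cx + w / 2, cy + h / 2,
                              cx - w / 2, cy + h / 2),
                            ncol = 2, byrow = TRUE),
            attributes = list())
        }
      } else {
        xs <- runif(n, extent[1], extent[3])
        ys <- runif(n, extent[2], extent[4])
        for (i in seq_len(n)) {
          attrs <- list()
          if (cls == "denning_tree")
            attrs <- list(dbh = runif(1, 80, 150), inside_site = TRUE)
          feats[[length(feats) + 1L]] <- list(
            class = cls, type = "point", x = xs[i], y = ys[i],
            attributes = attrs)
        }
      }
    }
    resource_map(feats, extent)
  })
}

# Den-tree screening: inside the site a tree qualifies by girth
# (DBH > 76.2 cm, strict); outside, by an opaque volume attribute (> 1000).
den_tree_qualifies <- function(f, dbh_min = 76.2, volume_min = 1000) {
  a <- f$attributes
  inside <- isTRUE(a$inside_site) || is.null(a$inside_site)
  if (inside) {
    !is.null(a$dbh) && a$dbh > dbh_min
  } else {
    !is.null(a$volume) && a$volume > volume_min
  }
}

# Features of one class after class-specific screening rules.
class_features <- function(map, class, dbh_min = 76.2, volume_min = 1000) {
  feats <- Filter(function(f) f$class == class, map$features)
  if (class == "denning_tree")
    feats <- Filter(function(f) den_tree_qualifies(f, dbh_min, volume_min),
                    feats)
  feats
}

#' Distance from points to the nearest (buffered) feature of one class
#'
#' Point features carry a 2 m buffer (distance is clamped at 0 inside it).
#' Meadow/water polygons have distance 0 inside and boundary distance
#' outside. Building-footprint polygons (attribute `use_class = "building"`)
#' are treated as a 2 m exterior ring: the interior footprint is excluded, so
#' interior points are assigned their distance to the boundary.
#'
#' @param map A [resource_map].
#' @param class One of [resource_classes].
#' @param x,y Query coordinates (metres).
#' @param point_buffer Buffer radius (m) applied around point features.
#' @return Numeric vector of distances; `Inf` when the class has no feature.
#' @export
feature_distances <- function(map, class, x, y, point_buffer = 2) {
  feats <- class_features(map, class)
  d <- rep(Inf, length(x))
  for (f in feats) {
    if (f$type == "point") {
      dk <- pmax(0, sqrt((x - f$x)^2 + (y - f$y)^2) - point_buffer)
    } else {
      ring <- dist_to_ring(x, y, f$coords)
      is_building <- identical(f$attributes$use_class, "building")
      if (is_building) {
        inside <- point_in_polygon(x, y, f$coords)
        # resource is the 2 m exterior ring only
        dk <- ifelse(inside, ring, pmax(0, ring - point_buffer))
      } else {
        inside <- point_in_polygon(x, y, f$coords)
        dk <- ifelse(inside, 0, ring)
      }
    }
    d <- pmin(d, dk)
  }
  d
}

#' Fixed landscape for the end-to-end validation scenario
#'
#' A deterministic layout used by the package's end-to-end validation:
#' six trash cans (one per dyad cluster plus two mid-edge cans), fruiting
#' plants and denning trees on an alternating 200 m lattice excluding
#' nodes within 150 m of any can (dense, short-range distance fields that
#' cannot confound the anchors), and meadow/water blocks on the far edges.
#' Implanted trash-can co-occurrences on this layout must surface as the
#' most negative contact-RSF coefficient; a drawn landscape can place
#' another class next to a can by accident, which would test the layout
#' rather than the pipeline.
#'
#' @return A [resource_map] over a 1600 m x 1600 m extent.
#' @export
validation_landscape <- function() {
  pt <- function(class, x, y, attrs = list())
    list(class = class, type = "point", x = x, y = y, attributes = attrs)
  rect <- function(class, cx, cy, half)
    list(class = class, type = "polygon",
         coords = matrix(c(cx - half, cy - half, cx + half, cy - half,
                           cx + half, cy + half, cx - half, cy + half),
                         ncol = 2, byrow = TRUE), attributes = list())
  cans <- list(c(500, 400), c(1100, 400), c(500, 1200), c(1100, 1200),
               c(800, 250), c(800, 1350))
  feats <- lapply(cans, function(p) pt("anthropogenic", p[1], p[2]))
  nodes <- expand.grid(x = seq(100, 1500, by = 200),
                       y = seq(100, 1500, by = 200))
  keep <- apply(nodes, 1, function(p)
    min(vapply(cans, function(q) sqrt(sum((p - q)^2)), numeric(1))) >= 150)
  nodes <- nodes[keep, ]
  cls <- rep(c("fruiting_plant", "denning_tree"), length.out = nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    attrs <- if (cls[i] == "denning_tree")
      list(dbh = 110, inside_site = TRUE) else list()
    feats[[length(feats) + 1]] <- pt(cls[i], nodes$x[i], nodes$y[i], attrs)
  }
  feats <- c(feats,
             list(rect("meadow", 60, 800, 25), rect("meadow", 1540, 800, 25),
                  rect("water", 800, 60, 30), rect("water", 800, 1540, 30)))
  resource_map(feats, c(0, 0, 1600, 1600))
}
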