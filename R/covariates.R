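# Distance-to-resource covariates: grid rasters of distance to the nearest
# (buffered) feature of a class, point extraction, the collinearity screen,
# z-standardization with a persisted spec, and binary 15 m presence layers.

#' Construct a raster grid specification
#'
#' Cells are referenced by their centres; the origin is the extent's
#' minimum corner.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` (m).
#' @param cell_size Cell side (m).
#' @return A `ctsp_grid` list with `xmin`, `ymin`, `cell_size`, `ncol`
#'   (x cells), `nrow` (y cells).
#' @export
raster_grid <- function(extent, cell_size = 0.25) {
  extent <- as.numeric(extent)
  structure(list(xmin = extent[1], ymin = extent[2], cell_size = cell_size,
                 ncol = ceiling((extent[3] - extent[1]) / cell_size),
                 nrow = ceiling((extent[4] - extent[2]) / cell_size)),
            class = "ctsp_grid")
}

grid_centres <- function(grid) {
  xs <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell_size
  ys <- grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cell_size
  list(xs = xs, ys = ys)
}

#' Build a distance raster for one resource class
#'
#' Point features carry a 2 m buffer, building footprints become 2 m
#' exterior rings, and den-tree candidates are screened (DBH > 76.2 cm
#' inside the site, volume > 1000 outside) before rasterization. Each cell
#' holds the Euclidean distance from its centre to the nearest buffered
#' feature, computed against the exact feature geometry.
#'
#' @param map A [resource_map].
#' @param class One of [resource_classes].
#' @param grid A `ctsp_grid` (default: the map extent at `cell_size`).
#' @param cell_size Used when `grid` is NULL.
#' @return A `ctsp_raster`: the grid plus a `values` matrix
#'   (`[x index, y index]`). An empty class yields an all-`Inf` raster with
#'   a warning.
#' @export
build_distance_raster <- function(map, class, grid = NULL, cell_size = 0.25) {
  if (is.null(grid)) grid <- raster_grid(map$extent, cell_size)
  g <- grid_centres(grid)
  gx <- rep(g$xs, times = grid$nrow)
  gy <- rep(g$ys, each = grid$ncol)
  if (length(class_features(map, class)) == 0) {
    warning("no features of class '", class, "': distance raster is Inf")
    vals <- rep(Inf, length(gx))
  } else {
    vals <- feature_distances(map, class, gx, gy)
  }
  structure(c(grid, list(values = matrix(vals, grid$ncol, grid$nrow),
                         class_name = class)),
            class = c("ctsp_raster", "ctsp_grid"))
}

#' Nearest-cell raster lookup
#'
#' @param raster A `ctsp_raster`.
#' @param x,y Query coordinates (m).
#' @param outside Value returned for out-of-extent points (default errors).
#' @return Numeric vector of cell values.
#' @export
raster_lookup <- function(raster, x, y, outside = NULL) {
  ix <- pmin(pmax(ceiling((x - raster$xmin) / raster$cell_size), 1L),
             raster$ncol)
  iy <- pmin(pmax(ceiling((y - raster$ymin) / raster$cell_size), 1L),
             raster$nrow)
  inb <- x >= raster$xmin & x <= raster$xmin + raster$ncol * raster$cell_size &
    y >= raster$ymin & y <= raster$ymin + raster$nrow * raster$cell_size
  out <- raster$values[cbind(ix, iy)]
  if (any(!inb)) {
    if (is.null(outside))
      stop("points outside raster extent at rows: ",
           paste(utils::head(which(!inb), 10), collapse = ", "))
    out[!inb] <- outside
  }
  out
}

#' Extract distance covariates for a set of points
#'
#' @param points Data frame with `x`, `y`.
#' @param rasters Named list of `ctsp_raster`s (one per class), or a
#'   [resource_map] for exact vector-geometry distances (no discretization).
#' @param classes Classes to extract when `rasters` is a map.
#' @return Tibble with one `dist_<class>` column per class.
#' @export
extract_distances <- function(points, rasters,
                              classes = resource_classes) {
  if (inherits(rasters, "resource_map")) {
    vals <- lapply(classes, function(cl)
      feature_distances(rasters, cl, points$x, points$y))
    names(vals) <- paste0("dist_", classes)
    return(tibble::as_tibble(vals))
  }
  vals <- lapply(rasters, function(r) raster_lookup(r, points$x, points$y))
  names(vals) <- paste0("dist_", names(rasters))
  tibble::as_tibble(vals)
}

#' Collinearity screen on distance covariates
#'
#' Flags covariate pairs with Pearson |r| >= `threshold` (inclusive) and
#' iteratively drops, within each offending pair, the member with the
#' larger mean absolute correlation to all other covariates.
#'
#' @param table Data frame of numeric covariates.
#' @param threshold Absolute-correlation threshold.
#' @return List with `retained`, `dropped`, and the correlation `matrix`.
#'   Zero-variance covariates are excluded before screening, with a
#'   warning.
#' @export
collinearity_screen <- function(table, threshold = 0.6) {
  stopifnot(ncol(table) >= 2, nrow(table) >= 3)
  sds <- vapply(table, sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance covariates excluded: ",
            paste(names(table)[sds == 0], collapse = ", "))
    table <- table[, sds > 0, drop = FALSE]
  }
  cm <- cor(as.matrix(table))
  keep <- colnames(cm)
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    off <- abs(sub); diag(off) <- 0
    if (all(off < threshold) || length(keep) == 1) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    # mean |r| to all other covariates (diagonal excluded)
    mean_r <- (rowSums(abs(sub)) - 1) / (length(keep) - 1)
    drop <- pair[which.max(mean_r[pair])]
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = setdiff(colnames(cm), keep), matrix = cm)
}

#' Standardize covariates (z-scores) with a persisted spec
#'
#' Means and SDs are pooled over all rows supplied (used + available) and
#' returned so that new points can be transformed identically.
#'
#' @param table Data frame of retained covariates.
#' @param spec Optional spec from a previous call, applied as-is.
#' @return List with `z` (tibble of z-scores) and `spec` (`mean`, `sd`).
#' @export
standardize_covariates <- function(table, spec = NULL) {
  if (is.null(spec)) {
    mu <- vapply(table, mean, numeric(1))
    sds <- vapply(table, sd, numeric(1))
    if (any(sds == 0))
      stop("cannot standardize constant covariate: ",
           paste(names(table)[sds == 0], collapse = ", "))
    spec <- list(mean = mu, sd = sds)
  }
  z <- as.data.frame(Map(function(v, m, s) (v - m) / s,
                         table[names(spec$mean)], spec$mean, spec$sd))
  names(z) <- paste0("z_", sub("^dist_", "", names(spec$mean)))
  list(z = tibble::as_tibble(z), spec = spec)
}

#' Binary resource-presence layer
#'
#' A cell is 1 iff its centre lies within `radius` of any (buffered)
#' feature of the class; identically the thresholded distance raster.
#'
#' @inheritParams build_distance_raster
#' @param radius Presence buffer radius (m).
#' @return A `ctsp_raster` of 0/1 values.
#' @export
binary_presence_layer <- function(map, class, radius = 15, grid = NULL,
                                  cell_size = 0.25) {
  r <- suppressWarnings(build_distance_raster(map, class, grid, cell_size))
  r$values <- (r$values <= radius) * 1
  r
}
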