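# Plain-text interchange: resource maps as GeoJSON, capture tables as CSV,
# and run configuration as YAML. jsonlite/yaml are soft dependencies.

#' Write a resource map as GeoJSON
#'
#' Coordinates are written in the map's planar metric frame.
#'
#' @param map A [resource_map].
#' @param path Output file.
#' @export
write_resource_geojson <- function(map, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write GeoJSON")
  feats <- lapply(map$features, function(f) {
    geom <- if (f$type == "point") {
      list(type = "Point", coordinates = c(f$x, f$y))
    } else {
      ring <- rbind(f$coords, f$coords[1, ])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(i)
             ring[i, ])))
    }
    list(type = "Feature", geometry = geom,
         properties = c(list(resource_class = f$class), f$attributes))
  })
  obj <- list(type = "FeatureCollection",
              bbox = map$extent[c(1, 2, 3, 4)],
              features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a resource map from GeoJSON written by [write_resource_geojson]
#' @param path Input file.
#' @return A [resource_map].
#' @export
read_resource_geojson <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read GeoJSON")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- lapply(obj$features, function(f) {
    props <- f$properties
    cls <- props$resource_class
    props$resource_class <- NULL
    if (f$geometry$type == "Point") {
      xy <- unlist(f$geometry$coordinates)
      list(class = cls, type = "point", x = xy[1], y = xy[2],
           attributes = props)
    } else {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      ring <- ring[-nrow(ring), , drop = FALSE]
      list(class = cls, type = "polygon", coords = ring,
           attributes = props)
    }
  })
  resource_map(feats, unlist(obj$bbox))
}

#' Read a capture-event table
#'
#' CSV with columns `individual_id` and `timestamp` (ISO-8601 UTC).
#' @param path Input file.
#' @return Tibble of capture events.
#' @export
read_capture_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                             tz = "UTC")
  tibble::as_tibble(df)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [sim_config].
#' @param path Input file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  args <- yaml::read_yaml(path)
  if (!is.null(args$hr_centers))
    args$hr_centers <- matrix(unlist(args$hr_centers), ncol = 2,
                              byrow = TRUE)
  do.call(sim_config, args)
}
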