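# Dyadic contact detection on the shared 1-minute grid, grouping of contact
# points into events, and event classification (duration, clock window,
# sex pairing, resource presence).

normalize_dyad <- function(id_a, id_b) {
  swap <- id_b < id_a
  list(a = ifelse(swap, id_b, id_a), b = ifelse(swap, id_a, id_b))
}

#' Detect dyadic contact points
#'
#' Minutes of the shared 1-min grid where the two predicted positions are
#' within `d_contact` of each other; runs of fewer than `min_run`
#' consecutive candidate minutes are discarded. Each retained minute yields
#' one contact point located at the dyad midpoint.
#'
#' @param track_a,track_b `predicted_track` tibbles (1-min grid).
#' @param d_contact Contact distance threshold (m).
#' @param min_run Minimum consecutive-minute run length retained.
#' @param comparator `"<="` (default) or `"<"` on the distance threshold.
#' @param method `"direct"` computes every per-minute distance;
#'   `"hash"` bins positions into `d_contact`-sized cells and only computes
#'   distances for minutes whose cells are adjacent. Results are identical.
#' @return Tibble `id_a`, `id_b`, `timestamp`, `x`, `y` (midpoint),
#'   `distance`, `x_a`, `y_a`, `x_b`, `y_b`; empty (with a message) when
#'   the tracks do not overlap in time.
#' @export
detect_contact_points <- function(track_a, track_b, d_contact = 15,
                                  min_run = 2, comparator = c("<=", "<"),
                                  method = c("direct", "hash")) {
  comparator <- match.arg(comparator)
  method <- match.arg(method)
  id_a <- attr(track_a, "individual_id")
  id_b <- attr(track_b, "individual_id")
  ma <- minute_index(track_a$timestamp)
  mb <- minute_index(track_b$timestamp)
  common <- intersect(ma, mb)
  empty <- tibble::tibble(id_a = character(), id_b = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric(), distance = numeric(),
                          x_a = numeric(), y_a = numeric(),
                          x_b = numeric(), y_b = numeric())
  if (!length(common)) {
    message("tracks have no temporal overlap")
    return(empty)
  }
  common <- sort(common)
  ia <- match(common, ma); ib <- match(common, mb)
  xa <- track_a$x[ia]; ya <- track_a$y[ia]
  xb <- track_b$x[ib]; yb <- track_b$y[ib]
  if (method == "direct") {
    dist <- sqrt((xa - xb)^2 + (ya - yb)^2)
    cand <- if (comparator == "<=") dist <= d_contact else dist < d_contact
  } else {
    # spatial hash: a pair can only be within d if their d-sized grid cells
    # are within one cell of each other on both axes
    near <- abs(floor(xa / d_contact) - floor(xb / d_contact)) <= 1 &
      abs(floor(ya / d_contact) - floor(yb / d_contact)) <= 1
    dist <- rep(Inf, length(common))
    dist[near] <- sqrt((xa[near] - xb[near])^2 + (ya[near] - yb[near])^2)
    cand <- if (comparator == "<=") dist <= d_contact else dist < d_contact
  }
  # run filter over consecutive minutes: breaks in the minute grid break runs
  grp <- cumsum(c(TRUE, diff(common) != 1L | diff(cand) != 0))
  keep <- cand & ave(cand, grp, FUN = length) >= min_run
  if (!any(keep)) return(empty)
  dy <- normalize_dyad(id_a, id_b)
  swap <- !identical(dy$a, id_a)
  tibble::tibble(
    id_a = dy$a, id_b = dy$b,
    timestamp = minute_time(common[keep]),
    x = (xa[keep] + xb[keep]) / 2, y = (ya[keep] + yb[keep]) / 2,
    distance = dist[keep],
    x_a = if (swap) xb[keep] else xa[keep],
    y_a = if (swap) yb[keep] else ya[keep],
    x_b = if (swap) xa[keep] else xb[keep],
    y_b = if (swap) ya[keep] else yb[keep])
}

#' Group contact points into contact events
#'
#' Maximal runs of consecutive minutes (1-min lag) become events. The event
#' location is the minute at which the pair was closest; ties resolve to
#' the earliest minute.
#'
#' @param points Contact-point tibble for one dyad, time-sorted.
#' @return Tibble `id_a`, `id_b`, `start`, `end`, `duration_min`, `x`, `y`,
#'   `min_distance`.
#' @export
group_events <- function(points) {
  if (nrow(points) == 0)
    return(tibble::tibble(id_a = character(), id_b = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_min = integer(), x = numeric(),
                          y = numeric(), min_distance = numeric()))
  if (nrow(unique(points[c("id_a", "id_b")])) != 1)
    stop("group_events expects points from a single dyad")
  points <- points[order(points$timestamp), ]
  m <- minute_index(points$timestamp)
  grp <- cumsum(c(1L, diff(m) != 1L))
  idx <- split(seq_len(nrow(points)), grp)
  rows <- lapply(idx, function(ii) {
    p <- points[ii, ]
    best <- which.min(p$distance)  # which.min takes the first on ties
    tibble::tibble(id_a = p$id_a[1], id_b = p$id_b[1],
                   start = p$timestamp[1], end = p$timestamp[nrow(p)],
                   duration_min = nrow(p), x = p$x[best], y = p$y[best],
                   min_distance = p$distance[best])
  })
  do.call(rbind, rows)
}

#' Classify contact events
#'
#' Adds the descriptors used by the typology analysis: duration class
#' (1-3 short, 4-6 medium, >= 7 long), clock window of the first minute
#' (foraging 21:30-04:30 local, otherwise denning), the sex pairing, and
#' binary resource presence read from 15 m presence layers at the event
#' location.
#'
#' @param events Event tibble from [group_events].
#' @param presence_layers Named list of binary rasters (see
#'   [binary_presence_layer]); conventionally `anthropogenic`, `natural`
#'   (fruiting plants) and `denning_tree`.
#' @param sexes Named character vector ("M"/"F") by individual id.
#' @param utc_offset Fixed local-time offset (hours).
#' @return The events tibble with `duration_class`, `time_class`,
#'   `sex_pair`, and one presence column per layer. Event locations outside
#'   a layer's extent get presence 0 with a warning.
#' @export
classify_event <- function(events, presence_layers, sexes, utc_offset = -4) {
  if (nrow(events) == 0) return(events)
  events$duration_class <- cut(events$duration_min, c(0, 3, 6, Inf),
                               labels = c("short", "medium", "long"))
  mod <- local_minute_of_day(events$start, utc_offset)
  foraging <- mod >= 21.5 * 60 | mod < 4.5 * 60
  events$time_class <- factor(ifelse(foraging, "foraging", "denning"),
                              levels = c("foraging", "denning"))
  sa <- unname(sexes[events$id_a]); sb <- unname(sexes[events$id_b])
  events$sex_pair <- factor(ifelse(sa == sb,
                                   ifelse(sa == "M", "MM", "FF"), "MF"),
                            levels = c("MM", "FF", "MF"))
  outside <- character()
  for (nm in names(presence_layers)) {
    v <- raster_lookup(presence_layers[[nm]], events$x, events$y,
                       outside = NA_real_)
    if (anyNA(v)) {
      outside <- c(outside, nm)
      v[is.na(v)] <- 0
    }
    events[[nm]] <- as.integer(v)
  }
  if (length(outside))
    warning("event locations outside the extent of layer(s) ",
            paste(outside, collapse = ", "), ": presence set to 0")
  events
}
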