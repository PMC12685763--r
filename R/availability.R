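# Availability (non-contact) sampling: for each contact point, five minutes
# per dyad member drawn uniformly without replacement from that member's
# eligible 1-min trajectory. Eligibility: inside the dyad's home-range
# union, within the overlapping tracking period, at least 25 m from every
# tracked individual's predicted position at that minute, and not during
# any contact involving the member.

# Minutes at which `id` takes part in any contact, from a pooled
# contact-point table.
contact_minutes <- function(contacts, id) {
  sel <- contacts$id_a == id | contacts$id_b == id
  unique(minute_index(contacts$timestamp[sel]))
}

# Eligible minute set for one member of a dyad (indices into its track).
eligible_minutes <- function(id, tracks, hr_union, all_contacts,
                             overlap, exclusion_dist = 25) {
  tr <- tracks[[id]]
  m <- minute_index(tr$timestamp)
  ok <- m >= overlap[1] & m <= overlap[2]
  ok <- ok & hr_contains(hr_union, tr$x, tr$y)
  ok <- ok & !(m %in% contact_minutes(all_contacts, id))
  # distance to every other tracked individual at the same minute
  for (other in setdiff(names(tracks), id)) {
    to <- tracks[[other]]
    mo <- minute_index(to$timestamp)
    j <- match(m, mo)
    has <- !is.na(j)
    d <- rep(Inf, length(m))
    d[has] <- sqrt((tr$x[has] - to$x[j[has]])^2 +
                     (tr$y[has] - to$y[j[has]])^2)
    ok <- ok & d >= exclusion_dist
  }
  which(ok)
}

#' Sample non-contact (available) points for a dyad
#'
#' @param contact_points Contact-point tibble for one dyad (each row seeds
#'   one availability draw).
#' @param tracks Named list of `predicted_track`s for every tracked
#'   individual (used for the proximity exclusion).
#' @param hr_union A `home_range` or list of them; the union defines the
#'   accessible area.
#' @param all_contacts Pooled contact-point tibble across all dyads (used
#'   to exclude any minute in which a member is in contact with anyone).
#' @param n_per_member Minutes drawn per member per contact point.
#' @param exclusion_dist Minimum distance (m) to any tracked individual.
#' @param seed Integer seed.
#' @return Tibble `id_a`, `id_b`, `source_individual`, `timestamp`, `x`,
#'   `y`, `weight` (1000), `contact_point` (row index). When a member has
#'   fewer eligible minutes than requested, all are taken and the shortfall
#'   is recorded in the `shortfall` attribute (never resampled).
#' @export
sample_non_contacts <- function(contact_points, tracks, hr_union,
                                all_contacts = contact_points,
                                n_per_member = 5, exclusion_dist = 25,
                                seed = NULL) {
  if (nrow(contact_points) == 0)
    stop("no contact points supplied")
  ids <- c(contact_points$id_a[1], contact_points$id_b[1])
  overlap <- c(max(vapply(ids, function(id)
    min(minute_index(tracks[[id]]$timestamp)), numeric(1))),
    min(vapply(ids, function(id)
      max(minute_index(tracks[[id]]$timestamp)), numeric(1))))
  elig <- lapply(ids, eligible_minutes, tracks = tracks,
                 hr_union = hr_union, all_contacts = all_contacts,
                 overlap = overlap, exclusion_dist = exclusion_dist)
  names(elig) <- ids
  shortfall <- list()
  with_seed(seed, {
    rows <- vector("list", nrow(contact_points) * 2L)
    k <- 0L
    for (cp in seq_len(nrow(contact_points))) {
      for (id in ids) {
        pool <- elig[[id]]
        take <- min(n_per_member, length(pool))
        if (take < n_per_member)
          shortfall[[length(shortfall) + 1L]] <-
            list(contact_point = cp, individual = id, available = length(pool))
        if (take == 0) next
        pick <- pool[sample.int(length(pool), take)]
        tr <- tracks[[id]]
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          id_a = contact_points$id_a[1], id_b = contact_points$id_b[1],
          source_individual = id, timestamp = tr$timestamp[pick],
          x = tr$x[pick], y = tr$y[pick], weight = 1000,
          contact_point = cp)
      }
    }
    out <- if (k) do.call(rbind, rows[seq_len(k)]) else
      tibble::tibble(id_a = character(), id_b = character(),
                     source_individual = character(),
                     timestamp = as.POSIXct(character(), tz = "UTC"),
                     x = numeric(), y = numeric(), weight = numeric(),
                     contact_point = integer())
    attr(out, "shortfall") <- shortfall
    out
  })
}

#' Assemble a used-available table from contacts and availability samples
#'
#' Attaches dyad summaries (contact-point and event counts) needed by the
#' dyad retention filter.
#'
#' @param contacts Pooled contact-point tibble (used rows, weight 1).
#' @param non_contacts Pooled availability tibble from
#'   [sample_non_contacts] (weight 1000).
#' @return Tibble `dyad_id`, `y`, `weight`, `x`, `y_coord`,
#'   `n_contact_points`, `n_events`.
#' @export
build_rsf_data <- function(contacts, non_contacts) {
  dyad_id <- function(a, b) paste(a, b, sep = ":")
  used <- tibble::tibble(
    dyad_id = dyad_id(contacts$id_a, contacts$id_b), y = 1L, weight = 1,
    x = contacts$x, y_coord = contacts$y)
  avail <- tibble::tibble(
    dyad_id = dyad_id(non_contacts$id_a, non_contacts$id_b), y = 0L,
    weight = 1000, x = non_contacts$x, y_coord = non_contacts$y)
  out <- rbind(used, avail)
  # per-dyad summaries from the used rows
  counts <- table(used$dyad_id)
  ev <- vapply(split(contacts, dyad_id(contacts$id_a, contacts$id_b)),
               function(p) nrow(group_events(p)), numeric(1))
  out$n_contact_points <- as.integer(counts[out$dyad_id])
  out$n_events <- as.integer(ev[out$dyad_id])
  out
}
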