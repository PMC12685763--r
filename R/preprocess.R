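# Quality control of raw GPS fixes: precision screening, capture-window
# masking, and the minimum-support gate for downstream inclusion.

#' Filter raw fixes on GPS quality
#'
#' Drops fixes that are 2D with pDOP > 5, and any fix with fewer than three
#' satellites in view. 3D fixes are retained regardless of pDOP. Fixes are
#' sorted by time within individual and exact-duplicate timestamps collapse
#' to the first by file order.
#'
#' @param fixes Tibble of raw fixes with at least `individual_id`,
#'   `timestamp`, `x`, `y`, `pdop`, `n_sats`, `fix_dim`.
#' @param pdop_max pDOP threshold for 2D fixes (strictly greater is dropped).
#' @param min_sats Minimum satellites in view (fewer is dropped).
#' @return Filtered tibble; empty input returns an empty tibble with a
#'   warning flag.
#' @export
filter_fixes <- function(fixes, pdop_max = 5, min_sats = 3) {
  if (nrow(fixes) == 0) {
    warning("empty fix table")
    return(fixes)
  }
  stopifnot(all(is.finite(fixes$x)), all(is.finite(fixes$y)))
  bad <- (fixes$fix_dim == "2D" & fixes$pdop > pdop_max) |
    fixes$n_sats < min_sats
  out <- fixes[!bad, , drop = FALSE]
  # stable sort keeps file order among equal timestamps; then dedupe
  out <- out[order(out$individual_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(paste(out$individual_id, as.numeric(out$timestamp)))
  out[!dup, , drop = FALSE]
}

#' Mask fixes around recapture events
#'
#' Removes fixes in the half-open window from 20:00 local time on the
#' capture night to 14:00 local the following afternoon. A capture whose
#' local clock time is before 14:00 is attributed to the previous night.
#'
#' @param fixes Fix tibble (any number of individuals).
#' @param capture_events Data frame with `individual_id` and `timestamp`
#'   (POSIXct UTC).
#' @param utc_offset Fixed local-time offset (hours).
#' @return Fix tibble with masked windows removed. Capture events for
#'   unknown individuals are ignored with a warning.
#' @export
apply_capture_mask <- function(fixes, capture_events, utc_offset = -4) {
  if (is.null(capture_events) || nrow(capture_events) == 0) return(fixes)
  unknown <- setdiff(unique(capture_events$individual_id),
                     unique(fixes$individual_id))
  if (length(unknown))
    warning("capture events for unknown individuals ignored: ",
            paste(unknown, collapse = ", "))
  drop <- rep(FALSE, nrow(fixes))
  for (k in seq_len(nrow(capture_events))) {
    id <- capture_events$individual_id[k]
    cap_local <- as.numeric(capture_events$timestamp[k]) + utc_offset * 3600
    day0 <- floor(cap_local / 86400) * 86400
    mod <- local_minute_of_day(capture_events$timestamp[k], utc_offset)
    if (mod < 14 * 60) day0 <- day0 - 86400  # early-hours capture: prior night
    start_local <- day0 + 20 * 3600
    end_local <- day0 + 86400 + 14 * 3600
    t_local <- as.numeric(fixes$timestamp) + utc_offset * 3600
    drop <- drop | (fixes$individual_id == id &
                      t_local >= start_local & t_local < end_local)
  }
  fixes[!drop, , drop = FALSE]
}

#' Minimum-support inclusion gate
#'
#' @param fixes One individual's fix tibble.
#' @param min_relocations Minimum fix count for inclusion (inclusive).
#' @return Logical: `TRUE` when the animal has enough relocations.
#' @export
check_min_support <- function(fixes, min_relocations = 150) {
  nrow(fixes) >= min_relocations
}
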