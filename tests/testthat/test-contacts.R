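test_that("the run filter keeps only consecutive co-occurrences", {
  d <- mk_dyad(c(20, 14, 14, 20))
  expect_equal(nrow(detect_contact_points(d$a, d$b)), 2)
  d <- mk_dyad(c(20, 14, 20, 14, 20))
  expect_equal(nrow(detect_contact_points(d$a, d$b)), 0)
  # threshold comparator: 15 m is a contact under <=, not under <
  d <- mk_dyad(c(15, 15))
  expect_equal(nrow(detect_contact_points(d$a, d$b)), 2)
  expect_equal(nrow(detect_contact_points(d$a, d$b, comparator = "<")), 0)
  # a gap in the minute grid breaks a run
  d <- mk_dyad(c(10, 10))
  d$b$timestamp[2] <- d$b$timestamp[2] + 60
  d$a$timestamp[2] <- d$a$timestamp[2] + 60
  cp <- detect_contact_points(d$a, d$b)
  expect_equal(nrow(cp), 0)
})

test_that("contact points carry the dyad midpoint and normalized ids", {
  d <- mk_dyad(c(10, 12), id_a = "RA-2", id_b = "RA-1")
  cp <- detect_contact_points(d$a, d$b)
  expect_equal(cp$id_a, rep("RA-1", 2))  # lexicographic normalization
  expect_equal(cp$x, c(5, 6))
  expect_equal(cp$distance, c(10, 12))
})

test_that("detection is symmetric and the grid hash matches brute force", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      n <- 200
      # random walks that wander in and out of contact range
      xa <- cumsum(rnorm(n, 0, 6)); ya <- cumsum(rnorm(n, 0, 6))
      xb <- xa + rnorm(n, 0, 12); yb <- ya + rnorm(n, 0, 12)
      a <- mk_track(xa, ya, id = "A"); b <- mk_track(xb, yb, id = "B")
      direct <- detect_contact_points(a, b)
      hashed <- detect_contact_points(a, b, method = "hash")
      expect_identical(direct, hashed)
      flipped <- detect_contact_points(b, a)
      expect_identical(direct, flipped)
    }
  })
})

test_that("no temporal overlap yields an empty, flagged result", {
  a <- mk_track(rep(0, 5), start = t_origin)
  b <- mk_track(rep(0, 5), id = "B", start = t_origin + 3600)
  expect_message(cp <- detect_contact_points(a, b), "overlap")
  expect_equal(nrow(cp), 0)
})

test_that("events split on gaps and locate the closest minute", {
  d <- mk_dyad(c(12, 5, 9, 20, 20, 7, 7))
  cp <- detect_contact_points(d$a, d$b)
  ev <- group_events(cp)
  expect_equal(ev$duration_min, c(3, 2))
  # first event located at its minimum-distance minute
  expect_equal(ev$min_distance[1], 5)
  expect_equal(ev$x[1], 2.5)
  # tie resolves to the earliest minute
  expect_equal(as.numeric(ev$start[2] - ev$end[1], units = "mins"), 3)
  expect_equal(minute_diff <- ev$min_distance[2], 7)
  expect_identical(ev$start[2], cp$timestamp[4])
  # duration bookkeeping: event durations sum to retained points
  expect_equal(sum(ev$duration_min), nrow(cp))
  expect_error(group_events(rbind(cp, transform(cp, id_b = "C"))),
               "single dyad")
})

test_that("event classification applies the duration, clock and layer rules", {
  feats <- list(list(class = "anthropogenic", type = "point", x = 0, y = 0,
                     attributes = list()))
  map <- resource_map(feats, c(-50, -50, 50, 50))
  grid <- raster_grid(c(-50, -50, 50, 50), cell_size = 0.2)
  layers <- list(
    anthropogenic = binary_presence_layer(map, "anthropogenic", grid = grid),
    natural = binary_presence_layer(map, "fruiting_plant", grid = grid),
    denning_tree = binary_presence_layer(map, "denning_tree", grid = grid))
  sexes <- c(A = "M", B = "F", C = "M")
  # local 21:29 vs 21:30 under UTC-4: UTC 01:29 / 01:30 next day
  mk_ev <- function(start_utc, dur, ids = c("A", "B"), x = 0, y = 0) {
    tibble::tibble(id_a = ids[1], id_b = ids[2],
                   start = as.POSIXct(start_utc, tz = "UTC"),
                   end = as.POSIXct(start_utc, tz = "UTC") + 60 * (dur - 1),
                   duration_min = dur, x = x, y = y, min_distance = 5)
  }
  ev <- rbind(mk_ev("2022-08-16 01:29:00", 6),
              mk_ev("2022-08-16 01:30:00", 7, ids = c("A", "C")),
              mk_ev("2022-08-16 02:00:00", 3, x = 14.9 + 2, y = 0),
              mk_ev("2022-08-16 02:10:00", 1, x = 15.1 + 2, y = 0))
  out <- classify_event(ev, layers, sexes)
  expect_equal(as.character(out$duration_class),
               c("medium", "long", "short", "short"))
  expect_equal(as.character(out$time_class),
               c("denning", "foraging", "foraging", "foraging"))
  expect_equal(as.character(out$sex_pair), c("MF", "MM", "MF", "MF"))
  # 15 m presence buffer sits on top of the 2 m point buffer
  expect_equal(out$anthropogenic, c(1, 1, 1, 0))
  expect_equal(out$natural, c(0, 0, 0, 0))
  # outside the layer extent: presence 0 with a warning
  far <- mk_ev("2022-08-16 03:00:00", 2, x = 500, y = 500)
  expect_warning(outf <- classify_event(far, layers, sexes), "outside")
  expect_equal(outf$anthropogenic, 0L)
})

test_that("implanted synthetic visits are recovered as single events", {
  map <- mk_map(seed = 71, extent = c(0, 0, 800, 800))
  cfg <- sim_config(n_individuals = 2, dropout_rate = 0, gps_error_sd = 3,
                    hr_centers = rbind(c(250, 250), c(510, 510)),
                    extent = c(0, 0, 800, 800), sigma2 = 8000)
  tracks <- simulate_tracks(cfg, t_origin, n_days = 8, seed = 72)
  ids <- names(tracks)
  f_idx <- which(vapply(map$features, function(f)
    f$class == "anthropogenic", logical(1)))[1]
  f <- map$features[[f_idx]]
  # three well-separated visits, including two that overlap in time and
  # must merge into one contiguous proximity run
  visits <- data.frame(
    id_a = ids[1], id_b = ids[2], feature = f_idx,
    t_start = t_origin + c(1.25, 3.25, 3.25 + 10 / (24 * 60), 5.25) * 86400,
    duration_min = c(20, 15, 15, 20))
  tracks <- implant_co_occurrences(tracks, map, visits, seed = 73)
  fits <- lapply(tracks, function(tr)
    fit_movement_models(filter_fixes(tr), models = "ou"))
  pts <- Map(function(fit, tr) predict_track(fit, filter_fixes(tr)),
             fits, tracks)
  cp <- detect_contact_points(pts[[1]], pts[[2]])
  ev <- group_events(cp)
  near <- sqrt((ev$x - f$x)^2 + (ev$y - f$y)^2) < 15
  # exactly one event per separated visit window (overlapping pair merged)
  expect_equal(sum(near), 3)
  expect_true(all(ev$duration_min[near] >= 2))
})
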