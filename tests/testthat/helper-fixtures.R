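# Shared fixture builders. Everything is generated in code at test time.

t_origin <- as.POSIXct("2022-08-15 00:00:00", tz = "UTC")

# A predicted_track on the 1-min grid from explicit coordinates.
mk_track <- function(x, y = rep(0, length(x)), id = "A",
                     start = t_origin + 2 * 3600, sex = "M") {
  n <- length(x)
  tr <- tibble::tibble(timestamp = start + 60 * (seq_len(n) - 1),
                       x = x, y = y, var = 0)
  attr(tr, "individual_id") <- id
  attr(tr, "sex") <- sex
  class(tr) <- c("predicted_track", class(tr))
  tr
}

# A dyad of tracks separated by the given per-minute distances.
mk_dyad <- function(distances, id_a = "A", id_b = "B", start = t_origin) {
  list(a = mk_track(rep(0, length(distances)), id = id_a, start = start),
       b = mk_track(distances, id = id_b, start = start))
}

# Raw fixes with clean quality metadata at a regular interval.
mk_fixes <- function(x, y, interval_s = 900, id = "RA-001",
                     start = t_origin) {
  n <- length(x)
  tibble::tibble(individual_id = id, sex = "M",
                 timestamp = start + interval_s * (seq_len(n) - 1),
                 x = x, y = y, pdop = 2.5, n_sats = 8L, fix_dim = "3D")
}

# A movement_fit object without going through the optimizer.
mk_fit <- function(model_form = "OU", mu = c(0, 0), sigma2 = 1e4,
                   tau_pos = 2, tau_vel = NULL, error_var = 0,
                   span_h = 480) {
  structure(list(model_form = model_form, mu = mu, sigma2 = sigma2,
                 tau_pos = tau_pos, tau_vel = tau_vel,
                 error_var = error_var, loglik = NA_real_,
                 aicc = NA_real_, n_fixes = NA_integer_,
                 tracking_span_h = span_h),
            class = "movement_fit")
}

# Random classified events table for MCA tests.
mk_events <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    duration_class = factor(sample(c("short", "medium", "long"), n, TRUE),
                            levels = c("short", "medium", "long")),
    sex_pair = factor(sample(c("MM", "FF", "MF"), n, TRUE)),
    time_class = factor(sample(c("foraging", "denning"), n, TRUE)),
    anthropogenic = sample(0:1, n, TRUE),
    natural = sample(0:1, n, TRUE),
    denning_tree = sample(0:1, n, TRUE)))
}

# Small landscape shared by covariate tests.
mk_map <- function(seed = 11, extent = c(0, 0, 400, 400)) {
  generate_landscape(extent, c(anthropogenic = 4, fruiting_plant = 5,
                               denning_tree = 5, meadow = 2, water = 1),
                     seed = seed)
}
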