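test_that("OU track sampling matches the stationary and transition law", {
  cfg <- sim_config(n_individuals = 1, tau_pos = 1, sigma2 = 1e4,
                    gps_error_sd = 0, dropout_rate = 0,
                    hr_centers = matrix(c(500, 400), 1))
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 60 * 86400, seed = 2)
  n <- nrow(tr)
  # stationary variance: per-axis sample variance ~ sigma2. The effective
  # number of independent samples is ~ tracking hours / (2 tau), giving an
  # MC standard error of sigma2 * sqrt(2 / n_eff).
  n_eff <- 60 * 24 / (2 * cfg$tau_pos)
  se <- cfg$sigma2 * sqrt(2 / n_eff)
  expect_lt(abs(var(tr$x) - cfg$sigma2), 3 * se)
  expect_lt(abs(var(tr$y) - cfg$sigma2), 3 * se)
  expect_lt(abs(mean(tr$x) - 500), 4 * sqrt(cfg$sigma2 * 2 / n_eff))

  # transition moments: regress x(t+dt) - mu on x(t) - mu over the regular
  # 15-min night steps; slope estimates exp(-dt/tau)
  dt_h <- diff(as.numeric(tr$timestamp)) / 3600
  i <- which(abs(dt_h - 0.25) < 1e-9)
  reg <- summary(lm(I(tr$x[i + 1] - 500) ~ 0 + I(tr$x[i] - 500)))
  expect_lt(abs(reg$coefficients[1, 1] - exp(-0.25 / 1)),
            3 * reg$coefficients[1, 2])

  # decorrelation limit: pairs more than 20 tau apart are uncorrelated
  idx <- seq(1, n, by = 96)   # ~1-day spacing at night cadence
  r <- cor(tr$x[idx[-length(idx)]], tr$x[idx[-1]])
  expect_lt(abs(r), 3 / sqrt(length(idx)) + 0.1)
})

test_that("degenerate variance pins every fix to the centre plus GPS noise", {
  cfg <- sim_config(n_individuals = 1, sigma2 = 0, gps_error_sd = 3,
                    dropout_rate = 0, hr_centers = matrix(c(50, 60), 1))
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 5 * 86400, seed = 3)
  expect_true(all(tr$x_true == 50))
  expect_true(all(tr$y_true == 60))
  expect_lt(max(abs(tr$x - 50)), 5 * 3)
  expect_error(simulate_ou_track(sim_config(tau_pos = -1), 1, t_origin,
                                 t_origin + 86400), "tau_pos")
})

test_that("tracks are pure functions of (config, seed) and dropouts thin", {
  cfg <- sim_config(n_individuals = 2, dropout_rate = 0.2)
  a <- simulate_ou_track(cfg, 1, t_origin, t_origin + 10 * 86400, seed = 9)
  b <- simulate_ou_track(cfg, 1, t_origin, t_origin + 10 * 86400, seed = 9)
  expect_identical(a, b)
  cfg0 <- sim_config(n_individuals = 2, dropout_rate = 0)
  full <- simulate_ou_track(cfg0, 1, t_origin, t_origin + 10 * 86400,
                            seed = 9)
  expect_lt(nrow(a), nrow(full))
  expect_equal(nrow(a) / nrow(full), 0.8, tolerance = 0.07)
})

test_that("duty cycle covers the night window at 15 min plus 4-h day fixes", {
  cfg <- sim_config()
  times <- duty_cycle_times(t_origin, t_origin + 2 * 86400, cfg)
  mod <- (as.numeric(times) / 3600 - 4) %% 24  # local hour (UTC-4)
  night <- mod >= 19 | mod < 7
  expect_true(all(diff(as.numeric(times[night])) %% 900 == 0))
  day_hours <- sort(unique(round(mod[!night], 4)))
  expect_equal(day_hours, c(11, 15))
})

test_that("implanted co-occurrences deform only the visit window", {
  map <- mk_map(seed = 2, extent = c(0, 0, 600, 600))
  cfg <- sim_config(n_individuals = 2, dropout_rate = 0,
                    hr_centers = rbind(c(250, 250), c(280, 280)),
                    extent = c(0, 0, 600, 600))
  tracks <- simulate_tracks(cfg, t_origin, n_days = 6, seed = 5)
  ids <- names(tracks)
  expect_identical(implant_co_occurrences(tracks, map,
                                          data.frame()[0, ]), tracks)

  f_idx <- which(vapply(map$features, function(f)
    f$class == "anthropogenic", logical(1)))[1]
  f <- map$features[[f_idx]]
  visit <- data.frame(id_a = ids[1], id_b = ids[2], feature = f_idx,
                      t_start = t_origin + 86400 + 2 * 3600,
                      duration_min = 30)
  out <- implant_co_occurrences(tracks, map, visit, seed = 7)
  t0 <- as.numeric(visit$t_start); t1 <- t0 + 30 * 60
  for (id in ids) {
    tt <- as.numeric(tracks[[id]]$timestamp)
    inwin <- tt >= t0 & tt <= t1
    faroff <- tt < t0 - 600 | tt > t1 + 600
    # fixes inside the window sit at the anchor; far fixes are bit-identical
    expect_true(all(sqrt((out[[id]]$x[inwin] - f$x)^2 +
                           (out[[id]]$y[inwin] - f$y)^2) < 7.5))
    expect_identical(out[[id]]$x[faroff], tracks[[id]]$x[faroff])
    expect_identical(out[[id]]$y[faroff], tracks[[id]]$y[faroff])
    expect_gt(sum(inwin), 0)
  }
  # the dyad stays within the contact threshold throughout the window
  ia <- as.numeric(out[[1]]$timestamp) >= t0 & as.numeric(out[[1]]$timestamp) <= t1
  ib <- as.numeric(out[[2]]$timestamp) >= t0 & as.numeric(out[[2]]$timestamp) <= t1
  common <- intersect(as.numeric(out[[1]]$timestamp[ia]),
                      as.numeric(out[[2]]$timestamp[ib]))
  xa <- out[[1]]$x[match(common, as.numeric(out[[1]]$timestamp))]
  xb <- out[[2]]$x[match(common, as.numeric(out[[2]]$timestamp))]
  ya <- out[[1]]$y[match(common, as.numeric(out[[1]]$timestamp))]
  yb <- out[[2]]$y[match(common, as.numeric(out[[2]]$timestamp))]
  expect_true(all(sqrt((xa - xb)^2 + (ya - yb)^2) < 15))
  expect_error(
    implant_co_occurrences(tracks, map,
                           transform(visit, t_start = t_origin - 86400)),
    "tracking period")
})

test_that("used-available generator reflects its true coefficients", {
  map <- generate_landscape(c(0, 0, 1200, 1200),
                            c(anthropogenic = 10, fruiting_plant = 12,
                              denning_tree = 12, meadow = 3, water = 2),
                            seed = 31)
  # null selection: used and available means agree within sampling error
  beta0 <- setNames(rep(0, 5), resource_classes)
  cfg0 <- true_rsf_config(beta0, n_used_per_dyad = 200, n_dyads = 4)
  tab0 <- generate_used_available(cfg0, map, seed = 41)
  for (cl in resource_classes) {
    z <- tab0[[paste0("z_", cl)]]
    d <- mean(z[tab0$y == 1]) - mean(z[tab0$y == 0])
    se <- sd(z) * sqrt(1 / sum(tab0$y == 1) + 1 / sum(tab0$y == 0))
    expect_lt(abs(d), 4 * se)
  }
  # directional selection shifts the targeted covariate down
  beta1 <- setNames(c(-1, 0, 0, 0, 0), resource_classes)
  cfg1 <- true_rsf_config(beta1, n_used_per_dyad = 200, n_dyads = 4)
  tab1 <- generate_used_available(cfg1, map, seed = 42)
  z1 <- tab1$z_anthropogenic
  expect_lt(mean(z1[tab1$y == 1]), mean(z1[tab1$y == 0]) - 0.2)
  # weights and ratio contract
  expect_true(all(tab1$weight[tab1$y == 1] == 1))
  expect_true(all(tab1$weight[tab1$y == 0] == 1000))
  expect_equal(sum(tab1$y == 0) / sum(tab1$y == 1), 10)
  # byte-identical under a fixed seed
  expect_identical(tab1, generate_used_available(cfg1, map, seed = 42))
})

test_that("rejection sampling realizes the exp(beta z) selection ratio", {
  # single active covariate; compare the used/available density ratio at two
  # covariate values against exp(beta dz), via an independent logistic fit
  map <- generate_landscape(c(0, 0, 1200, 1200),
                            c(anthropogenic = 10, fruiting_plant = 12,
                              denning_tree = 12, meadow = 3, water = 2),
                            seed = 31)
  beta <- setNames(c(-0.8, 0, 0, 0, 0), resource_classes)
  cfg <- true_rsf_config(beta, n_used_per_dyad = 400, n_dyads = 2)
  tab <- generate_used_available(cfg, map, seed = 43)
  fit <- suppressWarnings(
    glm(y ~ z_anthropogenic + z_fruiting_plant + z_denning_tree +
          z_meadow + z_water, family = binomial(), data = tab))
  b <- coef(fit)[["z_anthropogenic"]]
  se <- sqrt(diag(vcov(fit)))[["z_anthropogenic"]]
  expect_lt(abs(b - (-0.8)), 3 * se)
})

test_that("relocation CSV round-trips", {
  cfg <- sim_config(n_individuals = 1)
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 3 * 86400, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_relocations(tr, path)
  back <- read_relocations(path)
  expect_equal(back$x, tr$x)
  expect_equal(as.numeric(back$timestamp), as.numeric(tr$timestamp))
  expect_setequal(names(back), c("individual_id", "timestamp", "x", "y",
                                 "pdop", "n_sats", "fix_dim"))
})
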