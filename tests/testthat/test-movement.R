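test_that("sequential filter equals dense Gaussian likelihood", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      n <- sample(5:12, 1)
      fx <- mk_fixes(x = rnorm(n, 0, 80), y = rnorm(n, 0, 80),
                     interval_s = sample(c(900, 1800, 3600), 1))
      # irregular gap
      fx$timestamp[n] <- fx$timestamp[n] + 7200
      pars <- list(mu = c(rnorm(1, 0, 20), rnorm(1, 0, 20)),
                   sigma2 = exp(rnorm(1, log(8000), 0.3)),
                   tau_pos = exp(rnorm(1, log(2), 0.3)),
                   error_var = runif(1, 0, 50))
      for (m in c("iid", "ou", "ouf")) {
        tv <- if (m == "ouf") pars$tau_pos * 0.3 else NULL
        lf <- movement_loglik(fx, m, pars$mu, pars$sigma2, pars$tau_pos,
                              tv, pars$error_var, method = "filter")
        ld <- movement_loglik(fx, m, pars$mu, pars$sigma2, pars$tau_pos,
                              tv, pars$error_var, method = "direct")
        expect_lt(abs(lf - ld), 1e-8)
      }
    }
  })
})

test_that("AICc carries the small-sample penalty and the divergence guard", {
  cfg <- sim_config(n_individuals = 1, tau_pos = 2, sigma2 = 1e4,
                    gps_error_sd = 5, dropout_rate = 0,
                    hr_centers = matrix(c(0, 0), 1))
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 6 * 86400, seed = 4)
  fit <- fit_movement_models(tr, models = "ou", error = 25)
  k <- 4  # mu (2), sigma2, tau
  n <- nrow(tr)
  expect_equal(fit$aicc,
               -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  # n - k - 1 <= 0 leaves AICc infinite rather than negative
  tiny <- fit_movement_models(tr[1:5, ], models = "ouf", error = 25)
  expect_true(is.infinite(tiny$fits$aicc[tiny$fits$model == "OUF"]))
})

test_that("model selection identifies uncorrelated data as IID", {
  # sigma2 = 0 leaves only white GPS noise: an IID position process
  cfg <- sim_config(n_individuals = 1, sigma2 = 0, gps_error_sd = 20,
                    dropout_rate = 0, hr_centers = matrix(c(0, 0), 1))
  hits <- 0
  for (s in 1:5) {
    tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 11 * 86400,
                            seed = s)[1:500, ]
    fit <- fit_movement_models(tr)
    hits <- hits + (fit$model_form == "IID")
  }
  expect_gte(hits, 4)
})

test_that("OU parameters are recovered from simulated tracks", {
  cfg <- sim_config(n_individuals = 1, tau_pos = 4, sigma2 = 1e4,
                    gps_error_sd = 5, dropout_rate = 0,
                    hr_centers = matrix(c(0, 0), 1))
  taus <- sig <- numeric(5)
  for (s in 1:5) {
    tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 40 * 86400,
                            seed = 10 + s)
    fit <- fit_movement_models(tr, models = "ou")
    taus[s] <- fit$tau_pos; sig[s] <- fit$sigma2
  }
  expect_lt(abs(median(taus) - 4) / 4, 0.25)
  expect_lt(abs(median(sig) - 1e4) / 1e4, 0.25)
})

test_that("crossing time reads the position timescale of the best model", {
  expect_equal(crossing_time(mk_fit(tau_pos = 2.81)), 2.81)
  ouf <- mk_fit(model_form = "OUF", tau_pos = 3, tau_vel = 0.5)
  expect_equal(crossing_time(ouf), 3)   # position, not velocity, timescale
  expect_error(crossing_time(mk_fit(model_form = "IID")), "IID")
})

test_that("interpolation passes through error-free fixes on the grid", {
  withr::with_seed(41, {
    fx <- mk_fixes(x = rnorm(20, 0, 50), y = rnorm(20, 0, 50),
                   interval_s = 900)
    fit <- mk_fit(sigma2 = 2500, tau_pos = 2, error_var = 0)
    pt <- predict_track(fit, fx)
    expect_equal(as.numeric(diff(pt$timestamp[1:2]), units = "secs"), 60)
    # grid clipped to the observed span
    expect_gte(min(pt$timestamp), min(fx$timestamp))
    expect_lte(max(pt$timestamp), max(fx$timestamp))
    at_obs <- match(as.numeric(fx$timestamp), as.numeric(pt$timestamp))
    expect_equal(pt$x[at_obs], fx$x, tolerance = 1e-10)
    expect_equal(pt$var[at_obs], rep(0, 20), tolerance = 1e-8)
    expect_error(predict_track(mk_fit(model_form = "IID"), fx), "IID")
  })
})

test_that("the bridge tends to linear interpolation as tau grows", {
  fx <- mk_fixes(x = c(0, 100), y = c(0, 50), interval_s = 3600)
  fit <- mk_fit(sigma2 = 1e4, tau_pos = 1e6, error_var = 0)
  pt <- predict_track(fit, fx)
  frac <- seq(0, 1, length.out = nrow(pt))
  expect_equal(pt$x, frac * 100, tolerance = 1e-3)
  expect_equal(pt$y, frac * 50, tolerance = 1e-3)
})

test_that("two-point bridge matches the full-track smoother", {
  cfg <- sim_config(n_individuals = 1, tau_pos = 2, sigma2 = 1e4,
                    gps_error_sd = 5, dropout_rate = 0,
                    hr_centers = matrix(c(0, 0), 1))
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 10 * 86400,
                          seed = 9)[1:30, ]
  # error-free: the OU bridge is the exact smoother (Markov property)
  fit0 <- fit_movement_models(tr, models = "ou", error = 0)
  b0 <- predict_track(fit0, tr)
  s0 <- predict_track(fit0, tr, method = "smoother")
  expect_lt(max(abs(b0$x - s0$x), abs(b0$y - s0$y)), 1e-6)
  # with a GPS error nugget the two stay within 5% of the typical
  # prediction SD
  fit1 <- fit_movement_models(tr, models = "ou", error = 25)
  b1 <- predict_track(fit1, tr)
  s1 <- predict_track(fit1, tr, method = "smoother")
  typ_sd <- median(sqrt(s1$var))
  expect_lt(max(abs(b1$x - s1$x), abs(b1$y - s1$y)) / typ_sd, 0.05)
})

test_that("interpolation stays inside a sane envelope around the data", {
  cfg <- sim_config(n_individuals = 1, tau_pos = 2, sigma2 = 1e4,
                    gps_error_sd = 5, dropout_rate = 0,
                    hr_centers = matrix(c(0, 0), 1))
  tr <- simulate_ou_track(cfg, 1, t_origin, t_origin + 8 * 86400, seed = 13)
  fit <- fit_movement_models(tr, models = "ou")
  pt <- predict_track(fit, tr)
  sdp <- sqrt(pmax(pt$var, 0))
  expect_true(all(pt$x <= max(tr$x) + 3 * sdp + 1e-9))
  expect_true(all(pt$x >= min(tr$x) - 3 * sdp - 1e-9))
})
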