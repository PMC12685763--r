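# Continuous-time movement models fitted by exact Gaussian likelihood.
# Candidate forms: IID (uncorrelated positions), OU (range-resident
# autocorrelated positions, timescale tau_pos), and OUF (OU position with
# correlated velocities, second timescale tau_vel < tau_pos). Likelihoods
# are computed by a sequential Kalman filter over irregular gaps (1-state
# per axis for OU, 2-state for OUF) with the GPS error variance as a nugget;
# a dense multivariate-Gaussian evaluation from the model autocovariance is
# retained as an independent route.

# Position autocovariance function (one axis), dt in hours.
model_acf <- function(model, sigma2, tau_pos = NULL, tau_vel = NULL) {
  switch(model,
    iid = function(dt) ifelse(dt == 0, sigma2, 0),
    ou = function(dt) sigma2 * exp(-dt / tau_pos),
    ouf = function(dt) {
      sigma2 * (tau_pos * exp(-dt / tau_pos) - tau_vel * exp(-dt / tau_vel)) /
        (tau_pos - tau_vel)
    },
    stop("unknown model: ", model))
}

#' Exact log-likelihood of a movement model
#'
#' @param fixes Fix tibble (`timestamp`, `x`, `y`).
#' @param model One of `"iid"`, `"ou"`, `"ouf"`.
#' @param mu Length-2 centre (m).
#' @param sigma2 Stationary per-axis variance (m^2).
#' @param tau_pos,tau_vel Timescales (h); `tau_vel` only for OUF.
#' @param error_var GPS error variance nugget (m^2).
#' @param method `"filter"` (sequential Kalman) or `"direct"` (dense
#'   multivariate Gaussian); the two agree to numerical precision.
#' @return Log-likelihood (both axes).
#' @export
movement_loglik <- function(fixes, model, mu, sigma2, tau_pos = NULL,
                            tau_vel = NULL, error_var = 0,
                            method = c("filter", "direct")) {
  method <- match.arg(method)
  t_h <- (as.numeric(fixes$timestamp) - as.numeric(fixes$timestamp[1])) / 3600
  X <- cbind(fixes$x, fixes$y)
  if (method == "filter")
    kalman_loglik(model, t_h, X, mu, sigma2, tau_pos, tau_vel, error_var)
  else
    direct_loglik(model, t_h, X, mu, sigma2, tau_pos, tau_vel, error_var)
}

direct_loglik <- function(model, t_h, X, mu, sigma2, tau_pos, tau_vel,
                          error_var) {
  n <- nrow(X)
  k <- model_acf(model, sigma2, tau_pos, tau_vel)
  D <- abs(outer(t_h, t_h, "-"))
  C <- k(D)
  diag(C) <- sigma2 + error_var
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  ll <- 0
  for (ax in 1:2) {
    r <- X[, ax] - mu[ax]
    z <- backsolve(L, r, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  }
  ll
}

kalman_loglik <- function(model, t_h, X, mu, sigma2, tau_pos, tau_vel,
                          error_var) {
  n <- nrow(X)
  R <- error_var
  if (model == "iid") {
    s <- sqrt(sigma2 + R)
    return(sum(dnorm(X[, 1], mu[1], s, log = TRUE)) +
             sum(dnorm(X[, 2], mu[2], s, log = TRUE)))
  }
  if (sigma2 <= 0) return(-Inf)
  if (model == "ou")
    .ou_filter_cpp(t_h, X[, 1], X[, 2], mu[1], mu[2], sigma2, tau_pos, R)
  else
    .ouf_filter_cpp(t_h, X[, 1], X[, 2], mu[1], mu[2], sigma2, tau_pos,
                    tau_vel, R)
}

#' Fit candidate movement models and select by AICc
#'
#' Fits IID, OU and OUF by maximum likelihood (sequential filter over the
#' irregular fix schedule, GPS error as a fitted or fixed nugget) and
#' returns the minimum-AICc model.
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, infinite when `n - k - 1 <= 0`.
#'
#' @param fixes QC-passed fix tibble for one individual.
#' @param models Candidate forms to fit.
#' @param error GPS error variance (m^2): a number to fix the nugget, or
#'   `NULL` to estimate it (OU/OUF; for IID the nugget is absorbed into the
#'   variance).
#' @return A `movement_fit` with fields `model_form`, `mu`, `sigma2`,
#'   `tau_pos`, `tau_vel`, `error_var`, `loglik`, `aicc`, `n_fixes`, and the
#'   per-model AICc ladder in `$fits`.
#' @export
fit_movement_models <- function(fixes, models = c("iid", "ou", "ouf"),
                                error = NULL) {
  n <- nrow(fixes)
  if (n < 4) stop("too few fixes to fit movement models")
  t_h <- (as.numeric(fixes$timestamp) - as.numeric(fixes$timestamp[1])) / 3600
  X <- cbind(fixes$x, fixes$y)
  mu0 <- colMeans(X)
  s20 <- mean(c(var(X[, 1]), var(X[, 2])))
  span <- max(t_h)
  dt_med <- stats::median(diff(t_h))
  fit_error <- is.null(error)
  fixed_R <- if (fit_error) 0 else error

  unpack <- function(theta, model) {
    p <- list(mu = theta[1:2], sigma2 = exp(theta[3]),
              tau_pos = NULL, tau_vel = NULL,
              error_var = fixed_R)
    j <- 3
    if (model != "iid") { j <- j + 1; p$tau_pos <- exp(theta[j]) }
    if (model == "ouf") { j <- j + 1
      p$tau_vel <- p$tau_pos * stats::plogis(theta[j]) }
    if (fit_error && model != "iid") { j <- j + 1
      p$error_var <- exp(theta[j]) }
    p
  }
  nll <- function(theta, model) {
    p <- unpack(theta, model)
    if (model == "ouf" && p$tau_vel >= p$tau_pos * 0.999) return(1e10)
    ll <- kalman_loglik(model, t_h, X, p$mu, p$sigma2, p$tau_pos, p$tau_vel,
                        p$error_var)
    if (!is.finite(ll)) 1e10 else -ll
  }
  results <- list()
  for (model in models) {
    starts <- list()
    base <- c(mu0, log(s20))
    if (model == "iid") {
      starts[[1]] <- base
    } else {
      for (tau0 in unique(pmax(c(2 * dt_med, span / 10), 1e-3))) {
        th <- c(base, log(tau0))
        if (model == "ouf") th <- c(th, stats::qlogis(0.3))
        if (fit_error) th <- c(th, log(max(s20 / 100, 1)))
        starts[[length(starts) + 1]] <- th
      }
    }
    best <- NULL
    for (th0 in starts) {
      opt <- tryCatch(
        optim(th0, nll, model = model, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best)) next
    p <- unpack(best$par, model)
    k <- length(best$par)
    ll <- -best$value
    aicc <- if (n - k - 1 <= 0) Inf else
      -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    results[[model]] <- list(model_form = toupper(model), mu = p$mu,
                             sigma2 = p$sigma2, tau_pos = p$tau_pos,
                             tau_vel = p$tau_vel, error_var = p$error_var,
                             loglik = ll, aicc = aicc, k = k,
                             convergence = best$convergence)
  }
  if (!length(results))
    stop("no movement model converged")
  ladder <- tibble::tibble(
    model = vapply(results, `[[`, character(1), "model_form"),
    loglik = vapply(results, `[[`, numeric(1), "loglik"),
    k = vapply(results, `[[`, numeric(1), "k"),
    aicc = vapply(results, `[[`, numeric(1), "aicc"))
  best <- results[[which.min(ladder$aicc)]]
  best$n_fixes <- n
  best$fits <- ladder[order(ladder$aicc), ]
  best$tracking_span_h <- span
  best$individual_id <- if ("individual_id" %in% names(fixes))
    fixes$individual_id[1] else NA_character_
  class(best) <- "movement_fit"
  best
}

#' @export
print.movement_fit <- function(x, ...) {
  cat("<movement_fit>", x$model_form, "| n =", x$n_fixes, "\n")
  cat(sprintf("  sigma2 = %.1f m^2", x$sigma2))
  if (!is.null(x$tau_pos)) cat(sprintf(", tau_pos = %.2f h", x$tau_pos))
  if (!is.null(x$tau_vel)) cat(sprintf(", tau_vel = %.2f h", x$tau_vel))
  cat(sprintf(", error_var = %.1f m^2\n", x$error_var))
  cat(sprintf("  logLik = %.2f, AICc = %.2f\n", x$loglik, x$aicc))
  invisible(x)
}

#' Home-range crossing time
#'
#' The position autocorrelation timescale of the selected model, read as the
#' characteristic time to traverse the home range.
#'
#' @param fit A `movement_fit` (OU or OUF).
#' @return Crossing time in hours.
#' @export
crossing_time <- function(fit) {
  if (fit$model_form == "IID")
    stop("crossing time is undefined for an IID fit")
  fit$tau_pos
}

#' Predict a 1-minute track by conditional-mean interpolation
#'
#' Conditional mean of the fitted Gaussian process at each grid time given
#' the two flanking observed fixes (an OU bridge under the model's
#' autocovariance), with the per-axis prediction variance. The grid is
#' clipped to the observed span (no extrapolation). With
#' `method = "smoother"` the prediction conditions on every fix (dense
#' solve); the two routes agree closely and the bridge is the default.
#'
#' @param fit A `movement_fit` with `model_form` OU or OUF.
#' @param fixes The fix tibble the model was fitted to.
#' @param dt Grid spacing in seconds (default 60).
#' @param method `"bridge"` (two flanking fixes) or `"smoother"` (all
#'   fixes).
#' @return Tibble `timestamp`, `x`, `y`, `var` (per-axis prediction
#'   variance, m^2) of class `predicted_track`.
#' @export
predict_track <- function(fit, fixes, dt = 60, method = c("bridge",
                                                          "smoother")) {
  method <- match.arg(method)
  if (fit$model_form == "IID")
    stop("interpolation is undefined for an IID fit")
  ord <- order(fixes$timestamp)
  fixes <- fixes[ord, ]
  tt <- as.numeric(fixes$timestamp)
  t0 <- ceiling(tt[1] / dt) * dt
  t1 <- floor(tt[length(tt)] / dt) * dt
  if (t1 < t0) stop("no grid times inside the observed span")
  tg <- seq(t0, t1, by = dt)
  th <- (tt - tt[1]) / 3600
  gh <- (tg - tt[1]) / 3600
  kfun <- model_acf(tolower(fit$model_form), fit$sigma2, fit$tau_pos,
                    fit$tau_vel)
  R <- fit$error_var
  mu <- fit$mu
  if (method == "smoother") {
    C <- kfun(abs(outer(th, th, "-")))
    diag(C) <- fit$sigma2 + R
    Ci <- solve(C)
    Kgo <- kfun(abs(outer(gh, th, "-")))
    W <- Kgo %*% Ci
    px <- mu[1] + W %*% (fixes$x - mu[1])
    py <- mu[2] + W %*% (fixes$y - mu[2])
    pv <- pmax(0, fit$sigma2 - rowSums(W * Kgo))
    out <- tibble::tibble(timestamp = minute_time(tg / 60), x = as.numeric(px),
                          y = as.numeric(py), var = pv)
  } else {
    i <- findInterval(gh, th, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(th) - 1L)
    d1 <- gh - th[i]
    d2 <- th[i + 1L] - gh
    k1 <- kfun(d1); k2 <- kfun(d2)
    c12 <- kfun(th[i + 1L] - th[i])
    v0 <- fit$sigma2 + R
    det <- v0^2 - c12^2
    w1 <- (k1 * v0 - k2 * c12) / det
    w2 <- (k2 * v0 - k1 * c12) / det
    px <- mu[1] + w1 * (fixes$x[i] - mu[1]) + w2 * (fixes$x[i + 1L] - mu[1])
    py <- mu[2] + w1 * (fixes$y[i] - mu[2]) + w2 * (fixes$y[i + 1L] - mu[2])
    pv <- pmax(0, fit$sigma2 - (w1 * k1 + w2 * k2))
    out <- tibble::tibble(timestamp = minute_time(tg / 60), x = px, y = py,
                          var = pv)
  }
  attr(out, "individual_id") <- if ("individual_id" %in% names(fixes))
    fixes$individual_id[1] else NA_character_
  attr(out, "sex") <- if ("sex" %in% names(fixes)) fixes$sex[1] else
    NA_character_
  class(out) <- c("predicted_track", class(out))
  out
}
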