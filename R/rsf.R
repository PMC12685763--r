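# Population-level contact RSF: weighted mixed logistic regression with a
# fixed large intercept variance per dyad and random slopes for each
# distance covariate (Muff-style inhomogeneous point-process weighting:
# available rows carry weight 1000, used rows weight 1). Fitting goes
# through glmmTMB (Laplace approximation); a hand-written IRLS fitter for
# the no-random-effect model is exported as an independent cross-check.

#' Retain dyads with enough support
#'
#' @param data Used-available tibble with `dyad_id`, `n_contact_points`,
#'   `n_events` columns (see [build_rsf_data]).
#' @param min_points Minimum contact points per dyad (inclusive).
#' @param min_events Minimum distinct contact events per dyad (inclusive).
#' @return Filtered tibble (used and available rows of failing dyads both
#'   removed); errors when nothing remains.
#' @export
filter_dyads <- function(data, min_points = 10, min_events = 2) {
  keep <- data$n_contact_points >= min_points & data$n_events >= min_events
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no dyads satisfy the retention thresholds")
  out
}

#' Fit the weighted mixed logistic contact RSF
#'
#' Logit-linear model for used (1) versus available (0) rows with weights
#' 1/1000, a per-dyad random intercept whose variance is fixed at a large
#' constant (default 1e6, imposed through the optimizer's parameter map so
#' it is never estimated), and independent random slopes per covariate.
#'
#' @param data Used-available tibble with `dyad_id`, `y`, `weight` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param random_slopes Include per-dyad random slopes for every covariate.
#' @param random_effects `"dyad"` for the mixed model, `"none"` for plain
#'   weighted logistic regression (no grouping terms).
#' @param intercept_variance Fixed variance of the dyad intercept.
#' @return An `rsf_fit`: `coefficients` tibble (term, beta, se, p, rss and
#'   Wald CI), `slope_sd`, `ranef` (dyad conditional modes), `loglik`,
#'   `aic`, `n_dyads`, and the underlying `model`.
#' @export
fit_rsf <- function(data, covariates, random_slopes = TRUE,
                    random_effects = c("dyad", "none"),
                    intercept_variance = 1e6) {
  random_effects <- match.arg(random_effects)
  stopifnot(all(covariates %in% names(data)))
  fixed <- paste(c("1", covariates), collapse = " + ")
  if (random_effects == "none") {
    form <- as.formula(paste("y ~", fixed))
    mod <- glmmTMB::glmmTMB(form, data = data, family = binomial(),
                            weights = weight)
  } else {
    re <- c("(1 | dyad_id)",
            if (random_slopes)
              paste0("(0 + ", covariates, " | dyad_id)"))
    form <- as.formula(paste("y ~", fixed, "+", paste(re, collapse = " + ")))
    n_theta <- 1L + if (random_slopes) length(covariates) else 0L
    map <- list(theta = factor(c(NA, seq_len(n_theta - 1L))))
    start <- list(theta = c(log(sqrt(intercept_variance)),
                            rep(log(0.1), n_theta - 1L)))
    mod <- glmmTMB::glmmTMB(form, data = data, family = binomial(),
                            weights = weight, map = map, start = start)
    if (random_slopes) {
      # singular slope variances (components collapsing to zero) leave the
      # Hessian non-positive-definite; refit with those components fixed at 0
      vc0 <- glmmTMB::VarCorr(mod)$cond
      sds <- vapply(seq_along(vc0)[-1], function(i)
        sqrt(vc0[[i]][1, 1]), numeric(1))
      singular <- !isTRUE(mod$sdr$pdHess) | !is.finite(AIC(mod))
      if (singular && any(sds < 1e-3)) {
        keep_cov <- covariates[sds >= 1e-3]
        warning("singular random-slope variance for ",
                paste(covariates[sds < 1e-3], collapse = ", "),
                ": component fixed at 0 and model refitted")
        re <- c("(1 | dyad_id)",
                if (length(keep_cov)) paste0("(0 + ", keep_cov,
                                             " | dyad_id)"))
        form <- as.formula(paste("y ~", fixed, "+",
                                 paste(re, collapse = " + ")))
        n_theta <- 1L + length(keep_cov)
        map <- list(theta = factor(c(NA, seq_len(n_theta - 1L))))
        start <- list(theta = c(log(sqrt(intercept_variance)),
                                rep(log(0.1), n_theta - 1L)))
        mod <- glmmTMB::glmmTMB(form, data = data, family = binomial(),
                                weights = weight, map = map, start = start)
      }
    }
  }
  sm <- summary(mod)$coefficients$cond
  co <- rss_table(sm[, "Estimate"], sm[, "Std. Error"],
                  terms = rownames(sm))
  co$p <- sm[, "Pr(>|z|)"]
  vc <- glmmTMB::VarCorr(mod)$cond
  slope_sd <- if (random_effects == "dyad" && random_slopes) {
    vapply(covariates, function(cv) {
      hit <- vapply(vc, function(m) cv %in% rownames(m), logical(1))
      if (any(hit)) sqrt(vc[[which(hit)[1]]][cv, cv]) else NA_real_
    }, numeric(1))
  } else NULL
  re_modes <- if (random_effects == "dyad") {
    rf <- glmmTMB::ranef(mod)$cond$dyad_id
    tibble::as_tibble(cbind(dyad_id = rownames(rf), rf))
  } else NULL
  structure(list(
    coefficients = co,
    covariates = covariates,
    slope_sd = slope_sd,
    sigma2_intercept = if (random_effects == "dyad") intercept_variance
      else NA_real_,
    ranef = re_modes,
    loglik = as.numeric(logLik(mod)),
    aic = AIC(mod),
    n_dyads = length(unique(data$dyad_id)),
    converged = isTRUE(mod$sdr$pdHess),
    model = mod), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("<rsf_fit>", x$n_dyads, "dyads | AIC =", round(x$aic, 1), "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' A self-contained Newton/IRLS fitter for the no-random-effect weighted
#' logistic model, used as an independent cross-check on the mixed fit.
#'
#' @param X Model matrix (including the intercept column).
#' @param y 0/1 response.
#' @param weights Positive case weights.
#' @param tol Convergence tolerance on the coefficient step.
#' @param max_iter Iteration cap.
#' @return List with `beta`, `se`, `loglik`.
#' @export
rsf_irls <- function(X, y, weights, tol = 1e-12, max_iter = 100) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- weights * p * (1 - p)
    score <- crossprod(X, weights * (y - p))
    H <- crossprod(X, W * X)
    step <- solve(H, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  H <- crossprod(X, (weights * p * (1 - p)) * X)
  list(beta = beta, se = sqrt(diag(solve(H))),
       loglik = sum(weights * (y * log(p) + (1 - y) * log1p(-p))))
}

#' Select a covariate set by AIC
#'
#' Fits every candidate set and returns the minimum-AIC fit; exact ties go
#' to the smaller covariate set (most parsimonious).
#'
#' @param data Used-available tibble.
#' @param candidate_sets List of covariate-name vectors.
#' @param ... Passed to [fit_rsf].
#' @return The winning `rsf_fit`, with the AIC ladder in `$aic_ladder`.
#' @export
select_model <- function(data, candidate_sets, ...) {
  stopifnot(length(candidate_sets) >= 1)
  fits <- list(); errs <- character()
  for (i in seq_along(candidate_sets)) {
    f <- tryCatch(fit_rsf(data, candidate_sets[[i]], ...),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "rsf_fit")) fits[[length(fits) + 1L]] <- f
    else errs <- c(errs, f)
  }
  if (!length(fits))
    stop("all candidate fits failed: ", paste(unique(errs), collapse = "; "))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  sizes <- vapply(fits, function(f) length(f$covariates), numeric(1))
  best <- order(round(aics, 6), sizes)[1]
  out <- fits[[best]]
  out$aic_ladder <- tibble::tibble(
    covariates = vapply(fits, function(f)
      paste(f$covariates, collapse = "+"), character(1)),
    k = sizes, aic = aics)[order(aics), ]
  out
}

#' Relative selection strength table
#'
#' RSS = exp(beta) with Wald 95% CI exp(beta +/- 1.96 SE), plus the
#' one-SD-closer multiplier exp(-beta) (for distance covariates, the
#' multiplicative change in relative contact probability one standard
#' deviation closer to the feature).
#'
#' @param beta Coefficients (log scale).
#' @param se Standard errors.
#' @param terms Optional term names.
#' @return Tibble `term`, `beta`, `se`, `rss`, `rss_lower`, `rss_upper`,
#'   `one_sd_closer`.
#' @export
rss_table <- function(beta, se, terms = names(beta)) {
  tibble::tibble(
    term = if (is.null(terms)) paste0("b", seq_along(beta)) else terms,
    beta = as.numeric(beta), se = as.numeric(se),
    rss = exp(beta), rss_lower = exp(beta - 1.96 * se),
    rss_upper = exp(beta + 1.96 * se),
    one_sd_closer = exp(-beta))
}

#' RSS report for a fitted contact RSF
#'
#' @param fit An `rsf_fit`.
#' @return List with `population` (the RSS table, intercept excluded) and
#'   `dyad` (exponentiated dyad-level slopes, when random slopes were
#'   fitted).
#' @export
rss_report <- function(fit) {
  pop <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  dyad <- NULL
  if (!is.null(fit$ranef)) {
    cols <- intersect(fit$covariates, names(fit$ranef))
    if (length(cols)) {
      dyad <- fit$ranef[c("dyad_id", cols)]
      for (cv in cols) {
        b <- pop$beta[match(cv, pop$term)]
        dyad[[cv]] <- exp(b + dyad[[cv]])
      }
    }
  }
  list(population = pop, dyad = dyad)
}

#' Observed-versus-predicted calibration of the RSF
#'
#' Rows are ranked into `n_bins` equal-count bins of the fitted selection
#' score; within each bin the observed share of used points is regressed on
#' the share expected from the availability-weighted selection weights
#' (`exp(score)` over available rows). A well-calibrated model gives slope
#' ~1 and high R-squared.
#'
#' @param fit An `rsf_fit`.
#' @param data The table the model was fitted to.
#' @param n_bins Number of score bins (>= 2).
#' @return List with `slope`, `intercept`, `r_squared`, and the per-bin
#'   table.
#' @export
validate_calibration <- function(fit, data, n_bins = 10) {
  if (n_bins < 2) stop("need at least two bins")
  beta <- fit$coefficients$beta
  names(beta) <- fit$coefficients$term
  X <- as.matrix(data[fit$covariates])
  score <- drop(X %*% beta[fit$covariates])
  br <- quantile(score, probs = seq(0, 1, length.out = n_bins + 1))
  br <- unique(br)
  if (length(br) - 1 < n_bins)
    warning("tied scores reduced the bin count to ", length(br) - 1)
  bin <- cut(score, br, include.lowest = TRUE)
  w <- exp(score)
  avail <- data$y == 0
  expected <- tapply(w * avail, bin, sum) / sum(w[avail])
  observed <- tapply(data$y == 1, bin, sum) / sum(data$y == 1)
  expected[is.na(expected)] <- 0
  observed[is.na(observed)] <- 0
  fitlm <- lm(observed ~ expected)
  list(slope = unname(coef(fitlm)[2]), intercept = unname(coef(fitlm)[1]),
       r_squared = summary(fitlm)$r.squared,
       bins = tibble::tibble(bin = names(expected),
                             expected = as.numeric(expected),
                             observed = as.numeric(observed)))
}
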