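# Simultaneous identification of (alpha0, Ea, beta) across temperatures.
#
# Internal parameterization: theta = (log10 alpha0, Ea, log beta).
# alpha0 spans ~1e-10 .. 1e-1 across realistic conditions, so a log scale is
# required for conditioning; Ea stays on its natural J/mol scale.

#' Fitting configuration
#'
#' @param init Optional named starting values, a list or vector with elements
#'   \code{alpha0}, \code{Ea}, \code{beta} (natural scale). When omitted,
#'   starts are derived from per-temperature linearized Weibull fits followed
#'   by an Arrhenius regression, with a multistart grid as fallback.
#' @param lower,upper Bounds on the natural scale, named as \code{init}.
#'   Defaults: \code{alpha0} in [1e-14, 1e2] s, \code{Ea} in [0, 2e5] J/mol,
#'   \code{beta} in [1e-3, 3].
#' @param max_iterations Maximum Levenberg-Marquardt iterations per start.
#' @param tolerance Relative tolerance on the residual-sum-of-squares change
#'   (and on parameter change) for convergence.
#' @param multistart_grid Points per axis of the fallback start grid.
#' @param aggregate \code{"mean"} fits per-time replicate means (default);
#'   \code{"pool"} fits all replicate observations individually.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(init = NULL,
                       lower = c(alpha0 = 1e-14, Ea = 0, beta = 1e-3),
                       upper = c(alpha0 = 1e2, Ea = 2e5, beta = 3),
                       max_iterations = 500L,
                       tolerance = 1e-10,
                       multistart_grid = 5L,
                       aggregate = c("mean", "pool")) {
  aggregate <- match.arg(aggregate)
  lower <- lower[c("alpha0", "Ea", "beta")]
  upper <- upper[c("alpha0", "Ea", "beta")]
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper),
            lower[["alpha0"]] > 0, lower[["beta"]] > 0, lower[["Ea"]] >= 0)
  if (!is.null(init)) {
    init <- unlist(init)[c("alpha0", "Ea", "beta")]
    if (any(init < lower) || any(init > upper))
      stop("`init` must lie within the bounds", call. = FALSE)
  }
  structure(list(init = init, lower = lower, upper = upper,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 multistart_grid = as.integer(multistart_grid),
                 aggregate = aggregate),
            class = "fit_config")
}

# theta (internal) <-> natural scale
theta_to_params <- function(theta) {
  weibull_arrhenius_params(alpha0 = 10^theta[[1L]], Ea = theta[[2L]],
                           beta = exp(theta[[3L]]))
}
params_to_theta <- function(alpha0, Ea, beta) {
  c(la0 = log10(alpha0), Ea = Ea, lb = log(beta))
}

# Residual vector Y_obs - Y_pred on the pooled observation table.
# Direct log-space evaluation (no validated constructors): the optimizer's
# finite-difference steps may transiently cross the Ea >= 0 bound.
wa_residuals <- function(theta, obs) {
  log_alpha <- theta[[1L]] * log(10) +
    theta[[2L]] / (GAS_CONSTANT * (obs$temperature_C + 273.15))
  beta <- exp(theta[[3L]])
  u <- ifelse(obs$time == 0, -Inf, beta * (log(obs$time) - log_alpha))
  obs$yield - obs$y_eq * (1 - exp(-exp(u)))
}

# Levenberg-Marquardt wrapper with box bounds on the internal scale.
# Returns the nls.lm fit plus RSS; shared by the Weibull fitter and tests.
marquardt_fit <- function(resid_fn, start, lower, upper,
                          max_iterations = 500L, tolerance = 1e-10, ...) {
  ctrl <- minpack.lm::nls.lm.control(ftol = tolerance, ptol = tolerance,
                                     gtol = 0, maxiter = min(max_iterations, 1024L))
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl, ...)
  fit$rss <- sum(fit$fvec^2)
  fit
}

# Per-temperature linearized starts: for each curve regress
# log(-log(1 - Y/Yeq)) on log t (slope beta, intercept -beta log alpha),
# then Arrhenius regression of log alpha on 1/T.
linearized_start <- function(obs) {
  per_T <- split(obs, obs$temperature_C)
  la <- bt <- TK <- numeric(0)
  for (d in per_T) {
    frac <- d$yield / d$y_eq
    keep <- d$time > 0 & frac > 0 & frac < 0.9999
    if (sum(keep) < 2L) next
    z <- -log(1 - frac[keep])
    fit <- stats::lm(log(z) ~ log(d$time[keep]))
    b <- stats::coef(fit)[[2L]]
    if (!is.finite(b) || b <= 0) next
    la <- c(la, -stats::coef(fit)[[1L]] / b)
    bt <- c(bt, b)
    TK <- c(TK, d$temperature_C[1L] + 273.15)
  }
  if (length(la) < 2L) return(NULL)
  arr <- stats::lm(la ~ I(1 / TK))
  Ea <- stats::coef(arr)[[2L]] * GAS_CONSTANT
  alpha0 <- exp(stats::coef(arr)[[1L]])
  beta <- mean(bt)
  if (!all(is.finite(c(alpha0, Ea, beta))) || alpha0 <= 0 || beta <= 0)
    return(NULL)
  c(alpha0 = alpha0, Ea = max(Ea, 0), beta = beta)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit the Weibull-Arrhenius model to a multi-temperature dataset
#'
#' Identifies the shared parameters (alpha0, Ea, beta) by unweighted
#' nonlinear least squares over all curves and sampling times simultaneously.
#' Each curve's equilibrium yield is held fixed at its supplied value (it is
#' an observed quantity, not a fitted one). Optimization runs on the internal
#' scale (log10 alpha0, Ea, log beta) with box bounds, starting from
#' linearized per-temperature Weibull fits and falling back to a multistart
#' grid when the data-driven start fails or does not converge.
#'
#' @param dataset A \code{\link{kinetics_dataset}} with curves at >= 2
#'   distinct temperatures and >= 4 observations in total.
#' @param config A \code{\link{fit_config}}.
#' @return An object of class \code{weibull_fit} with elements
#'   \code{params} (natural-scale point estimates,
#'   \code{\link{weibull_arrhenius_params}}), \code{theta} (internal-scale
#'   estimates), \code{covariance} (3x3, internal scale),
#'   \code{standard_errors} (natural scale, delta method), \code{ci95}
#'   (natural scale), \code{rss}, \code{n_obs}, \code{dof}, \code{sigma2},
#'   \code{converged}, \code{n_iterations}, and the fitted observation table
#'   \code{observations} (with a \code{fitted} column).
#' @examples
#' des <- synthetic_design(true_params = weibull_arrhenius_params(5e-7, 43000, 0.53),
#'                         equilibrium_yield = 74.7, noise_sd = 0)
#' fit <- fit_weibull_arrhenius(generate_extraction_dataset(des))
#' fit$params
#' @export
fit_weibull_arrhenius <- function(dataset, config = fit_config()) {
  stopifnot(inherits(dataset, "kinetics_dataset"),
            inherits(config, "fit_config"))
  temps <- vapply(dataset$curves, `[[`, numeric(1), "temperature_C")
  if (length(unique(temps)) < 2L)
    stop("simultaneous fitting needs curves at >= 2 temperatures",
         call. = FALSE)
  obs <- dataset_observations(dataset, aggregate = config$aggregate)
  obs <- obs[order(obs$temperature_C, obs$time), , drop = FALSE]
  if (nrow(obs) < 4L)
    stop("need at least 4 observations to identify 3 parameters",
         call. = FALSE)

  lo <- params_to_theta(config$lower[["alpha0"]],
                        max(config$lower[["Ea"]], 0), config$lower[["beta"]])
  hi <- params_to_theta(config$upper[["alpha0"]], config$upper[["Ea"]],
                        config$upper[["beta"]])

  starts <- list()
  if (!is.null(config$init)) {
    starts <- list(params_to_theta(config$init[["alpha0"]],
                                   config$init[["Ea"]],
                                   config$init[["beta"]]))
  } else {
    ls <- linearized_start(obs)
    if (!is.null(ls))
      starts <- list(clamp(params_to_theta(
        clamp(ls[["alpha0"]], config$lower[["alpha0"]], config$upper[["alpha0"]]),
        clamp(ls[["Ea"]], config$lower[["Ea"]], config$upper[["Ea"]]),
        clamp(ls[["beta"]], config$lower[["beta"]], config$upper[["beta"]])),
        lo, hi))
    # The linearized start is noise-sensitive (the Arrhenius regression uses
    # one noisy per-temperature alpha each): always add a coarse interior
    # grid and keep the best-RSS solution.
    fr <- c(0.25, 0.5, 0.75)
    coarse <- expand.grid(la0 = lo[[1L]] + fr * (hi[[1L]] - lo[[1L]]),
                          Ea = lo[[2L]] + fr * (hi[[2L]] - lo[[2L]]),
                          lb = lo[[3L]] + fr * (hi[[3L]] - lo[[3L]]))
    starts <- c(starts, lapply(seq_len(nrow(coarse)), function(i)
      c(la0 = coarse$la0[i], Ea = coarse$Ea[i], lb = coarse$lb[i])))
  }

  run_one <- function(st) {
    tryCatch(marquardt_fit(wa_residuals, st, lo, hi,
                           max_iterations = config$max_iterations,
                           tolerance = config$tolerance, obs = obs),
             error = function(e) NULL)
  }

  best <- NULL
  for (st in starts) {
    f <- run_one(st)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  # Multistart fallback: grid over the internal box
  if (is.null(best) || !(best$info %in% 1:4)) {
    g <- config$multistart_grid
    grid <- expand.grid(la0 = seq(lo[[1L]], hi[[1L]], length.out = g),
                        Ea = seq(lo[[2L]], hi[[2L]], length.out = g),
                        lb = seq(lo[[3L]], hi[[3L]], length.out = g))
    for (i in seq_len(nrow(grid))) {
      f <- run_one(c(la0 = grid$la0[i], Ea = grid$Ea[i], lb = grid$lb[i]))
      if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
    }
  }
  if (is.null(best))
    stop("all optimization starts failed", call. = FALSE)

  theta <- stats::setNames(as.numeric(best$par), c("la0", "Ea", "lb"))
  params <- theta_to_params(theta)
  n_obs <- nrow(obs)
  dof <- n_obs - 3L
  rss <- best$rss
  sigma2 <- rss / dof

  J <- numeric_jacobian(function(th) wa_residuals(th, obs), theta)
  cv <- covariance_from_jacobian(J, sigma2)

  se_int <- sqrt(pmax(diag(cv$cov), 0))
  # delta method to the natural scale:
  # d alpha0/d la0 = alpha0 ln10; d beta/d lb = beta
  grad <- c(params$alpha0 * log(10), 1, params$beta)
  se_nat <- se_int * grad

  ci <- ci_endpoints(theta, se_int, dof, level = 0.95)
  obs$fitted <- obs$yield - best$fvec

  structure(list(
    condition = dataset$condition, response = dataset$response,
    params = params, theta = theta,
    covariance = cv$cov, rank_deficient = cv$rank_deficient,
    standard_errors = stats::setNames(se_nat, c("alpha0", "Ea", "beta")),
    ci95 = ci, rss = rss, sigma2 = sigma2,
    n_obs = n_obs, dof = dof,
    converged = best$info %in% 1:4 && !cv$rank_deficient,
    n_iterations = best$niter,
    observations = obs, config = config),
    class = "weibull_fit")
}

# Central-difference Jacobian of a residual function
numeric_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(abs(theta[[j]]), 1)
    tp <- tm <- theta
    tp[[j]] <- tp[[j]] + h
    tm[[j]] <- tm[[j]] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

# sigma2 * (J'J)^-1 with a pseudo-inverse fallback for rank deficiency
covariance_from_jacobian <- function(J, sigma2) {
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
  rank_deficient <- is.null(cov)
  if (rank_deficient) {
    warning("J'J is singular: rank-deficient fit, intervals unreliable",
            call. = FALSE)
    s <- svd(JtJ)
    pos <- s$d > max(s$d) * 1e-12
    inv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    cov <- sigma2 * inv
  }
  cov <- (cov + t(cov)) / 2
  list(cov = cov, rank_deficient = rank_deficient)
}

# t-interval on the internal scale, endpoints mapped monotonically to the
# natural scale (10^ for log10 alpha0, exp for log beta) so that coverage is
# preserved under the reparameterization.
ci_endpoints <- function(theta, se_int, dof, level) {
  tq <- stats::qt(1 - (1 - level) / 2, df = dof)
  lo <- theta - tq * se_int
  hi <- theta + tq * se_int
  data.frame(
    parameter = c("alpha0", "Ea", "beta"),
    estimate = c(10^theta[[1L]], theta[[2L]], exp(theta[[3L]])),
    low = c(10^lo[[1L]], lo[[2L]], exp(lo[[3L]])),
    high = c(10^hi[[1L]], hi[[2L]], exp(hi[[3L]])),
    row.names = NULL)
}

#' Confidence intervals for fitted Weibull-Arrhenius parameters
#'
#' t-based intervals \code{estimate +/- qt((1+level)/2, dof) * SE} computed on
#' the internal optimization scale and mapped back to the natural parameter
#' scale by the monotone reparameterization, giving asymmetric intervals for
#' \code{alpha0} and \code{beta}. With zero residuals the intervals collapse
#' to the estimates.
#'
#' @param fit A \code{weibull_fit} from \code{\link{fit_weibull_arrhenius}}.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A data frame with columns \code{parameter}, \code{estimate},
#'   \code{low}, \code{high}.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "weibull_fit"), level > 0, level < 1)
  se_int <- sqrt(pmax(diag(fit$covariance), 0))
  ci_endpoints(fit$theta, se_int, fit$dof, level)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull-Arrhenius fit: %s / %s (%d obs, dof %d)\n",
              x$condition, x$response, x$n_obs, x$dof))
  ci <- x$ci95
  for (i in seq_len(nrow(ci)))
    cat(sprintf("  %-7s %.5g  [%.5g, %.5g]  SE %.3g\n", ci$parameter[i],
                ci$estimate[i], ci$low[i], ci$high[i], x$standard_errors[i]))
  cat(sprintf("  RSS %.6g, converged: %s (%d iterations)\n",
              x$rss, x$converged, x$n_iterations))
  invisible(x)
}
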