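# Simultaneous multi-temperature least squares: round trips, oracles,
# invariances of the optimizer and of the interval machinery.

test_that("noiseless synthetic data are recovered to high precision", {
  des <- synthetic_design(weibull_arrhenius_params(5e-7, 43000, 0.53),
                          equilibrium_yield = 74.7, noise_sd = 0,
                          replicates = 1L)
  fit <- fit_weibull_arrhenius(generate_extraction_dataset(des))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha0 / 5e-7 - 1), 1e-4)
  expect_lt(abs(fit$params$Ea / 43000 - 1), 1e-4)
  expect_lt(abs(fit$params$beta / 0.53 - 1), 1e-4)
  expect_lt(fit$rss, 1e-8)
  # zero residuals: intervals collapse onto the estimates
  ci <- confidence_intervals(fit, 0.95)
  expect_equal(ci$low, ci$estimate, tolerance = 1e-6)
  expect_equal(ci$high, ci$estimate, tolerance = 1e-6)
})

test_that("first-order data with Ea suppressed give beta = 1", {
  times <- c(60, 120, 180, 240, 300, 360, 480, 600, 1800)
  alpha <- 120
  curves <- lapply(c(5, 15, 25), function(Tc)
    extraction_curve("CE", Tc, "TPC", times,
                     74.7 * (1 - exp(-times / alpha)),
                     equilibrium_yield = 74.7))
  ds <- kinetics_dataset(curves)
  cfg <- fit_config(upper = c(alpha0 = 1e4, Ea = 1e-3, beta = 3))
  fit <- fit_weibull_arrhenius(ds, cfg)
  expect_equal(fit$params$beta, 1, tolerance = 1e-4)
  expect_equal(fit$params$alpha0 *
                 exp(fit$params$Ea / (8.314 * 288.15)), alpha,
               tolerance = 1e-3)
})

test_that("interval machinery matches the linear-regression closed form", {
  # a straight-line pseudo-model through the same LM + J'J machinery
  x <- c(1, 2, 3, 5, 8)
  y <- c(2.1, 3.9, 6.2, 9.8, 16.1)
  resid_fn <- function(p) y - (p[1] + p[2] * x)
  f <- uaekin:::marquardt_fit(resid_fn, c(0, 1), c(-Inf, -Inf), c(Inf, Inf),
                              tolerance = 1e-14)
  est <- as.numeric(f$par)
  dof <- length(y) - 2L
  J <- uaekin:::numeric_jacobian(resid_fn, est)
  cv <- uaekin:::covariance_from_jacobian(J, f$rss / dof)
  se <- sqrt(diag(cv$cov))
  tq <- qt(0.975, dof)
  lmfit <- lm(y ~ x)
  expect_equal(est, unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(se, unname(summary(lmfit)$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(cbind(est - tq * se, est + tq * se),
               unname(confint(lmfit)), tolerance = 1e-8)
})

test_that("interval width grows monotonically with the confidence level", {
  des <- synthetic_design(weibull_arrhenius_params(5e-7, 43000, 0.53),
                          74.7, noise_sd = 2, seed = 11)
  fit <- fit_weibull_arrhenius(generate_extraction_dataset(des))
  widths <- sapply(c(0.80, 0.90, 0.95, 0.99), function(lv) {
    ci <- confidence_intervals(fit, lv)
    ci$high - ci$low
  })
  expect_true(all(diff(t(widths))[, 1] > 0))
  expect_true(all(diff(t(widths))[, 2] > 0))
  expect_true(all(diff(t(widths))[, 3] > 0))
  # ci95 brackets the estimates
  expect_true(all(fit$ci95$low <= fit$ci95$estimate + 1e-12))
  expect_true(all(fit$ci95$estimate <= fit$ci95$high + 1e-12))
})

test_that("fit is invariant to curve order and time-point order", {
  des <- synthetic_design(weibull_arrhenius_params(5e-7, 43000, 0.53),
                          74.7, noise_sd = 2, replicates = 1L, seed = 5)
  ds <- generate_extraction_dataset(des)
  base <- fit_weibull_arrhenius(ds)
  # reverse curve order; present each curve's time points in shuffled order
  # (one observation per replicate index keeps the container contract)
  set.seed(99)
  shuffled <- lapply(rev(ds$curves), function(k) {
    o <- sample(length(k$times))
    extraction_curve(k$condition, k$temperature_C, k$response,
                     k$times[o], k$yields[o],
                     equilibrium_yield = k$equilibrium_yield,
                     replicate = seq_along(o))
  })
  alt <- fit_weibull_arrhenius(kinetics_dataset(shuffled))
  expect_lt(abs(alt$params$alpha0 / base$params$alpha0 - 1), 1e-6)
  expect_lt(abs(alt$params$Ea / base$params$Ea - 1), 1e-6)
  expect_lt(abs(alt$params$beta / base$params$beta - 1), 1e-6)
})

test_that("covariance is symmetric PSD and dof bookkeeping is right", {
  des <- synthetic_design(weibull_arrhenius_params(5e-7, 43000, 0.53),
                          74.7, noise_sd = 2, seed = 3)
  fit <- fit_weibull_arrhenius(generate_extraction_dataset(des))
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-12)
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_identical(fit$n_obs, 27L)  # replicate means: 3 temps x 9 times
  expect_identical(fit$dof, 24L)
  # pooled fitting keeps every replicate observation
  fit_pool <- fit_weibull_arrhenius(generate_extraction_dataset(des),
                                    fit_config(aggregate = "pool"))
  expect_identical(fit_pool$n_obs, 81L)
})

test_that("underdetermined or single-temperature input is rejected", {
  k5 <- extraction_curve("CE", 5, "TPC", c(60, 1800), c(10, 67))
  expect_error(fit_weibull_arrhenius(kinetics_dataset(list(k5))),
               ">= 2 temperatures")
  k15 <- extraction_curve("CE", 15, "TPC", 1800, 67)
  expect_error(fit_weibull_arrhenius(kinetics_dataset(list(
    extraction_curve("CE", 5, "TPC", 1800, 60), k15))),
    "at least 4 observations")
})
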