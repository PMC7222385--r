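# Forward Weibull-Arrhenius model: closed forms, limits, monotonicity.

test_that("alpha_at_temperature reproduces reported characteristic times", {
  # UAE2/TPC at 5 degC: ~37 s
  p <- weibull_arrhenius_params(1.69e-3, 23103.4, 0.618)
  expect_lt(abs(alpha_at_temperature(p, 278.15) / 37 - 1), 0.05)
  # CE/TPC at 25 degC: ~45 s (cross-checked by high-precision exponentiation)
  p2 <- weibull_arrhenius_params(4.09e-10, 62948.8, 0.609)
  a25 <- alpha_at_temperature(p2, 298.15)
  expect_lt(abs(a25 / 45 - 1), 0.05)
  expect_equal(a25, 43.70081930150038, tolerance = 1e-12)
})

test_that("alpha(T) has the Arrhenius limits and monotonicity", {
  # Ea = 0: exponent vanishes, alpha == alpha0 at any temperature
  p0 <- weibull_arrhenius_params(0.37, 0, 1)
  expect_identical(alpha_at_temperature(p0, c(200, 298.15, 400)),
                   rep(0.37, 3))
  # Ea > 0: strictly decreasing in T
  p <- weibull_arrhenius_params(5e-7, 43000, 0.5)
  a <- alpha_at_temperature(p, seq(270, 320, by = 1))
  expect_true(all(diff(a) < 0))
  # log-space evaluation survives extreme Ea/(RT) without overflow
  pbig <- weibull_arrhenius_params(1e-14, 2e5, 0.5)
  expect_true(is.finite(alpha_at_temperature(pbig, 100)))
  expect_error(alpha_at_temperature(p, 0), "positive")
  expect_error(alpha_at_temperature(p, -10), "positive")
})

test_that("weibull_yield matches its closed forms and limits", {
  # t = 0 -> 0 (initial extract concentration is zero)
  expect_identical(weibull_yield(0, 37, 0.618, 83), 0)
  # beta = 1, t = alpha: first-order kinetics, Y = Yeq (1 - e^-1)
  expect_equal(weibull_yield(37, 37, 1, 100), 100 * (1 - exp(-1)),
               tolerance = 1e-14)
  # frozen value from an independent 50-digit evaluation of the model
  expect_equal(weibull_yield(600, 37, 0.618, 83.0), 82.691335004279,
               tolerance = 1e-10)
  expect_error(weibull_yield(-1, 37, 0.618, 83), "non-negative")
  expect_error(weibull_yield(10, -1, 0.618, 83), "positive")
})

test_that("beta = 1 reduces the model to first-order kinetics exactly", {
  t <- c(0, 30, 60, 300, 1800)
  expect_equal(weibull_yield(t, 45, 1, 74.7), 74.7 * (1 - exp(-t / 45)),
               tolerance = 1e-15)
})

test_that("yield curves are bounded by Yeq and non-decreasing in time", {
  set.seed(7)
  tgrid <- c(0, sort(runif(40, 0, 3600)))
  for (i in 1:25) {
    alpha <- 10^runif(1, -1, 3)
    beta <- runif(1, 0.05, 2.5)
    yeq <- runif(1, 20, 100)
    y <- weibull_yield(tgrid, alpha, beta, yeq)
    # strictly below yeq mathematically; equality only by float underflow
    expect_true(all(y >= 0 & y <= yeq))
    expect_true(all(diff(y) >= 0))
  }
})

test_that("predict_curve composes scale and shape, warmer is faster", {
  p <- weibull_arrhenius_params(5e-7, 43000, 0.53)
  expect_identical(predict_curve(p, 74.7, 0, 15), 0)
  times <- c(30, 60, 120, 300, 600, 1800)
  y5 <- predict_curve(p, 74.7, times, 5)
  y25 <- predict_curve(p, 74.7, times, 25)
  expect_true(all(y25 > y5))
  # elementwise equal to the explicit composition
  a15 <- alpha_at_temperature(p, celsius_to_kelvin(15))
  expect_equal(predict_curve(p, 74.7, times, 15),
               weibull_yield(times, a15, 0.53, 74.7), tolerance = 1e-15)
  # asymptote equals the equilibrium yield
  pce <- reference_params_for("CE", "TPC")
  expect_equal(predict_curve(pce, 67.3, 3600e6, 25), 67.3, tolerance = 1e-6)
})

test_that("parameter and container validation catches bad inputs", {
  expect_error(weibull_arrhenius_params(-1, 1000, 0.5), "alpha0")
  expect_error(weibull_arrhenius_params(1, -5, 0.5), "Ea")
  expect_error(weibull_arrhenius_params(1, 1000, 0), "beta")
  expect_error(extraction_curve("CE", 5, "TPC", c(60, 60), c(10, 20)),
               "strictly increasing")
  c1 <- extraction_curve("CE", 5, "TPC", c(60, 1800), c(10, 67))
  c2 <- extraction_curve("CE", 15, "TFC", c(60, 1800), c(12, 70))
  expect_error(kinetics_dataset(list(c1, c2)), "share")
  c3 <- extraction_curve("CE", 5, "TPC", c(60, 1800), c(12, 70))
  expect_error(kinetics_dataset(list(c1, c3)), "distinct")
})

test_that("default equilibrium yield is the mean terminal observation", {
  k <- extraction_curve("CE", 5, "TPC", times = rep(c(60, 1800), 3),
                        yields = c(10, 82, 11, 83, 12, 84),
                        replicate = rep(1:3, each = 2))
  expect_equal(k$equilibrium_yield, 83)
})
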