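# Synthetic-data generator: determinism, noise calibration, fixtures.

test_that("noiseless generation equals the forward model exactly", {
  tp <- weibull_arrhenius_params(5e-7, 43000, 0.53)
  des <- synthetic_design(tp, 74.7, noise_sd = 0, replicates = 1L)
  ds <- generate_extraction_dataset(des)
  for (k in ds$curves)
    expect_identical(k$yields,
                     predict_curve(tp, k$equilibrium_yield, k$times,
                                   k$temperature_C))
  expect_identical(attr(ds, "n_truncated"), 0L)
})

test_that("generation is deterministic given the seed", {
  tp <- weibull_arrhenius_params(5e-7, 43000, 0.53)
  d1 <- generate_extraction_dataset(synthetic_design(tp, 74.7, seed = 12))
  d2 <- generate_extraction_dataset(synthetic_design(tp, 74.7, seed = 12))
  d3 <- generate_extraction_dataset(synthetic_design(tp, 74.7, seed = 13))
  expect_identical(d1$curves[[1]]$yields, d2$curves[[1]]$yields)
  expect_false(identical(d1$curves[[1]]$yields, d3$curves[[1]]$yields))
})

test_that("noise is calibrated: empirical sd near noise_sd, few truncations", {
  tp <- weibull_arrhenius_params(5e-7, 43000, 0.53)
  # ~10^4 draws across the design
  des <- synthetic_design(tp, 74.7, noise_sd = 2, replicates = 556L,
                          temperatures = c(15, 25),
                          sample_times = c(300, 600, 1800), seed = 4)
  ds <- generate_extraction_dataset(des)
  resid <- unlist(lapply(ds$curves, function(k) {
    mu <- predict_curve(tp, k$equilibrium_yield,
                        sort(unique(k$times)), k$temperature_C)
    k$yields - mu[match(k$times, sort(unique(k$times)))]
  }))
  expect_gt(length(resid), 3000)
  expect_lt(abs(sd(resid) / 2 - 1), 0.03)
  # far from zero yield, truncation is rare
  expect_lt(attr(ds, "n_truncated") / length(resid), 0.01)
})

test_that("calorimetry traces invert the power balance", {
  tr <- generate_calorimetry_trace(104, mass = 0.2, cp = 4186,
                                   duration = 300, noise_sd = 0)
  slopes <- diff(tr$temperatures)
  expect_equal(unique(round(slopes, 12)), 0.124223602484472,
               tolerance = 1e-10)
  expect_equal(estimate_power(tr, mass = 0.2, cp = 4186)$power, 104,
               tolerance = 1e-8)
  flat <- generate_calorimetry_trace(0, mass = 0.2, cp = 4186, noise_sd = 0)
  expect_equal(diff(range(flat$temperatures)), 0)
})

test_that("all nine reference fixtures exist, validate, and refit", {
  tab <- reference_params()
  for (i in seq_len(nrow(tab))) {
    ds <- reference_dataset(tab$condition[i], tab$response[i])
    expect_s3_class(ds, "kinetics_dataset")
    expect_length(ds$curves, 3L)
    expect_true(all(vapply(ds$curves, function(k) length(k$times),
                           integer(1)) == 9L))
  }
  expect_error(reference_dataset("XX", "TPC"), "unknown")
  # UAE2/TPC round trip: the fitter recovers the generating parameters
  fit <- fit_weibull_arrhenius(reference_dataset("UAE2", "TPC"))
  expect_lt(abs(fit$params$alpha0 / 1.69e-3 - 1), 0.01)
  expect_lt(abs(fit$params$Ea / 23103.4 - 1), 0.01)
  expect_lt(abs(fit$params$beta / 0.618 - 1), 0.01)
})

test_that("CE/AA fixture asymptote equals its equilibrium line at 25 degC", {
  ds <- reference_dataset("CE", "AA")
  k25 <- ds$curves[[which(vapply(ds$curves, `[[`, numeric(1),
                                 "temperature_C") == 25)]]
  expect_equal(k25$equilibrium_yield, 0.063 * 25 + 36.17, tolerance = 1e-12)
  p <- reference_params_for("CE", "AA")
  expect_equal(predict_curve(p, k25$equilibrium_yield, 3600e6, 25),
               k25$equilibrium_yield, tolerance = 1e-9)
})

test_that("generate -> fit -> evaluate MRE vanishes as noise vanishes", {
  tp <- weibull_arrhenius_params(5e-7, 43000, 0.53)
  mres <- sapply(c(2, 0.5, 0), function(s) {
    des <- synthetic_design(tp, 74.7, noise_sd = s, seed = 6)
    fit_mre(fit_weibull_arrhenius(generate_extraction_dataset(des)))
  })
  expect_true(all(diff(mres) < 0))
  expect_lt(mres[3], 1e-6)
})
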