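# Synthetic extraction datasets and calorimetry traces with the statistical
# structure the analysis assumes, plus bundled reference parameter sets for
# aqueous extraction of antioxidant compounds from orange byproduct.

#' Design of a synthetic extraction experiment
#'
#' Describes the ground truth and sampling layout used by
#' \code{\link{generate_extraction_dataset}}: true kinetic parameters, the
#' equilibrium-yield model, the temperature set, the sampling times
#' (default 1, 2, 3, 4, 5, 6, 8, 10 and 30 min), the number of replicates
#' and an additive Gaussian noise level on the yield scale.
#'
#' @param true_params A \code{\link{weibull_arrhenius_params}} object.
#' @param equilibrium_yield Either a single percent value (temperature-
#'   independent equilibrium), a numeric vector with one value per
#'   temperature, or an \code{\link{fit_equilibrium_line}} object evaluated
#'   at each temperature.
#' @param temperatures Extraction temperatures, degrees Celsius.
#' @param sample_times Sampling times, seconds.
#' @param replicates Replicate curves per temperature.
#' @param noise_sd Standard deviation of additive Gaussian noise,
#'   yield-percent points. Default 2, a realistic replicate scatter for
#'   spectrophotometric yield assays.
#' @param condition,response Labels for the generated curves.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(true_params,
                             equilibrium_yield,
                             temperatures = c(5, 15, 25),
                             sample_times = c(60, 120, 180, 240, 300,
                                              360, 480, 600, 1800),
                             replicates = 3L,
                             noise_sd = 2,
                             condition = "SYN", response = "SYN",
                             seed = 1L) {
  stopifnot(inherits(true_params, "weibull_arrhenius_params"),
            is.numeric(temperatures), length(temperatures) >= 2L,
            is.numeric(sample_times), all(sample_times >= 0),
            replicates >= 1L, noise_sd >= 0)
  if (inherits(equilibrium_yield, "equilibrium_line")) {
    y_eq <- predict_equilibrium(equilibrium_yield, temperatures)
  } else if (length(equilibrium_yield) == 1L) {
    y_eq <- rep(equilibrium_yield, length(temperatures))
  } else {
    stopifnot(length(equilibrium_yield) == length(temperatures))
    y_eq <- equilibrium_yield
  }
  if (any(y_eq <= 0)) stop("equilibrium yields must be positive", call. = FALSE)
  structure(list(true_params = true_params, temperatures = temperatures,
                 y_eq = y_eq, sample_times = sort(sample_times),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 condition = condition, response = response,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic multi-temperature extraction dataset
#'
#' Evaluates the Weibull-Arrhenius mean curve (the same code path as
#' \code{\link{predict_curve}}) at every design point, adds i.i.d. Gaussian
#' noise on the yield scale, truncates at 0 (negative yields are not
#' physical; truncations are counted in the \code{n_truncated} attribute),
#' and stores the ground truth alongside.
#'
#' @param design A \code{\link{synthetic_design}}.
#' @return A \code{\link{kinetics_dataset}} whose curves carry the design
#'   (true) equilibrium yields; attributes \code{true_params} and
#'   \code{design} hold the ground truth, \code{n_truncated} the number of
#'   zero-truncated observations.
#' @export
generate_extraction_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n_trunc <- 0L
  curves <- vector("list", length(design$temperatures))
  for (i in seq_along(design$temperatures)) {
    Tc <- design$temperatures[i]
    mu <- predict_curve(design$true_params, design$y_eq[i],
                        design$sample_times, Tc)
    nt <- length(design$sample_times)
    times <- rep(design$sample_times, design$replicates)
    repl <- rep(seq_len(design$replicates), each = nt)
    y <- rep(mu, design$replicates) +
      stats::rnorm(nt * design$replicates, 0, design$noise_sd)
    n_trunc <- n_trunc + sum(y < 0)
    y <- pmax(y, 0)
    curves[[i]] <- extraction_curve(
      condition = design$condition, temperature_C = Tc,
      response = design$response, times = times, yields = y,
      equilibrium_yield = design$y_eq[i],
      replicate = if (design$replicates > 1L) repl else NULL)
  }
  out <- kinetics_dataset(curves)
  attr(out, "true_params") <- design$true_params
  attr(out, "design") <- design
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Generate a synthetic calorimetry trace
#'
#' Inverts the calorimetric power balance: a linear temperature ramp with
#' slope \eqn{P / (m C_p)} sampled at 1 Hz, plus Gaussian sensor noise.
#'
#' @param power Dissipated ultrasonic power, W.
#' @param mass Solvent mass, kg.
#' @param cp Specific heat, J/(kg degC).
#' @param duration Trace duration, seconds (sampled at 0, 1, ..., duration).
#' @param noise_sd Sensor noise sd, K.
#' @param seed Integer seed.
#' @param t_start Initial solvent temperature, degrees Celsius.
#' @return A \code{\link{calorimetry_trace}}.
#' @export
generate_calorimetry_trace <- function(power, mass, cp, duration = 300,
                                       noise_sd = 0, seed = 1L,
                                       t_start = 20) {
  stopifnot(power >= 0, mass > 0, cp > 0, duration >= 2, noise_sd >= 0)
  set.seed(seed)
  times <- seq(0, duration, by = 1)
  temps <- t_start + (power / (mass * cp)) * times +
    stats::rnorm(length(times), 0, noise_sd)
  calorimetry_trace(times, temps, probe_id = "synthetic")
}

#' Reference Weibull-Arrhenius parameter sets
#'
#' Bundled identified parameters for the aqueous extraction of total
#' phenolics (TPC), total flavonoids (TFC) and antioxidant activity (AA,
#' ABTS assay) from orange byproduct under mechanical agitation (CE, 80 rpm)
#' and ultrasound assistance at 520 W/L (UAE1) and 790 W/L (UAE2), within
#' 5-25 degC. These serve as ground truth for fixture datasets and
#' parameter-recovery studies.
#'
#' @return Data frame with columns \code{condition}, \code{response},
#'   \code{alpha0} (s), \code{Ea} (J/mol), \code{beta}.
#' @export
reference_params <- function() {
  data.frame(
    condition = rep(c("CE", "UAE1", "UAE2"), times = 3),
    response = rep(c("TPC", "TFC", "AA"), each = 3),
    alpha0 = c(4.09e-10, 5.09e-7, 1.69e-3,
               1.83e-7, 5.76e-2, 5.77e-2,
               5.31e-11, 1.28e-7, 5.01e-7),
    Ea = c(62948.8, 43058.2, 23103.4,
           48065.9, 15518.9, 15518.8,
           66300.2, 46010.7, 41050.3),
    beta = c(0.609, 0.529, 0.618,
             0.460, 0.025, 0.009,
             0.371, 0.501, 0.502),
    stringsAsFactors = FALSE)
}

#' Reference equilibrium-yield models
#'
#' Equilibrium yields (percent) per condition and response within 5-25 degC.
#' TPC equilibrium yields show no temperature dependence and are constants;
#' TFC and AA follow linear temperature regressions \eqn{Y_{eq} = a T + b}.
#'
#' @param condition \code{"CE"}, \code{"UAE1"} or \code{"UAE2"}.
#' @param response \code{"TPC"}, \code{"TFC"} or \code{"AA"}.
#' @param temperature_C Temperature(s) at which to evaluate, degrees Celsius.
#' @return Equilibrium yield(s), percent.
#' @export
reference_equilibrium <- function(condition, response, temperature_C) {
  key <- paste(condition, response, sep = "/")
  spec <- switch(key,
    "CE/TPC" = c(0, 67.3), "UAE1/TPC" = c(0, 74.7), "UAE2/TPC" = c(0, 83.0),
    "CE/TFC" = c(0.301, 48.74), "UAE1/TFC" = c(1.398, 46.28),
    "UAE2/TFC" = c(0.977, 55.64),
    "CE/AA" = c(0.063, 36.17), "UAE1/AA" = c(0.153, 68.35),
    "UAE2/AA" = c(0.317, 86.92),
    stop("unknown condition/response: ", key, call. = FALSE))
  spec[1L] * temperature_C + spec[2L]
}

#' Reference mean relative errors
#'
#' Bundled MRE values (percent) of the Weibull-Arrhenius simulation of each
#' condition x response extraction experiment, used by the evaluation
#' summaries.
#'
#' @return Data frame with columns \code{condition}, \code{response},
#'   \code{mre}.
#' @export
reference_mre <- function() {
  data.frame(
    condition = rep(c("CE", "UAE1", "UAE2"), times = 3),
    response = rep(c("TPC", "TFC", "AA"), each = 3),
    mre = c(4.6, 3.7, 1.6,
            3.4, 2.6, 2.3,
            5.0, 2.7, 1.8),
    stringsAsFactors = FALSE)
}

#' Noiseless fixture dataset for one reference condition
#'
#' Deterministic 3-temperature x 9-time dataset generated from the
#' \code{\link{reference_params}} ground truth and
#' \code{\link{reference_equilibrium}} yields; refitting it recovers the
#' reference parameters.
#'
#' @param condition \code{"CE"}, \code{"UAE1"} or \code{"UAE2"}.
#' @param response \code{"TPC"}, \code{"TFC"} or \code{"AA"}.
#' @return A \code{\link{kinetics_dataset}} (noiseless, single replicate).
#' @export
reference_dataset <- function(condition, response) {
  tab <- reference_params()
  row <- tab[tab$condition == condition & tab$response == response, ]
  if (nrow(row) != 1L)
    stop("unknown condition/response: ", condition, "/", response,
         call. = FALSE)
  temps <- c(5, 15, 25)
  des <- synthetic_design(
    true_params = weibull_arrhenius_params(row$alpha0, row$Ea, row$beta),
    equilibrium_yield = reference_equilibrium(condition, response, temps),
    temperatures = temps, replicates = 1L, noise_sd = 0,
    condition = condition, response = response, seed = 1L)
  generate_extraction_dataset(des)
}
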