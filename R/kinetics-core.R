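# Universal gas constant, J/(mol K)
GAS_CONSTANT <- 8.314

# Evaluate `expr` muffling summary.lm's warning on zero-residual fits, which
# are expected for noiseless synthetic inputs
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Weibull-Arrhenius kinetic parameters
#'
#' Container for the three identifiable parameters of the combined
#' Weibull-Arrhenius extraction-yield model: the pre-exponential scale
#' \eqn{\alpha_0} (seconds), the activation energy \eqn{E_a} (J/mol) and the
#' dimensionless shape \eqn{\beta}. The temperature-dependent Weibull scale
#' is \eqn{\alpha(T) = \alpha_0 \exp(+E_a / (R T))} with \eqn{T} in Kelvin,
#' so the extraction rate \eqn{1/\alpha} follows the usual Arrhenius law and
#' \eqn{\alpha} decreases (extraction accelerates) with temperature.
#'
#' @param alpha0 Pre-exponential scale, seconds; must be > 0.
#' @param Ea Activation energy, J/mol; must be >= 0.
#' @param beta Dimensionless Weibull shape; must be > 0. \code{beta = 1}
#'   gives first-order kinetics; \code{beta < 1} a rate that decreases over
#'   extraction time.
#'
#' @return An object of class \code{weibull_arrhenius_params}.
#' @examples
#' p <- weibull_arrhenius_params(alpha0 = 1.69e-3, Ea = 23103.4, beta = 0.618)
#' alpha_at_temperature(p, 278.15) # characteristic time at 5 degC, seconds
#' @export
weibull_arrhenius_params <- function(alpha0, Ea, beta) {
  stopifnot(is.numeric(alpha0), is.numeric(Ea), is.numeric(beta),
            length(alpha0) == 1L, length(Ea) == 1L, length(beta) == 1L)
  if (!is.finite(alpha0) || alpha0 <= 0)
    stop("`alpha0` must be a positive finite scale in seconds", call. = FALSE)
  if (!is.finite(Ea) || Ea < 0)
    stop("`Ea` must be a non-negative activation energy in J/mol", call. = FALSE)
  if (!is.finite(beta) || beta <= 0)
    stop("`beta` must be a positive shape parameter", call. = FALSE)
  structure(list(alpha0 = alpha0, Ea = Ea, beta = beta, R = GAS_CONSTANT),
            class = "weibull_arrhenius_params")
}

#' @export
print.weibull_arrhenius_params <- function(x, ...) {
  cat("Weibull-Arrhenius parameters\n")
  cat(sprintf("  alpha0: %.4g s\n  Ea:     %.6g J/mol\n  beta:   %.4g\n",
              x$alpha0, x$Ea, x$beta))
  invisible(x)
}

#' Weibull scale parameter at a given temperature
#'
#' Evaluates \eqn{\alpha(T) = \alpha_0 \exp(E_a / (R T))} in log space to
#' avoid floating overflow for large \eqn{E_a / (R T)}. Because the rate
#' \eqn{1/\alpha} obeys the Arrhenius law, \eqn{\alpha(T)} is strictly
#' decreasing in temperature whenever \eqn{E_a > 0}.
#'
#' @param params A \code{\link{weibull_arrhenius_params}} object.
#' @param temperature_K Absolute temperature(s), Kelvin; must be > 0.
#' @return Characteristic time(s) \eqn{\alpha}, seconds.
#' @export
alpha_at_temperature <- function(params, temperature_K) {
  stopifnot(inherits(params, "weibull_arrhenius_params"),
            is.numeric(temperature_K))
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("`temperature_K` must be positive (absolute temperature)",
         call. = FALSE)
  exp(log(params$alpha0) + params$Ea / (params$R * temperature_K))
}

#' Weibull extraction yield
#'
#' Cumulative Weibull yield curve
#' \eqn{Y(t) = Y_{eq} (1 - \exp(-(t/\alpha)^\beta))}: zero at \eqn{t = 0},
#' monotone non-decreasing, approaching the equilibrium yield asymptotically.
#'
#' @param t Extraction time(s), seconds; must be >= 0.
#' @param alpha Weibull scale (characteristic time), seconds; > 0.
#' @param beta Weibull shape; > 0.
#' @param y_eq Equilibrium yield, percent of the matrix content; > 0.
#' @return Yield(s) in percent, in \eqn{[0, y_{eq})}.
#' @export
weibull_yield <- function(t, alpha, beta, y_eq) {
  stopifnot(is.numeric(t), is.numeric(alpha), is.numeric(beta),
            is.numeric(y_eq))
  if (any(t < 0)) stop("extraction time `t` must be non-negative", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0) || any(y_eq <= 0))
    stop("`alpha`, `beta` and `y_eq` must be positive", call. = FALSE)
  # (t/alpha)^beta in log space; t = 0 maps to yield 0 for any beta > 0
  u <- ifelse(t == 0, -Inf, beta * (log(t) - log(alpha)))
  y_eq * (1 - exp(-exp(u)))
}

#' Predict an extraction-yield curve
#'
#' Composes \code{\link{alpha_at_temperature}} and \code{\link{weibull_yield}}
#' to evaluate the full model at a set of sampling times and one extraction
#' temperature (user-facing Celsius; converted internally as T + 273.15 K).
#'
#' @param params A \code{\link{weibull_arrhenius_params}} object.
#' @param y_eq Equilibrium yield for this curve, percent.
#' @param times Sampling times, seconds, non-negative.
#' @param temperature_C Extraction temperature, degrees Celsius.
#' @return Numeric vector of predicted yields (percent), one per time.
#' @export
predict_curve <- function(params, y_eq, times, temperature_C) {
  alpha <- alpha_at_temperature(params, celsius_to_kelvin(temperature_C))
  weibull_yield(times, alpha, params$beta, y_eq)
}

#' @rdname predict_curve
#' @export
celsius_to_kelvin <- function(temperature_C) {
  if (any(temperature_C < -273.15))
    stop("temperature below absolute zero", call. = FALSE)
  temperature_C + 273.15
}

#' A single extraction-yield time series
#'
#' One condition x temperature x response time series of extraction yields
#' (percent of the content of the initial byproduct), together with its
#' equilibrium yield -- the terminal (30 min) observed yield treated as the
#' asymptote of the Weibull model.
#'
#' @param condition Extraction condition label, e.g. \code{"CE"} (mechanical
#'   agitation), \code{"UAE1"}, \code{"UAE2"} (ultrasound at two acoustic
#'   power densities), or any user-defined label.
#' @param temperature_C Extraction temperature, degrees Celsius.
#' @param response Response label, e.g. \code{"TPC"}, \code{"TFC"},
#'   \code{"AA"}.
#' @param times Sampling times, seconds, strictly increasing and >= 0.
#'   With replicates, supply each time once and a yield matrix, or repeat
#'   times via \code{replicate}.
#' @param yields Observed yields, percent; same length as \code{times}.
#' @param equilibrium_yield Equilibrium yield, percent; > 0. Defaults to the
#'   (mean) yield at the final sampling time.
#' @param replicate Optional integer replicate index per observation; when
#'   given, \code{times} need only be increasing within replicate.
#' @return An object of class \code{extraction_curve}.
#' @export
extraction_curve <- function(condition, temperature_C, response,
                             times, yields, equilibrium_yield = NULL,
                             replicate = NULL) {
  stopifnot(is.numeric(times), is.numeric(yields),
            length(times) == length(yields), length(times) >= 1L)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.null(replicate)) {
    if (any(diff(times) <= 0))
      stop("`times` must be strictly increasing", call. = FALSE)
  } else {
    stopifnot(length(replicate) == length(times))
    for (r in unique(replicate)) {
      if (any(diff(times[replicate == r]) <= 0))
        stop("`times` must be strictly increasing within each replicate",
             call. = FALSE)
    }
  }
  if (any(yields < 0))
    stop("`yields` must be non-negative percentages", call. = FALSE)
  if (any(yields > 100))
    warning("yields above 100% retained as-is (measurement noise?)",
            call. = FALSE)
  if (is.null(equilibrium_yield)) {
    tmax <- max(times)
    equilibrium_yield <- mean(yields[times == tmax])
  }
  if (!is.finite(equilibrium_yield) || equilibrium_yield <= 0)
    stop("`equilibrium_yield` must be positive", call. = FALSE)
  structure(list(condition = as.character(condition),
                 temperature_C = as.numeric(temperature_C),
                 response = as.character(response),
                 times = as.numeric(times), yields = as.numeric(yields),
                 equilibrium_yield = as.numeric(equilibrium_yield),
                 replicate = if (is.null(replicate)) NULL
                             else as.integer(replicate)),
            class = "extraction_curve")
}

#' @export
print.extraction_curve <- function(x, ...) {
  cat(sprintf("Extraction curve: %s / %s at %g degC, %d obs, Yeq = %.2f%%\n",
              x$condition, x$response, x$temperature_C,
              length(x$times), x$equilibrium_yield))
  invisible(x)
}

#' Multi-temperature kinetics dataset
#'
#' Bundles the extraction curves of one condition and one response measured
#' at two or more distinct temperatures. All curves are used simultaneously
#' when identifying the shared (alpha0, Ea, beta) parameters.
#'
#' @param curves A list of \code{\link{extraction_curve}} objects sharing
#'   condition and response, with distinct temperatures.
#' @return An object of class \code{kinetics_dataset}.
#' @export
kinetics_dataset <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  if (!all(vapply(curves, inherits, logical(1), "extraction_curve")))
    stop("`curves` must be a list of extraction_curve objects", call. = FALSE)
  conds <- unique(vapply(curves, `[[`, character(1), "condition"))
  resps <- unique(vapply(curves, `[[`, character(1), "response"))
  if (length(conds) != 1L || length(resps) != 1L)
    stop("all curves must share one condition and one response", call. = FALSE)
  temps <- vapply(curves, `[[`, numeric(1), "temperature_C")
  if (anyDuplicated(temps))
    stop("curve temperatures must be distinct", call. = FALSE)
  structure(list(condition = conds, response = resps,
                 curves = curves[order(temps)]),
            class = "kinetics_dataset")
}

#' @export
print.kinetics_dataset <- function(x, ...) {
  temps <- vapply(x$curves, `[[`, numeric(1), "temperature_C")
  cat(sprintf("Kinetics dataset: %s / %s at %s degC (%d observations)\n",
              x$condition, x$response, paste(temps, collapse = ", "),
              sum(vapply(x$curves, function(k) length(k$times), integer(1)))))
  invisible(x)
}

# Flatten a dataset to one observation table (optionally averaging replicates)
dataset_observations <- function(dataset, aggregate = c("mean", "pool")) {
  aggregate <- match.arg(aggregate)
  rows <- lapply(dataset$curves, function(k) {
    d <- data.frame(time = k$times, yield = k$yields,
                    temperature_C = k$temperature_C,
                    y_eq = k$equilibrium_yield)
    if (aggregate == "mean" && (!is.null(k$replicate) || anyDuplicated(k$times))) {
      agg <- stats::aggregate(yield ~ time, data = d, FUN = mean)
      d <- data.frame(time = agg$time, yield = agg$yield,
                      temperature_C = k$temperature_C,
                      y_eq = k$equilibrium_yield)
    }
    d
  })
  do.call(rbind, rows)
}
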