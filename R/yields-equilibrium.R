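# Concentration -> yield conversion and equilibrium-yield analysis.

#' Extraction yield from concentrations
#'
#' Converts an extract concentration to an extraction yield as a percentage
#' of the content of the initial byproduct: \eqn{Y = 100 C / C_{max}}. Both
#' quantities must be on the same basis (e.g. mg GAE / 100 g dry matter), so
#' the yield is invariant to a common unit change.
#'
#' @param concentration Extract concentration(s) \eqn{C}, >= 0.
#' @param c_max Concentration in the initial byproduct, same units; > 0.
#' @return Yield(s) in percent. Values above 100 are retained (with a
#'   warning) rather than clipped: the fitter must see the data as-is.
#' @examples
#' extraction_yield(750, 1674) # 44.8% of the total phenolic content
#' @export
extraction_yield <- function(concentration, c_max) {
  stopifnot(is.numeric(concentration), is.numeric(c_max))
  if (any(c_max <= 0))
    stop("`c_max` must be positive", call. = FALSE)
  if (any(concentration < 0))
    stop("`concentration` must be non-negative", call. = FALSE)
  y <- 100 * concentration / c_max
  if (any(y > 100))
    warning(sum(y > 100), " yield value(s) above 100% retained as-is",
            call. = FALSE)
  y
}

#' Equilibrium yield of an extraction curve
#'
#' The yield at the terminal sampling time (nominally 30 min), taken as the
#' equilibrium value and used as the fixed asymptote of the Weibull model.
#' Replicate terminal observations are averaged.
#'
#' @param curve An \code{\link{extraction_curve}}, or a data frame / list
#'   with elements \code{times} and \code{yields}.
#' @return Equilibrium yield, percent.
#' @export
equilibrium_yield <- function(curve) {
  times <- curve$times
  yields <- curve$yields
  stopifnot(is.numeric(times), is.numeric(yields),
            length(times) == length(yields), length(times) >= 1L)
  mean(yields[times == max(times)])
}

#' Linear temperature dependence of equilibrium yields
#'
#' Ordinary least-squares line \eqn{Y_{eq} = a T + b} over per-temperature
#' equilibrium yields. The slope is tested against zero at the 95% level
#' (two-sided t-test with n - 2 dof); when it is not significant the
#' \code{temperature_dependent} flag is \code{FALSE} and the equilibrium
#' yield is better summarized by its mean across temperatures.
#'
#' @param temperatures Extraction temperatures, degrees Celsius; >= 3 points
#'   with >= 2 distinct values.
#' @param y_eq Equilibrium yields, percent; same length.
#' @return An object of class \code{equilibrium_line}: \code{slope}
#'   (percent/degC), \code{intercept} (percent), \code{r_squared},
#'   \code{slope_p_value}, \code{temperature_dependent}, \code{mean_y_eq}.
#' @examples
#' fit_equilibrium_line(c(5, 15, 25), 0.301 * c(5, 15, 25) + 48.74)
#' @export
fit_equilibrium_line <- function(temperatures, y_eq) {
  stopifnot(is.numeric(temperatures), is.numeric(y_eq),
            length(temperatures) == length(y_eq))
  if (length(unique(temperatures)) < 2L)
    stop("need >= 2 distinct temperatures", call. = FALSE)
  if (length(temperatures) < 3L)
    stop("need >= 3 points for the slope test", call. = FALSE)
  fit <- stats::lm(y_eq ~ temperatures)
  # exact (collinear) inputs are legitimate here; r^2 is still well defined
  sm <- quiet_perfect_fit(summary(fit))
  slope <- stats::coef(fit)[[2L]]
  r2 <- sm$r.squared
  p <- sm$coefficients[2L, 4L]
  structure(list(slope = slope, intercept = stats::coef(fit)[[1L]],
                 r_squared = r2, slope_p_value = p,
                 temperature_dependent = is.finite(p) && p < 0.05,
                 mean_y_eq = mean(y_eq), n = length(y_eq)),
            class = "equilibrium_line")
}

#' @export
print.equilibrium_line <- function(x, ...) {
  cat(sprintf("Y_eq = %.4g T (degC) + %.4g   (r^2 = %.4g)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  temperature dependence %s (slope p = %.3g); mean Y_eq %.2f%%\n",
              if (x$temperature_dependent) "observed" else "not observed",
              x$slope_p_value, x$mean_y_eq))
  invisible(x)
}

#' @rdname fit_equilibrium_line
#' @param line An \code{equilibrium_line}.
#' @param temperature_C Temperature(s) at which to evaluate the line; when
#'   the dependence is not significant the across-temperature mean is
#'   returned instead.
#' @export
predict_equilibrium <- function(line, temperature_C) {
  stopifnot(inherits(line, "equilibrium_line"))
  if (line$temperature_dependent)
    line$slope * temperature_C + line$intercept
  else
    rep(line$mean_y_eq, length(temperature_C))
}
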