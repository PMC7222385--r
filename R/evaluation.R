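# Model adequacy: mean relative error and the derived summary statistics.

#' Mean relative error between observed and simulated yields
#'
#' \eqn{MRE = 100/n \sum_i |Y_i^{exp} - Y_i^{cal}| / Y_i^{exp}}, the
#' adequacy statistic for extraction-curve simulations. Zero-time
#' observations (where the observed yield is 0) must be excluded upstream;
#' any zero observed value raises an error rather than an infinite MRE.
#'
#' @param y_exp Observed yields, percent; all > 0.
#' @param y_cal Simulated/fitted yields, percent; same length.
#' @return MRE in percent (>= 0).
#' @examples
#' mean_relative_error(c(50, 100), c(45, 110)) # 10
#' @export
mean_relative_error <- function(y_exp, y_cal) {
  stopifnot(is.numeric(y_exp), is.numeric(y_cal),
            length(y_exp) == length(y_cal), length(y_exp) >= 1L)
  if (any(y_exp == 0))
    stop("observed yield of 0 (zero-time point?): exclude it before ",
         "computing the MRE", call. = FALSE)
  100 * mean(abs(y_exp - y_cal) / abs(y_exp))
}

#' Mean and sample standard deviation of MRE values
#'
#' Summarizes a set of per-experiment MREs as mean +/- sample sd (n - 1
#' denominator). For a single value the sd is reported as 0 with
#' \code{sd_defined = FALSE}. Raw values are kept unrounded; the print
#' method displays one decimal.
#'
#' @param values MRE values, percent; >= 1.
#' @return An object of class \code{mre_summary}: \code{mean}, \code{sd},
#'   \code{n}, \code{sd_defined}.
#' @export
summarize_mre <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 1L) stop("empty MRE vector", call. = FALSE)
  if (any(values < 0)) stop("MRE values must be >= 0", call. = FALSE)
  sd_defined <- length(values) >= 2L
  structure(list(mean = mean(values),
                 sd = if (sd_defined) stats::sd(values) else 0,
                 n = length(values), sd_defined = sd_defined),
            class = "mre_summary")
}

#' @export
print.mre_summary <- function(x, ...) {
  cat(sprintf("MRE: %.1f +/- %.1f%% (n = %d%s)\n", x$mean, x$sd, x$n,
              if (x$sd_defined) "" else "; sd undefined, reported as 0"))
  invisible(x)
}

#' Percent reduction in activation energy
#'
#' \eqn{100 (E_a^{ref} - E_a^{alt}) / E_a^{ref}}: how much an alternative
#' condition (e.g. ultrasound assistance) lowers the energy barrier for
#' release of a compound relative to a reference condition (e.g. mechanical
#' agitation).
#'
#' @param ea_reference Reference activation energy, J/mol; > 0.
#' @param ea_alternative Alternative activation energy, J/mol.
#' @return Percent decrease (negative if the alternative is larger).
#' @export
ea_reduction <- function(ea_reference, ea_alternative) {
  stopifnot(is.numeric(ea_reference), is.numeric(ea_alternative))
  if (any(ea_reference <= 0))
    stop("`ea_reference` must be positive", call. = FALSE)
  100 * (ea_reference - ea_alternative) / ea_reference
}

#' Reduction of the Weibull scale across temperature and ultrasound
#'
#' For each response, the percent decrease of the characteristic time
#' \eqn{\alpha} between the slowest configuration (reference condition at the
#' low temperature) and the fastest (alternative condition at the high
#' temperature): \eqn{100 (1 - \alpha_{alt}(T_{hi}) / \alpha_{ref}(T_{lo}))}.
#' Summarizes the combined acceleration from raising the temperature and
#' applying ultrasound.
#'
#' @param table Data frame with columns \code{condition}, \code{response},
#'   \code{alpha0}, \code{Ea}, \code{beta} (e.g. \code{\link{reference_params}()}).
#' @param reference,alternative Condition labels; defaults \code{"CE"} and
#'   \code{"UAE2"}.
#' @param temp_low_C,temp_high_C Temperatures, degrees Celsius; defaults 5
#'   and 25.
#' @return Named numeric vector of percent decreases, one per response.
#' @export
alpha_reduction_range <- function(table, reference = "CE",
                                  alternative = "UAE2",
                                  temp_low_C = 5, temp_high_C = 25) {
  need <- c("condition", "response", "alpha0", "Ea", "beta")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  responses <- unique(table$response)
  out <- vapply(responses, function(r) {
    ref <- table[table$condition == reference & table$response == r, ]
    alt <- table[table$condition == alternative & table$response == r, ]
    if (nrow(ref) != 1L || nrow(alt) != 1L)
      stop("need exactly one ", reference, " and one ", alternative,
           " entry for response ", r, call. = FALSE)
    a_ref <- alpha_at_temperature(
      weibull_arrhenius_params(ref$alpha0, ref$Ea, ref$beta),
      celsius_to_kelvin(temp_low_C))
    a_alt <- alpha_at_temperature(
      weibull_arrhenius_params(alt$alpha0, alt$Ea, alt$beta),
      celsius_to_kelvin(temp_high_C))
    100 * (1 - a_alt / a_ref)
  }, numeric(1))
  stats::setNames(out, responses)
}

#' MRE of a fitted model against its observations
#'
#' Convenience wrapper computing the MRE of a \code{weibull_fit} over the
#' observation table it was fitted to, excluding zero-time points.
#'
#' @param fit A \code{weibull_fit}.
#' @return MRE in percent.
#' @export
fit_mre <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  obs <- fit$observations
  keep <- obs$time > 0 & obs$yield > 0
  mean_relative_error(obs$yield[keep], obs$fitted[keep])
}
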