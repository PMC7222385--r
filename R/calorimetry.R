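# Calorimetric estimation of effective ultrasonic power: P = m Cp dT/dt,
# with dT/dt the OLS slope of the initial solvent temperature rise.

#' Calorimetry temperature trace
#'
#' Sampled (time, temperature) pairs from a thermocouple logging the solvent
#' during ultrasound application (nominally 1 Hz over the first 5 min).
#' Traces from multiple probes logged on a common time base can be averaged
#' per time point with \code{\link{average_traces}} before regression.
#'
#' @param times Sampling times, seconds, strictly increasing.
#' @param temperatures Solvent temperatures, degrees Celsius; same length.
#' @param probe_id Optional probe label.
#' @return An object of class \code{calorimetry_trace}.
#' @export
calorimetry_trace <- function(times, temperatures, probe_id = "probe") {
  stopifnot(is.numeric(times), is.numeric(temperatures),
            length(times) == length(temperatures), length(times) >= 2L)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times),
                 temperatures = as.numeric(temperatures),
                 probe_id = as.character(probe_id)),
            class = "calorimetry_trace")
}

#' @rdname calorimetry_trace
#' @param traces List of \code{calorimetry_trace} objects on identical time
#'   bases (e.g. the two thermocouples of one run).
#' @export
average_traces <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  t0 <- traces[[1L]]$times
  for (tr in traces)
    if (!isTRUE(all.equal(tr$times, t0)))
      stop("traces must share one time base to be averaged", call. = FALSE)
  temps <- rowMeans(vapply(traces, `[[`, numeric(length(t0)), "temperatures"))
  calorimetry_trace(t0, temps, probe_id = "averaged")
}

#' Effective ultrasonic power from a temperature-rise trace
#'
#' Estimates the heating rate dT/dt as the ordinary least-squares slope of
#' temperature against time over the analysis window (default the first
#' 300 s), then P = m Cp dT/dt. The slope standard error propagates linearly
#' to the power. OLS over the full window is used instead of a two-point
#' difference for robustness to 1 Hz sensor noise.
#'
#' @param trace A \code{\link{calorimetry_trace}}, or a list of traces on a
#'   shared time base (averaged per time point before regression).
#' @param mass Solvent mass, kg; defaults to \code{volume * 0.998} (water at
#'   ambient) when \code{volume} is supplied.
#' @param cp Specific heat of the solvent, J/(kg degC); default 4186 (water).
#' @param volume Extraction volume, litres; needed for the power density and
#'   for the default mass.
#' @param window Analysis window \code{c(start, end)} in seconds; default
#'   \code{c(0, 300)}.
#' @return An object of class \code{power_result} with elements \code{power}
#'   (W), \code{power_density} (W/L, \code{NA} without \code{volume}),
#'   \code{slope} and \code{slope_stderr} (K/s), \code{power_stderr} (W),
#'   \code{mass}, \code{cp}, \code{volume}, \code{n}, and \code{cooling}
#'   (flag, \code{TRUE} when the slope is negative).
#' @examples
#' tr <- generate_calorimetry_trace(power = 104, mass = 0.2, cp = 4186,
#'                                  duration = 300, noise_sd = 0, seed = 1)
#' estimate_power(tr, mass = 0.2, cp = 4186, volume = 0.2)
#' @export
estimate_power <- function(trace, mass = NULL, cp = 4186, volume = NULL,
                           window = c(0, 300)) {
  if (is.list(trace) && !inherits(trace, "calorimetry_trace"))
    trace <- average_traces(trace)
  stopifnot(inherits(trace, "calorimetry_trace"))
  if (is.null(mass)) {
    if (is.null(volume))
      stop("supply `mass`, or `volume` for the water-density default",
           call. = FALSE)
    mass <- volume * 0.998
  }
  if (mass <= 0 || cp <= 0)
    stop("`mass` and `cp` must be positive", call. = FALSE)
  stopifnot(is.numeric(window), length(window) == 2L, window[1L] < window[2L])
  keep <- trace$times >= window[1L] & trace$times <= window[2L]
  if (sum(keep) < 3L)
    stop("fewer than 3 samples in the analysis window", call. = FALSE)
  tt <- trace$times[keep]
  TT <- trace$temperatures[keep]
  fit <- stats::lm(TT ~ tt)
  slope <- stats::coef(fit)[[2L]]
  slope_se <- quiet_perfect_fit(summary(fit))$coefficients[2L, 2L]
  power <- mass * cp * slope
  structure(list(power = power,
                 power_density = if (is.null(volume)) NA_real_
                                 else power_density(power, volume),
                 slope = slope, slope_stderr = slope_se,
                 power_stderr = mass * cp * slope_se,
                 mass = mass, cp = cp,
                 volume = if (is.null(volume)) NA_real_ else volume,
                 n = sum(keep), cooling = slope < 0),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Ultrasonic power: %.3f +/- %.3f W (slope %.5g K/s, n = %d)\n",
              x$power, x$power_stderr, x$slope, x$n))
  if (!is.na(x$power_density))
    cat(sprintf("  acoustic power density: %.1f W/L in %.3g L\n",
                x$power_density, x$volume))
  if (x$cooling) cat("  NOTE: negative slope -- cooling trace\n")
  invisible(x)
}

#' Acoustic power density
#'
#' Ratio of the effective ultrasonic power to the total extraction volume.
#'
#' @param power Effective ultrasonic power, W.
#' @param volume Total extraction volume, litres; must be > 0.
#' @return Power density, W/L.
#' @examples
#' power_density(104, 0.2) # 520 W/L
#' @export
power_density <- function(power, volume) {
  stopifnot(is.numeric(power), is.numeric(volume))
  if (any(volume <= 0)) stop("`volume` must be positive", call. = FALSE)
  power / volume
}

#' Replicate summary of power densities
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' acoustic power densities of replicate calorimetry runs.
#'
#' @param results List of \code{power_result} objects (>= 2), or a numeric
#'   vector of power densities in W/L.
#' @return List with \code{mean}, \code{sd}, \code{n} (W/L).
#' @export
replicate_summary <- function(results) {
  if (is.list(results))
    results <- vapply(results, function(r) {
      stopifnot(inherits(r, "power_result"))
      r$power_density
    }, numeric(1))
  if (length(results) < 2L)
    stop("need >= 2 replicate results", call. = FALSE)
  if (anyNA(results))
    stop("power density missing: supply `volume` to estimate_power()",
         call. = FALSE)
  list(mean = mean(results), sd = stats::sd(results), n = length(results))
}

#' Read a calorimetry trace from CSV
#'
#' Expects a header with columns \code{time_s} and \code{temperature_C}.
#'
#' @param path CSV file path.
#' @param probe_id Probe label for the returned trace.
#' @return A \code{\link{calorimetry_trace}}.
#' @export
read_calorimetry_csv <- function(path, probe_id = basename(path)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "temperature_C")
  if (!all(need %in% names(d)))
    stop("calorimetry CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  calorimetry_trace(d$time_s, d$temperature_C, probe_id = probe_id)
}
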