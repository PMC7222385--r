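# CSV schemas and the end-to-end pipeline. Files always carry time in
# seconds (comma-separated, dot decimal, mandatory header).

KINETICS_KEY_COLS <- c("condition", "response", "temperature_C", "time_s")

#' Load extraction kinetics data from CSV
#'
#' Reads a long-format table with mandatory columns \code{condition},
#' \code{response}, \code{temperature_C}, \code{time_s} and either
#' \code{yield_pct} or the pair \code{concentration}, \code{c_max}
#' (converted through \code{\link{extraction_yield}}). An optional
#' \code{replicate} column disambiguates repeated (condition, response,
#' temperature, time) rows. Equilibrium yields are derived from the terminal
#' (largest-time) rows of each curve. Zero-time rows are accepted and kept
#' in the curves, but downstream MRE computation excludes them.
#'
#' @param path CSV file path.
#' @return Named list of \code{\link{kinetics_dataset}} objects, one per
#'   \code{condition/response} combination.
#' @export
load_kinetics_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(KINETICS_KEY_COLS, names(d))
  if (length(missing_cols))
    stop("kinetics CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  has_yield <- "yield_pct" %in% names(d)
  has_conc <- all(c("concentration", "c_max") %in% names(d))
  if (!has_yield && !has_conc)
    stop("kinetics CSV needs either `yield_pct` or both `concentration` ",
         "and `c_max`", call. = FALSE)
  num_cols <- c("temperature_C", "time_s",
                if (has_yield) "yield_pct",
                if (has_conc) c("concentration", "c_max"))
  for (cl in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[cl]]))))
    if (length(bad))
      stop(sprintf("non-numeric `%s` in row(s) %s", cl,
                   paste(utils::head(bad + 1L, 5L), collapse = ", ")),
           call. = FALSE)
    d[[cl]] <- as.numeric(d[[cl]])
  }
  if (!has_yield) d$yield_pct <- extraction_yield(d$concentration, d$c_max)
  if (!"replicate" %in% names(d)) {
    key <- do.call(paste, c(d[KINETICS_KEY_COLS], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup))
      stop("duplicate (condition, response, temperature, time) without a ",
           "`replicate` column in row(s) ",
           paste(utils::head(dup + 1L, 5L), collapse = ", "), call. = FALSE)
    d$replicate <- 1L
  }

  out <- list()
  for (cond in unique(d$condition)) {
    for (resp in unique(d$response[d$condition == cond])) {
      dd <- d[d$condition == cond & d$response == resp, , drop = FALSE]
      curves <- lapply(sort(unique(dd$temperature_C)), function(Tc) {
        dt <- dd[dd$temperature_C == Tc, , drop = FALSE]
        dt <- dt[order(dt$replicate, dt$time_s), , drop = FALSE]
        y_eq <- mean(dt$yield_pct[dt$time_s == max(dt$time_s)])
        extraction_curve(cond, Tc, resp, dt$time_s, dt$yield_pct,
                         equilibrium_yield = y_eq,
                         replicate = if (max(dt$replicate) > 1L)
                           dt$replicate else NULL)
      })
      out[[paste(cond, resp, sep = "/")]] <- kinetics_dataset(curves)
    }
  }
  out
}

#' @rdname load_kinetics_csv
#' @param datasets A \code{kinetics_dataset} or list of them.
#' @export
write_kinetics_csv <- function(datasets, path) {
  if (inherits(datasets, "kinetics_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    do.call(rbind, lapply(ds$curves, function(k)
      data.frame(condition = k$condition, response = k$response,
                 temperature_C = k$temperature_C, time_s = k$times,
                 yield_pct = k$yields,
                 replicate = if (is.null(k$replicate)) 1L else k$replicate)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full extraction-kinetics analysis pipeline
#'
#' For every condition/response dataset: fits the Weibull-Arrhenius model
#' simultaneously across temperatures, computes 95% confidence intervals and
#' the fit MRE, and fits the linear temperature dependence of the
#' equilibrium yields (when curves at >= 3 temperatures are present). The
#' result is a structured report mirroring the standard presentation of
#' extraction-kinetics studies: identified parameters with uncertainties,
#' equilibrium lines, and an MRE table with per-response and overall
#' summaries.
#'
#' @param input A path to a kinetics CSV (see \code{\link{load_kinetics_csv}})
#'   or a (list of) \code{\link{kinetics_dataset}}.
#' @param config A \code{\link{fit_config}}.
#' @param conditions,responses Optional filters.
#' @param output_path Optional path for a JSON serialization of the report.
#' @return An object of class \code{uaekin_report}: \code{fits} (named list
#'   of \code{weibull_fit}), \code{parameter_table} (data frame),
#'   \code{equilibrium_lines}, \code{mre} (per-dataset values, per-response
#'   and overall \code{\link{summarize_mre}} summaries), \code{failures},
#'   and \code{provenance}.
#' @export
run_pipeline <- function(input, config = fit_config(),
                         conditions = NULL, responses = NULL,
                         output_path = NULL) {
  datasets <- if (is.character(input)) load_kinetics_csv(input)
              else if (inherits(input, "kinetics_dataset"))
                stats::setNames(list(input),
                                paste(input$condition, input$response,
                                      sep = "/"))
              else input
  keep <- vapply(datasets, function(ds) {
    (is.null(conditions) || ds$condition %in% conditions) &&
      (is.null(responses) || ds$response %in% responses)
  }, logical(1))
  datasets <- datasets[keep]
  if (!length(datasets))
    message("no datasets selected: empty report")

  fits <- list()
  failures <- character(0)
  for (nm in names(datasets)) {
    fits[[nm]] <- tryCatch(fit_weibull_arrhenius(datasets[[nm]], config),
                           error = function(e) e)
    if (inherits(fits[[nm]], "error")) {
      failures <- c(failures, sprintf("%s: %s", nm,
                                      conditionMessage(fits[[nm]])))
      fits[[nm]] <- NULL
    } else if (!fits[[nm]]$converged) {
      failures <- c(failures, sprintf("%s: fit did not converge", nm))
    }
  }

  par_tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(condition = f$condition, response = f$response,
               alpha0 = f$params$alpha0, Ea = f$params$Ea,
               beta = f$params$beta,
               alpha0_low = f$ci95$low[1], alpha0_high = f$ci95$high[1],
               Ea_low = f$ci95$low[2], Ea_high = f$ci95$high[2],
               beta_low = f$ci95$low[3], beta_high = f$ci95$high[3],
               rss = f$rss, n_obs = f$n_obs, converged = f$converged,
               mre = fit_mre(f))))
  rownames(par_tab) <- NULL

  eq_lines <- lapply(datasets, function(ds) {
    temps <- vapply(ds$curves, `[[`, numeric(1), "temperature_C")
    if (length(temps) < 3L) return(NULL)
    y_eq <- vapply(ds$curves, `[[`, numeric(1), "equilibrium_yield")
    fit_equilibrium_line(temps, y_eq)
  })
  eq_lines <- eq_lines[!vapply(eq_lines, is.null, logical(1))]

  mre_values <- if (is.null(par_tab)) numeric(0)
                else stats::setNames(par_tab$mre,
                                     paste(par_tab$condition,
                                           par_tab$response, sep = "/"))
  per_response <- if (is.null(par_tab)) list()
                  else lapply(split(par_tab$mre, par_tab$response),
                              summarize_mre)
  overall <- if (length(mre_values)) summarize_mre(mre_values) else NULL

  report <- structure(list(
    fits = fits, parameter_table = par_tab,
    equilibrium_lines = eq_lines,
    mre = list(per_dataset = mre_values, per_response = per_response,
               overall = overall),
    failures = failures,
    provenance = list(
      package = "uaekin",
      version = as.character(utils::packageVersion("uaekin")),
      arrhenius_sign = "alpha(T) = alpha0 * exp(+Ea/(R*T))",
      aggregate = config$aggregate,
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "uaekin_report")
  if (!is.null(output_path)) write_report_json(report, output_path)
  report
}

# JSON serialization of the report (timestamps and fit objects excluded
# from the round-trippable numeric payload)
write_report_json <- function(report, path) {
  payload <- list(
    parameters = report$parameter_table,
    equilibrium_lines = lapply(report$equilibrium_lines, function(l)
      l[c("slope", "intercept", "r_squared", "slope_p_value",
          "temperature_dependent", "mean_y_eq")]),
    mre = list(per_dataset = as.list(report$mre$per_dataset),
               per_response = lapply(report$mre$per_response,
                                     function(s) s[c("mean", "sd", "n")]),
               overall = if (is.null(report$mre$overall)) NULL
                         else report$mre$overall[c("mean", "sd", "n")]),
    failures = report$failures,
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.uaekin_report <- function(x, ...) {
  cat("Extraction-kinetics report\n")
  if (!is.null(x$parameter_table)) {
    cat("\nIdentified Weibull-Arrhenius parameters:\n")
    tab <- x$parameter_table
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-10s alpha0 %.3e s  Ea %.1f J/mol  beta %.3f  MRE %.1f%%\n",
                  paste(tab$condition[i], tab$response[i], sep = "/"),
                  tab$alpha0[i], tab$Ea[i], tab$beta[i], tab$mre[i]))
  }
  if (length(x$equilibrium_lines)) {
    cat("\nEquilibrium-yield temperature dependence:\n")
    for (nm in names(x$equilibrium_lines)) {
      l <- x$equilibrium_lines[[nm]]
      cat(sprintf("  %-10s %s\n", nm,
                  if (l$temperature_dependent)
                    sprintf("Y_eq = %.3f T + %.2f (r^2 = %.3f)",
                            l$slope, l$intercept, l$r_squared)
                  else sprintf("no T dependence; mean Y_eq = %.1f%%",
                               l$mean_y_eq)))
    }
  }
  if (!is.null(x$mre$overall))
    cat(sprintf("\nOverall MRE: %.1f +/- %.1f%% (n = %d)\n",
                x$mre$overall$mean, x$mre$overall$sd, x$mre$overall$n))
  if (length(x$failures))
    cat("\nFailures:\n", paste(" ", x$failures, collapse = "\n"), "\n")
  invisible(x)
}
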