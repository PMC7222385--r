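# Closed-form oracles shared across test files.

# Normal-equations OLS for y ~ x: c(intercept, slope)
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Printed alpha values (s) at 5 and 25 degC per condition/response, as
# reported alongside the reference parameter table
printed_alpha_values <- function() {
  data.frame(
    condition = rep(c("CE", "CE", "CE", "UAE1", "UAE2", "UAE1",
                      "UAE2", "UAE1", "UAE2"), each = 2),
    response = rep(c("TPC", "TFC", "AA", "TPC", "TPC", "TFC",
                     "TFC", "AA", "AA"), each = 2),
    temperature_C = rep(c(5, 25), times = 9),
    alpha = c(279, 45, 199, 49, 154, 23, 63, 18, 37, 19,
              48, 30, 48, 30, 57, 15, 26, 8))
}

# One reference row as a params object
reference_params_for <- function(condition, response) {
  tab <- reference_params()
  r <- tab[tab$condition == condition & tab$response == response, ]
  weibull_arrhenius_params(r$alpha0, r$Ea, r$beta)
}
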