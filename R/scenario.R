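#' Build an initiation scenario
#'
#' An initiation scenario is the generative truth behind a synthetic
#' population: the expected number of people injecting for the first time in
#' each calendar year, together with the (possibly drifting) distribution of
#' age at first injection. Two presets are provided:
#'
#' * `"constant"`: the same expected rate `amplitude` every year.
#' * `"gaussian_peak"`: `rate(c) = amplitude * exp(-(c - peak_year)^2 / (2 * width^2))`,
#'   an epidemic-wave shape — initiation rising to a single peak and declining,
#'   as UK heroin injection did with its late-1990s peak.
#'
#' @param preset `"constant"` or `"gaussian_peak"`.
#' @param years inclusive integer calendar-year range of initiation.
#' @param amplitude expected initiations per year (`"constant"`), or at the
#'   peak (`"gaussian_peak"`). Must be positive.
#' @param peak_year calendar year of the peak (`"gaussian_peak"` only); must
#'   lie within `years`.
#' @param width Gaussian width in years (`"gaussian_peak"` only).
#' @param age_mean mean age at first injection: a single value, a length-2
#'   vector `(start, end)` interpolated linearly across `years` (a drifting
#'   age of initiation), or a vector with one value per year.
#' @param age_sd standard deviation of age at first injection, years.
#' @param age_min minimum age at initiation; the age distribution is a normal
#'   truncated below at this value.
#' @return An object of class `initiation_scenario`: a list with elements
#'   `years`, `rate` (named by year), `age_mean` (named by year), `age_sd`,
#'   `age_min`.
#' @examples
#' sc <- make_scenario("gaussian_peak",
#'   years = 1980:2019, amplitude = 10000,
#'   peak_year = 1998, width = 5
#' )
#' sc$rate["1998"]
#' @export
make_scenario <- function(preset = c("constant", "gaussian_peak"),
                          years = 1960:2019,
                          amplitude = 1000,
                          peak_year = NULL,
                          width = NULL,
                          age_mean = c(21, 30),
                          age_sd = 5,
                          age_min = 15) {
  preset <- match.arg(preset)
  stopifnot(
    length(years) >= 1, all(diff(years) == 1),
    is.numeric(amplitude), length(amplitude) == 1,
    is.numeric(age_sd), age_sd > 0, age_min >= 0
  )
  if (amplitude <= 0) stop("'amplitude' must be positive")
  rate <- switch(preset,
    constant = rep(amplitude, length(years)),
    gaussian_peak = {
      if (is.null(peak_year) || is.null(width)) {
        stop("preset 'gaussian_peak' requires 'peak_year' and 'width'")
      }
      if (!peak_year %in% years) stop("'peak_year' must lie within 'years'")
      if (width <= 0) stop("'width' must be positive")
      amplitude * exp(-(years - peak_year)^2 / (2 * width^2))
    }
  )
  am <- if (length(age_mean) == 1) {
    rep(age_mean, length(years))
  } else if (length(age_mean) == 2) {
    seq(age_mean[1], age_mean[2], length.out = length(years))
  } else if (length(age_mean) == length(years)) {
    age_mean
  } else {
    stop("'age_mean' must have length 1, 2, or one value per year")
  }
  structure(
    list(
      years = as.integer(years),
      rate = setNames(rate, years),
      age_mean = setNames(am, years),
      age_sd = age_sd,
      age_min = age_min
    ),
    class = "initiation_scenario"
  )
}

#' @export
print.initiation_scenario <- function(x, ...) {
  cat(sprintf(
    "<initiation_scenario> %d-%d; total expected initiations %.0f; peak %s (%.0f/yr)\n",
    min(x$years), max(x$years), sum(x$rate),
    names(which.max(x$rate)), max(x$rate)
  ))
  invisible(x)
}

#' True relative initiation curve of a scenario
#'
#' Normalises the scenario's expected initiation rates to sum to one, for
#' comparison with relative back-calculated cohort curves.
#'
#' @param scenario an [make_scenario()] object.
#' @return Named numeric vector (by calendar year) summing to 1.
#' @export
scenario_relative_curve <- function(scenario) {
  stopifnot(inherits(scenario, "initiation_scenario"))
  scenario$rate / sum(scenario$rate)
}
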