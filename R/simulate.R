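#' Simulate a population of people who start and stop injecting
#'
#' Draws, for each calendar year `c` of the scenario, a Poisson number of new
#' injectors with mean `rate(c)`; each person receives an integer age at first
#' injection from a normal distribution truncated below at `age_min` (mean
#' drifting by year as the scenario specifies), and a continuous injecting
#' duration. Durations are exponential — a constant per-year probability of
#' stopping (cessation or death), so the number still injecting from a cohort
#' decays exponentially with mean duration `mu`.
#'
#' @param scenario an [make_scenario()] object.
#' @param mu mean injecting duration in years (> 0); default 15.
#' @param seed integer seed; the population is deterministic given the seed.
#' @param duration_age_effect optional log-linear dependence of duration on
#'   age at initiation: person `i` in cohort `c` has mean duration
#'   `mu * exp(duration_age_effect * (init_age_i - age_mean(c)))`. The default
#'   0 keeps duration independent of age. A negative value (older initiates
#'   stop sooner) induces the age-correlated attrition that biases naive
#'   estimates of age at first injection in old cohorts.
#' @return A tibble with one row per person: `init_year`, `init_age`
#'   (integer years), `duration` (real years).
#' @examples
#' sc <- make_scenario("constant", years = 1990:1999, amplitude = 50)
#' pop <- simulate_population(sc, mu = 15, seed = 1)
#' @export
simulate_population <- function(scenario, mu = 15, seed,
                                duration_age_effect = 0) {
  stopifnot(inherits(scenario, "initiation_scenario"))
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0) stop("'mu' must be > 0")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n_per_year <- rpois(length(scenario$years), scenario$rate)
  init_year <- rep(scenario$years, n_per_year)
  n <- length(init_year)
  if (n == 0) {
    return(tibble::tibble(
      init_year = integer(), init_age = integer(), duration = numeric()
    ))
  }
  mean_age <- rep(unname(scenario$age_mean), n_per_year)
  # truncated normal by inverse CDF: u uniform on [F(age_min), 1)
  p_lo <- stats::pnorm(scenario$age_min, mean_age, scenario$age_sd)
  u <- p_lo + runif(n) * (1 - p_lo)
  init_age <- as.integer(round(qnorm(u, mean_age, scenario$age_sd)))
  init_age <- pmax(init_age, as.integer(scenario$age_min))
  mu_i <- mu * exp(duration_age_effect * (init_age - mean_age))
  duration <- rexp(n, rate = 1 / mu_i)
  tibble::tibble(init_year = init_year, init_age = init_age, duration = duration)
}

#' Corruption parameters for simulated survey records
#'
#' Probabilities of the data problems seen in self-completed surveillance
#' questionnaires, applied independently per record (and per field for the
#' missingness probabilities) after sampling.
#'
#' @param p_missing_age,p_missing_age_first,p_missing_year_first probability
#'   each field is deleted (item non-response).
#' @param p_non_recent probability a sampled record reports not injecting
#'   recently.
#' @param p_performance_only probability of an image-and-performance-
#'   enhancing-drugs-only record (non-psychoactive).
#' @param p_implausible probability the reported age at first injection is
#'   corrupted to exceed the current age.
#' @return An object of class `corruption_params`.
#' @export
corruption_params <- function(p_missing_age = 0,
                              p_missing_age_first = 0,
                              p_missing_year_first = 0,
                              p_non_recent = 0,
                              p_performance_only = 0,
                              p_implausible = 0) {
  p <- c(
    p_missing_age = p_missing_age,
    p_missing_age_first = p_missing_age_first,
    p_missing_year_first = p_missing_year_first,
    p_non_recent = p_non_recent,
    p_performance_only = p_performance_only,
    p_implausible = p_implausible
  )
  if (any(p < 0 | p > 1)) stop("corruption probabilities must lie in [0, 1]")
  structure(as.list(p), class = "corruption_params")
}

#' Survey design for cross-sectional sampling of a simulated population
#'
#' @param survey_years integer calendar years in which surveys are fielded
#'   (e.g. annual like the English UAM survey, or biennial like Scotland's
#'   NESI).
#' @param sample_size target participants per survey: a single number recycled
#'   across years, or a vector named by survey year.
#' @param corruption a [corruption_params()] object.
#' @param seed integer seed governing sampling and corruption.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(survey_years, sample_size = 2000,
                          corruption = corruption_params(), seed) {
  stopifnot(all(survey_years == as.integer(survey_years)))
  if (missing(seed)) stop("'seed' is required")
  survey_years <- as.integer(survey_years)
  n <- if (length(sample_size) == 1) {
    setNames(rep(as.integer(sample_size), length(survey_years)), survey_years)
  } else {
    if (is.null(names(sample_size)) ||
      !all(as.character(survey_years) %in% names(sample_size))) {
      stop("'sample_size' must be scalar or named by survey year")
    }
    setNames(
      as.integer(sample_size[as.character(survey_years)]),
      survey_years
    )
  }
  if (any(n < 0)) stop("sample sizes must be non-negative")
  stopifnot(inherits(corruption, "corruption_params"))
  structure(
    list(
      survey_years = survey_years, sample_size = n,
      corruption = corruption, seed = as.integer(seed)
    ),
    class = "survey_design"
  )
}

#' Simulate cross-sectional surveys of people currently injecting
#'
#' For each survey year `t`, samples uniformly without replacement from the
#' people currently injecting at `t` — those with `init_year <= t` and
#' `t - init_year < duration` (time is discrete at whole calendar years; the
#' continuous duration is compared against the integer gap). Each sampled
#' person yields one survey record with
#' `age = init_age + (t - init_year)`, `age_first_inj = init_age` and
#' `year_first_inj = init_year`; corruption (field deletion, non-recency and
#' performance-only flags, implausible ages) is then applied per
#' [corruption_params()]. Deterministic given the design seed; each survey
#' year uses its own child seed, so adding a survey year leaves the others
#' unchanged.
#'
#' @param population tibble from [simulate_population()].
#' @param design a [survey_design()] object.
#' @param survey_label value of the `survey` column in the output.
#' @return A tibble in the participant-record schema of [read_survey_csv()]:
#'   `survey, survey_year, region, sex, age, age_first_inj, year_first_inj,
#'   duration, recent_inj, psychoactive` (duration left `NA`; it is derived
#'   downstream by [derive_fields()]).
#' @export
simulate_surveys <- function(population, design, survey_label = "synthetic") {
  stopifnot(inherits(design, "survey_design"))
  cp <- design$corruption
  out <- vector("list", length(design$survey_years))
  for (i in seq_along(design$survey_years)) {
    t <- design$survey_years[i]
    n_target <- design$sample_size[[as.character(t)]]
    eligible <- which(population$init_year <= t &
      t - population$init_year < population$duration)
    n_t <- min(n_target, length(eligible))
    if (n_t < n_target) {
      warning(sprintf(
        "survey %d: only %d currently injecting; sample truncated from %d",
        t, length(eligible), n_target
      ))
    }
    set.seed(child_seed(design$seed, "survey", t))
    idx <- if (n_t > 0) sample(eligible, n_t) else integer()
    p <- population[idx, ]
    rec <- tibble::tibble(
      survey = rep(survey_label, n_t),
      survey_year = rep(as.integer(t), n_t),
      region = rep(NA_character_, n_t),
      sex = rep(NA_character_, n_t),
      age = p$init_age + (t - p$init_year),
      age_first_inj = p$init_age,
      year_first_inj = p$init_year,
      duration = rep(NA_integer_, n_t),
      recent_inj = rep(1L, n_t),
      psychoactive = rep(1L, n_t)
    )
    out[[i]] <- corrupt_records(rec, cp, child_seed(design$seed, "corrupt", t))
  }
  dplyr::bind_rows(out)
}

# apply corruption flags/deletions independently per record and field
corrupt_records <- function(rec, cp, seed) {
  n <- nrow(rec)
  if (n == 0) return(rec)
  set.seed(seed)
  implaus <- runif(n) < cp$p_implausible
  if (any(implaus)) {
    rec$age_first_inj[implaus] <- rec$age[implaus] +
      sample(1:5, sum(implaus), replace = TRUE)
  }
  rec$age[runif(n) < cp$p_missing_age] <- NA_integer_
  rec$age_first_inj[runif(n) < cp$p_missing_age_first] <- NA_integer_
  rec$year_first_inj[runif(n) < cp$p_missing_year_first] <- NA_integer_
  rec$recent_inj[runif(n) < cp$p_non_recent] <- 0L
  rec$psychoactive[runif(n) < cp$p_performance_only] <- 0L
  rec
}
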