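# build a survey record row with sensible defaults; NA-able fields accept NULL
srec <- function(survey_year = 2019L, age = NA, age_first_inj = NA,
                 year_first_inj = NA, duration = NA, recent_inj = 1L,
                 psychoactive = 1L, survey = "synthetic", region = NA,
                 sex = NA, last_inj_year = NULL) {
  out <- tibble::tibble(
    survey = survey,
    survey_year = as.integer(survey_year),
    region = as.character(region),
    sex = as.character(sex),
    age = as.integer(age),
    age_first_inj = as.integer(age_first_inj),
    year_first_inj = as.integer(year_first_inj),
    duration = as.integer(duration),
    recent_inj = as.integer(recent_inj),
    psychoactive = as.integer(psychoactive)
  )
  if (!is.null(last_inj_year)) out$last_inj_year <- as.integer(last_inj_year)
  out
}

# clean synthetic survey table from a scenario, no corruption
simulate_clean_table <- function(scenario, survey_years, n, seed, mu = 15,
                                 duration_age_effect = 0) {
  pop <- simulate_population(scenario,
    mu = mu, seed = child_seed(seed, "pop"),
    duration_age_effect = duration_age_effect
  )
  des <- survey_design(survey_years, n, seed = child_seed(seed, "design"))
  tab <- derive_fields(simulate_surveys(pop, des))
  apply_exclusions(tab)$clean
}

# histogram tibble from named count vectors, e.g. hist_tbl(`2000` = c(`1990` = 10))
hist_tbl <- function(...) {
  args <- list(...)
  dplyr::bind_rows(lapply(names(args), function(t) {
    tibble::tibble(
      survey_year = as.integer(t),
      stratum = "all",
      init_year = as.integer(names(args[[t]])),
      count = unname(args[[t]])
    )
  }))
}
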