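test_that("derive_fields fills exactly what the identities allow", {
  r <- derive_fields(srec(2019, age = 40, age_first_inj = 22))
  expect_identical(r$duration, 18L)
  expect_identical(r$year_first_inj, 2001L)

  # age unknown: neither age nor age_first_inj is derivable
  r2 <- derive_fields(srec(2019, year_first_inj = 2001, duration = 18))
  expect_true(is.na(r2$age))
  expect_true(is.na(r2$age_first_inj))

  full <- derive_fields(srec(2019,
    age = 40, age_first_inj = 22,
    year_first_inj = 2001, duration = 18
  ))
  expect_identical(full, srec(2019,
    age = 40, age_first_inj = 22,
    year_first_inj = 2001, duration = 18
  ))

  # derivation chains: year_first -> duration -> age_first (given age)
  r3 <- derive_fields(srec(2019, age = 40, year_first_inj = 2001))
  expect_identical(r3$duration, 18L)
  expect_identical(r3$age_first_inj, 22L)
})

toy_table <- function() {
  dplyr::bind_rows(
    srec(2019, age = 30, age_first_inj = 20, recent_inj = 0), # not recent
    srec(2019, age = 30, age_first_inj = 20, psychoactive = 0), # performance-only
    srec(2019), # nothing derivable
    srec(2019, age = 30, age_first_inj = 35), # implausible
    srec(2019, age = 30, age_first_inj = 20),
    srec(2019, age = 44, age_first_inj = 25)
  )
}

test_that("the exclusion cascade counts each record once, in order", {
  res <- apply_exclusions(derive_fields(toy_table()))
  expect_identical(res$log$input, 6L)
  expect_identical(res$log$excluded_not_recent, 1L)
  expect_identical(res$log$excluded_performance_only, 1L)
  expect_identical(res$log$excluded_insufficient, 1L)
  expect_identical(res$log$excluded_implausible, 1L)
  expect_identical(res$log$retained, 2L)
  expect_identical(nrow(res$clean), 2L)

  # age at first injection older than current age is implausible
  solo <- apply_exclusions(derive_fields(srec(2019, age = 30, age_first_inj = 35)))
  expect_identical(solo$log$excluded_implausible, 1L)

  # idempotence: re-running on clean output excludes nothing
  again <- apply_exclusions(res$clean)
  expect_identical(again$log$retained, again$log$input)
  expect_identical(again$clean, res$clean)

  empty <- apply_exclusions(toy_table()[0, ])
  expect_identical(empty$log$input, 0L)
  expect_identical(nrow(empty$clean), 0L)
})

test_that("recency modes control how unknown recency is treated", {
  unk_91 <- srec(1991, age = 25, age_first_inj = 20, recent_inj = NA)
  unk_95 <- srec(1995, age = 25, age_first_inj = 20, recent_inj = NA)

  expect_identical(
    apply_exclusions(derive_fields(unk_91), "strict")$log$retained, 0L
  )
  # early-era surveys had no recency item: unknowns retained through 1992
  expect_identical(
    apply_exclusions(derive_fields(unk_91), "assume_recent_pre1993")$log$retained,
    1L
  )
  expect_identical(
    apply_exclusions(derive_fields(unk_95), "assume_recent_pre1993")$log$retained,
    0L
  )

  # year-of-last-injection dialect: same or previous year counts as recent
  li_ok <- srec(1995,
    age = 25, age_first_inj = 20, recent_inj = NA,
    last_inj_year = 1994
  )
  li_old <- srec(1995,
    age = 25, age_first_inj = 20, recent_inj = NA,
    last_inj_year = 1992
  )
  expect_identical(
    apply_exclusions(derive_fields(li_ok), "last_inj_year")$log$retained, 1L
  )
  expect_identical(
    apply_exclusions(derive_fields(li_old), "last_inj_year")$log$retained, 0L
  )
  expect_error(apply_exclusions(unk_95, "last_inj_year"), "last_inj_year")
})

test_that("duration-vs-year arithmetic tolerates one year, no more", {
  off1 <- srec(2019,
    age = 40, age_first_inj = 22, year_first_inj = 2000,
    duration = 18
  ) # 2019 - 2000 = 19 vs duration 18: within tolerance
  off2 <- srec(2019,
    age = 40, age_first_inj = 22, year_first_inj = 1999,
    duration = 18
  ) # gap 2: implausible
  expect_identical(apply_exclusions(off1)$log$retained, 1L)
  expect_identical(apply_exclusions(off2)$log$excluded_implausible, 1L)
})

test_that("exclusion counts reconcile and track the corruption rates", {
  sc <- make_scenario("constant", years = 1970:2009, amplitude = 400)
  pop <- simulate_population(sc, mu = 15, seed = 21)

  check_one <- function(cp, field, p, expected_of = function(log, n) n * p) {
    rec <- simulate_surveys(pop, survey_design(
      c(2000, 2005, 2009), 2000, cp,
      seed = 22
    ))
    res <- apply_exclusions(derive_fields(rec))
    log <- res$log
    expect_identical(
      log$input,
      log$retained + log$excluded_not_recent + log$excluded_performance_only +
        log$excluded_insufficient + log$excluded_implausible
    )
    n <- log$input
    expect_lt(abs(log[[field]] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
  check_one(
    corruption_params(p_non_recent = 0.15), "excluded_not_recent", 0.15
  )
  check_one(
    corruption_params(p_performance_only = 0.1), "excluded_performance_only", 0.1
  )
  check_one(
    corruption_params(p_implausible = 0.05), "excluded_implausible", 0.05
  )
  # a record is insufficient only when at most one of the three fields survives
  p_m <- 0.3
  p_insuff <- 3 * p_m^2 * (1 - p_m) + p_m^3
  check_one(
    corruption_params(
      p_missing_age = p_m, p_missing_age_first = p_m,
      p_missing_year_first = p_m
    ),
    "excluded_insufficient", p_insuff
  )
})

test_that("survey CSVs round-trip and malformed input is rejected", {
  tab <- derive_fields(toy_table())
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(tab, path)
  back <- read_survey_csv(path)
  expect_identical(back, tab)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("survey,year,age", "x,2000,30"), bad)
  expect_error(read_survey_csv(bad), "header")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "survey,survey_year,region,sex,age,age_first_inj,year_first_inj,duration,recent_inj,psychoactive",
    "x,2000,,,thirty,20,,,1,1"
  ), bad2)
  expect_error(read_survey_csv(bad2), "not numeric")
})
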