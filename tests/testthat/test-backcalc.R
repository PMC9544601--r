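test_that("the survival model is a valid strictly decreasing exponential", {
  m <- survival_model(15)
  expect_equal(surv_prob(m, 0), 1)
  d <- 0:100
  for (mu in c(0.5, 5, 15, 40)) {
    s <- surv_prob(survival_model(mu), d)
    expect_true(all(diff(s) < 0))
  }
  expect_error(survival_model(0), "positive")
  expect_error(surv_prob(m, -1), "non-negative")
})

test_that("single-survey inversion matches closed forms", {
  m <- survival_model(15)
  cv <- backcalc_single(hist_tbl(`2000` = c(`1990` = 10, `2000` = 10)), m)
  expect_equal(
    unname(cv$values["1990"] / cv$values["2000"]),
    exp(10 / 15),
    tolerance = 1e-12
  )
  expect_equal(sum(cv$values), 1)

  point <- backcalc_single(hist_tbl(`2000` = c(`1995` = 7)), m)
  expect_identical(unname(point$values), 1)

  raw <- backcalc_single(hist_tbl(`2000` = c(`1990` = 10, `2000` = 10)), m,
    normalise = FALSE
  )
  expect_equal(unname(raw$values["2000"]), 10)
  expect_equal(unname(raw$values["1990"]), 10 * exp(10 / 15))

  expect_error(
    backcalc_single(hist_tbl(`2000` = c(`1990` = 0)), m), "positive"
  )
  expect_error(
    backcalc_single(hist_tbl(`2000` = c(`2005` = 3)), m), "initiation year"
  )
})

test_that("inverting the forward map recovers the curve exactly", {
  set.seed(55)
  truth <- setNames(runif(25, 10, 500), 1980:2004)
  for (mu in c(5, 15, 40)) {
    m <- survival_model(mu)
    h <- expected_initiation_histogram(truth, 2010, m)
    rec <- backcalc_single(h, m)
    expect_lt(max(abs(rec$values - truth / sum(truth))), 1e-10)
  }
})

test_that("wrong assumed duration biases cohorts by the known factor", {
  truth <- setNames(rep(100, 30), 1980:2009)
  mu_true <- 15
  h <- expected_initiation_histogram(truth, 2010, survival_model(mu_true))
  for (mu_wrong in c(10, 20)) {
    est <- backcalc_single(h, survival_model(mu_wrong), normalise = FALSE)
    d <- 2010 - as.integer(names(est$values))
    factor_expected <- exp(d * (1 / mu_wrong - 1 / mu_true))
    rel_err <- abs(est$values / (truth * factor_expected) - 1)
    expect_lt(max(rel_err), 1e-8)
  }
})

test_that("combining surveys is consistent, weighted, and reproducible", {
  m <- survival_model(15)
  h1 <- hist_tbl(`2000` = c(`1990` = 40, `1995` = 60, `2000` = 30))
  single <- backcalc_single(h1, m)
  comb <- combine_surveys(h1, m, n_mc = 0)
  # combine_surveys also reports zero-count cohorts inside the observed span
  expect_equal(comb$values[names(single$values)], single$values,
    tolerance = 1e-12
  )
  expect_true(all(comb$values[setdiff(names(comb$values),
    names(single$values))] == 0))

  # doubling the evidence leaves the point estimate alone but tightens the
  # prediction interval
  one <- combine_surveys(h1, m, n_mc = 1000, seed = 5)
  dup <- combine_surveys(dplyr::bind_rows(h1, h1), m, n_mc = 1000, seed = 5)
  expect_equal(dup$values, one$values, tolerance = 1e-12)
  width <- function(cv) mean(cv$pri["high", ] - cv$pri["low", ])
  expect_lt(width(dup), width(one))

  expect_identical(
    combine_surveys(h1, m, n_mc = 200, seed = 9)$pri,
    combine_surveys(h1, m, n_mc = 200, seed = 9)$pri
  )
  expect_error(combine_surveys(h1, m, n_mc = 200), "seed")
  expect_error(combine_surveys(h1, m, n_mc = 50, seed = 1), "n_mc")
})

test_that("d_max truncation limits how far back a survey informs", {
  m <- survival_model(2) # d_max = 10
  h <- hist_tbl(`2000` = c(`1985` = 5, `1995` = 5, `2000` = 5))
  cv <- combine_surveys(h, m, n_mc = 0)
  expect_false("1985" %in% names(cv$values))
  expect_identical(unname(cv$n_surveys_informing[c("1995", "2000")]), c(1L, 1L))
})

test_that("calibration reproduces the flat-curve worked example and scales linearly", {
  m <- survival_model(15)
  flat <- injectcohort:::new_cohort_curve(
    values = setNames(rep(0.2, 5), 1996:2000),
    scale = "relative", mu = 15
  )
  anchor <- calibration_anchor(2000, 1000)
  cal <- calibrate(flat, anchor, m)
  # oracle: direct summation of the five survival terms
  implied_rel <- 0.2 * sum(exp(-(0:4) / 15))
  expect_equal(implied_rel, 0.879068, tolerance = 1e-6)
  expect_equal(unname(cal$values), rep(1000 / implied_rel * 0.2, 5),
    tolerance = 1e-12
  )
  expect_equal(unname(cal$values[1]), 227.5, tolerance = 1e-3)

  cal2 <- calibrate(flat, calibration_anchor(2000, 2000), m)
  expect_equal(cal2$values, cal$values * 2, tolerance = 1e-12)

  yrs <- as.integer(names(cal$values))
  implied_abs <- sum(cal$values * surv_prob(m, 2000 - yrs))
  expect_lt(abs(implied_abs / 1000 - 1), 1e-9)

  expect_error(calibrate(flat, calibration_anchor(1990, 100), m), "precedes")
  expect_error(calibrate(cal, anchor, m), "relative")
})

test_that("anchor uncertainty widens the calibrated prediction intervals", {
  m <- survival_model(15)
  h <- hist_tbl(`2005` = c(`1995` = 50, `2000` = 80, `2005` = 40))
  cv <- combine_surveys(h, m, n_mc = 1000, seed = 13)
  fixed <- calibrate(cv, calibration_anchor(2005, 10000), m)
  wide <- calibrate(
    cv,
    calibration_anchor(2005, 10000,
      prevalence_low = 6000,
      prevalence_high = 14000
    ),
    m,
    seed = 13
  )
  expect_gt(
    mean(wide$pri["high", ] - wide$pri["low", ]),
    mean(fixed$pri["high", ] - fixed$pri["low", ])
  )
  # point estimate uses the central prevalence either way
  expect_equal(wide$values, fixed$values)
})

test_that("sensitivity runs are seed-stable and calibrated", {
  sc <- make_scenario("gaussian_peak",
    years = 1975:2014, amplitude = 800,
    peak_year = 1995, width = 6
  )
  clean <- simulate_clean_table(sc, seq(1995, 2014, 2), 600, seed = 61)
  hists <- initiation_histograms(clean)
  anchor <- calibration_anchor(2010, 50000)

  sens <- duration_sensitivity(hists, c(10, 15),
    anchor = anchor, n_mc = 200,
    seed = 71
  )
  direct <- calibrate(
    combine_surveys(hists, survival_model(15), n_mc = 200, seed = 71),
    anchor,
    seed = 71
  )
  expect_equal(sens[["15"]]$values, direct$values)
  expect_identical(sens[["15"]]$pri, direct$pri)

  # adding a third mu never perturbs the existing runs
  sens3 <- duration_sensitivity(hists, c(10, 15, 20),
    anchor = anchor,
    n_mc = 200, seed = 71
  )
  expect_identical(sens3[["10"]]$pri, sens[["10"]]$pri)
  expect_identical(sens3[["15"]]$pri, sens[["15"]]$pri)

  for (cv in sens3) {
    yrs <- as.integer(names(cv$values))
    past <- yrs <= 2010
    implied <- sum(cv$values[past] *
      surv_prob(survival_model(cv$mu), 2010 - yrs[past]))
    expect_lt(abs(implied / 50000 - 1), 1e-9)
  }
  expect_error(duration_sensitivity(hists, numeric()), "positive")
})

test_that("recent cohorts informed by few surveys have wider intervals", {
  sc <- make_scenario("gaussian_peak",
    years = 1970:2019, amplitude = 1000,
    peak_year = 1995, width = 8
  )
  clean <- simulate_clean_table(sc, 1990:2019, 800, seed = 81)
  cv <- combine_surveys(initiation_histograms(clean), survival_model(15),
    n_mc = 300, seed = 82
  )
  rel_width <- (cv$pri["high", ] - cv$pri["low", ]) / pmax(cv$values, 1e-12)
  yrs <- as.integer(names(cv$values))
  recent <- yrs >= max(yrs) - 2
  well_informed <- cv$n_surveys_informing >= 10
  expect_gt(mean(rel_width[recent]), mean(rel_width[well_informed]))
})

test_that("prediction intervals cover resampling noise at close to nominal rate", {
  sc <- make_scenario("constant", years = 1990:2004, amplitude = 300)
  truth_rate <- sc$rate
  m <- survival_model(15)
  hits <- total <- 0
  hits_sparse <- total_sparse <- 0
  for (r in 1:200) {
    clean <- simulate_clean_table(sc, c(2000, 2004), 500, seed = 1000 + r)
    hists <- initiation_histograms(clean)
    cv <- combine_surveys(hists, m, n_mc = 200, seed = 2000 + r)
    yrs <- names(cv$values)
    truth <- truth_rate[yrs] / sum(truth_rate[yrs])
    # expected observed count per cohort, maximised over the two surveys
    yrs_all <- as.integer(names(truth_rate))
    exp_count <- vapply(as.integer(yrs), function(c) {
      max(vapply(unique(hists$survey_year), function(t) {
        if (c > t) return(0)
        w <- truth_rate * surv_prob(m, pmax(t - yrs_all, 0))
        w[yrs_all > t] <- 0
        500 * w[[as.character(c)]] / sum(w)
      }, numeric(1)))
    }, numeric(1))
    in_pri <- cv$pri["low", ] <= truth & truth <= cv$pri["high", ]
    dense <- exp_count >= 5
    hits <- hits + sum(in_pri[dense])
    total <- total + sum(dense)
    hits_sparse <- hits_sparse + sum(in_pri[!dense])
    total_sparse <- total_sparse + sum(!dense)
  }
  coverage <- hits / total
  expect_gte(coverage, 0.85)
  expect_lte(coverage, 1)
  if (total_sparse > 0) expect_gte(hits_sparse / total_sparse, 0.5)
})
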