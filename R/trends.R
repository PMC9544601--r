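#' Fit quantile trends against calendar year
#'
#' Estimates conditional quantiles of an outcome (age, age at first
#' injection, or injecting duration) as a quadratic function of calendar
#' year, by minimising the pinball (check) loss
#' `rho_tau(u) = u * (tau - 1[u < 0])` for each quantile level over
#' `b0 + b1 * y + b2 * y^2`, where `y` is the year centred at the midpoint of
#' its observed range (for numerical conditioning; fitted values are
#' unaffected). Fitting uses [quantreg::rq()]. Reported values for a given
#' year are the model's fitted quantiles at that year, so small survey years
#' borrow strength from the smooth trend. Fitted quantiles are sorted within
#' each year so the reported quartiles never cross.
#'
#' @param table clean survey-record tibble.
#' @param outcome column name: `"age"`, `"age_first_inj"` or `"duration"`.
#' @param taus quantile levels in (0, 1); default quartiles.
#' @param strata optional column name to stratify by (e.g. `"region"`); each
#'   stratum is fitted separately with the same quadratic form.
#' @param year_var time axis, `"survey_year"` by default (use
#'   `"year_first_inj"` for trends by year of initiation).
#' @param ci if `TRUE`, percentile bootstrap confidence intervals for the
#'   fitted quantiles (records resampled with replacement and the model
#'   refitted).
#' @param n_boot bootstrap resamples (default 200).
#' @param seed seed for the bootstrap (required when `ci = TRUE`).
#' @param min_stratum strata with fewer records are skipped with a warning.
#' @return An object of class `quantile_trend`: list with `fitted` (tibble
#'   `outcome, stratum, tau, year, fitted, ci_low, ci_high`) and
#'   `coefficients` (tibble `stratum, tau, intercept, linear, quadratic`,
#'   on the centred-year scale, with the midpoint in column `year_mid`).
#' @export
fit_quantile_trend <- function(table, outcome, taus = c(0.25, 0.5, 0.75),
                               strata = NULL, year_var = "survey_year",
                               ci = FALSE, n_boot = 200, seed = NULL,
                               min_stratum = 30) {
  stopifnot(outcome %in% names(table), year_var %in% names(table))
  if (any(taus <= 0 | taus >= 1)) stop("'taus' must lie in (0, 1)")
  if (ci && is.null(seed)) stop("'seed' is required when ci = TRUE")
  groups <- if (is.null(strata)) {
    list("all" = table)
  } else {
    split(table, table[[strata]])
  }
  fitted_out <- list()
  coef_out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    d <- d[!is.na(d[[outcome]]) & !is.na(d[[year_var]]), ]
    if (nrow(d) < min_stratum) {
      warning(sprintf(
        "stratum '%s' has %d records (< %d); skipped", g, nrow(d), min_stratum
      ))
      next
    }
    res <- fit_one_stratum(d, outcome, taus, year_var, ci, n_boot,
      seed = if (ci) child_seed(seed, "boot", g) else NULL
    )
    res$fitted$stratum <- g
    res$coefficients$stratum <- g
    fitted_out[[g]] <- res$fitted
    coef_out[[g]] <- res$coefficients
  }
  if (length(fitted_out) == 0) stop("no stratum met the minimum size")
  structure(
    list(
      fitted = dplyr::bind_rows(fitted_out)[, c(
        "outcome", "stratum", "tau", "year", "fitted", "ci_low", "ci_high"
      )],
      coefficients = dplyr::bind_rows(coef_out)[, c(
        "stratum", "tau", "year_mid", "intercept", "linear", "quadratic"
      )],
      outcome = outcome, year_var = year_var, taus = sort(taus)
    ),
    class = "quantile_trend"
  )
}

fit_one_stratum <- function(d, outcome, taus, year_var, ci, n_boot, seed) {
  yrs <- sort(unique(d[[year_var]]))
  mid <- mean(range(yrs))
  yc <- d[[year_var]] - mid
  yv <- d[[outcome]]
  taus <- sort(taus)
  fit_coefs <- function(y_out, y_cen) {
    if (length(unique(y_out)) == 1) {
      # degenerate outcome: flat fit at the common value
      matrix(c(y_out[1], 0, 0),
        nrow = 3, ncol = length(taus),
        dimnames = list(c("b0", "b1", "b2"), taus)
      )
    } else {
      f <- suppressWarnings(
        quantreg::rq(y_out ~ y_cen + I(y_cen^2), tau = taus)
      )
      cm <- matrix(coef(f), nrow = 3)
      dimnames(cm) <- list(c("b0", "b1", "b2"), taus)
      cm
    }
  }
  cm <- fit_coefs(yv, yc)
  predict_years <- function(cmat) {
    x <- cbind(1, yrs - mid, (yrs - mid)^2)
    fv <- x %*% cmat # years x taus
    t(apply(fv, 1, sort)) # enforce non-crossing within year
  }
  fv <- predict_years(cm)
  ci_lo <- ci_hi <- matrix(NA_real_, nrow = length(yrs), ncol = length(taus))
  if (ci) {
    set.seed(seed)
    boots <- array(NA_real_, c(length(yrs), length(taus), n_boot))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(yv), replace = TRUE)
      boots[, , b] <- predict_years(fit_coefs(yv[idx], yc[idx]))
    }
    ci_lo <- apply(boots, c(1, 2), quantile, probs = 0.025)
    ci_hi <- apply(boots, c(1, 2), quantile, probs = 0.975)
  }
  fitted <- tibble::tibble(
    outcome = outcome,
    tau = rep(taus, each = length(yrs)),
    year = rep(yrs, length(taus)),
    fitted = as.vector(fv),
    ci_low = as.vector(ci_lo),
    ci_high = as.vector(ci_hi)
  )
  coefficients <- tibble::tibble(
    tau = taus, year_mid = mid,
    intercept = cm["b0", ], linear = cm["b1", ], quadratic = cm["b2", ]
  )
  list(fitted = fitted, coefficients = coefficients)
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat(sprintf(
    "<quantile_trend> outcome '%s' vs %s; taus %s; %d strata\n",
    x$outcome, x$year_var, paste(x$taus, collapse = "/"),
    length(unique(x$fitted$stratum))
  ))
  print(x$fitted, n = 6)
  invisible(x)
}

#' Restrict to participants who started injecting recently
#'
#' Keeps records with `0 <= survey_year - year_first_inj < window`. Analyses
#' of age at first injection by year of initiation use this window because
#' participants surveyed many years after starting are survivors of their
#' cohort — with age-related attrition they are biased toward those who
#' started young. The default 3-year window means an initiation year of 2000
#' draws on surveys from 2000-2002.
#'
#' @param table clean survey-record tibble.
#' @param window positive integer number of years.
#' @return The filtered tibble, for trend fitting against `year_first_inj`.
#' @export
recent_initiates <- function(table, window = 3) {
  if (window < 1) stop("'window' must be >= 1")
  gap <- table$survey_year - table$year_first_inj
  table[!is.na(gap) & gap >= 0 & gap < window, , drop = FALSE]
}

#' Tabulate initiation-year distributions by survey year
#'
#' Counts, within each survey year (and optional stratum), the reported year
#' of first injection. These histograms are the raw material of the
#' back-calculation: a survey's distribution of initiation years is the true
#' cohort-size curve filtered by survivorship.
#'
#' @param table clean survey-record tibble.
#' @param strata optional column name to stratify by.
#' @return A tibble `survey_year, stratum, init_year, count` with one row per
#'   observed (survey year, initiation year) pair; per-survey totals equal
#'   the clean table's row counts.
#' @export
initiation_histograms <- function(table, strata = NULL) {
  g <- tibble::tibble(
    survey_year = table$survey_year,
    stratum = if (is.null(strata)) "all" else as.character(table[[strata]]),
    init_year = table$year_first_inj
  )
  dplyr::count(g, .data$survey_year, .data$stratum, .data$init_year,
    name = "count"
  )
}

#' Modal initiation year and duration per survey year
#'
#' @param hists histogram tibble from [initiation_histograms()].
#' @return Tibble `survey_year, stratum, modal_init_year, modal_duration,
#'   total`; modes are `NA` for empty survey years. Ties take the earliest
#'   initiation year.
#' @export
initiation_modes <- function(hists) {
  if (nrow(hists) == 0) {
    return(tibble::tibble(
      survey_year = integer(), stratum = character(),
      modal_init_year = integer(), modal_duration = integer(),
      total = integer()
    ))
  }
  dplyr::summarise(
    dplyr::group_by(hists, .data$survey_year, .data$stratum),
    modal_init_year = .data$init_year[which.max(.data$count)],
    modal_duration = .data$survey_year[1] - modal_init_year,
    total = sum(.data$count),
    .groups = "drop"
  )
}
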