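#' Exponential cessation (survival) model
#'
#' People are assumed to leave the injecting population (through cessation or
#' death) with a constant hazard, so the probability of still injecting `d`
#' years after first injection is `S(d) = exp(-d / mu)`. The mean duration
#' `mu` is an assumption, not estimated from the data; 15 years is the
#' primary value, with 10-20 years explored in sensitivity analyses.
#'
#' @param mu mean injecting duration in years, > 0.
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(mu = 15) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu <= 0) {
    stop("'mu' must be a positive number")
  }
  structure(list(mu = mu), class = "survival_model")
}

#' Survival probability at integer years since initiation
#'
#' @param model a [survival_model()].
#' @param d years since first injection (non-negative).
#' @return `exp(-d / mu)`, vectorised over `d`.
#' @export
surv_prob <- function(model, d) {
  stopifnot(inherits(model, "survival_model"))
  if (any(d < 0)) stop("'d' must be non-negative")
  exp(-d / model$mu)
}

#' Expected initiation histogram implied by a cohort curve
#'
#' The forward map of the back-calculation: a survey in year `t` of people
#' currently injecting observes cohort `c` in proportion to
#' `N(c) * S(t - c)`. Used to generate noise-free histograms from a known
#' curve, e.g. to verify that inversion recovers it.
#'
#' @param values named numeric vector: cohort year -> N(c), non-negative.
#' @param survey_year integer survey year `t`; must be >= all cohort years.
#' @param model a [survival_model()].
#' @param total optional; rescale counts to this total.
#' @return Histogram tibble `survey_year, stratum, init_year, count` (counts
#'   real-valued, zero-expectation cohorts omitted).
#' @export
expected_initiation_histogram <- function(values, survey_year, model,
                                          total = NULL) {
  yrs <- as.integer(names(values))
  if (any(yrs > survey_year)) stop("cohort years must not exceed survey_year")
  counts <- unname(values) * surv_prob(model, survey_year - yrs)
  if (!is.null(total)) counts <- counts * total / sum(counts)
  keep <- counts > 0
  tibble::tibble(
    survey_year = as.integer(survey_year), stratum = "all",
    init_year = yrs[keep], count = counts[keep]
  )
}

new_cohort_curve <- function(values, scale, mu, pri = NULL,
                             n_surveys_informing = NULL, replicates = NULL) {
  structure(
    list(
      values = values, scale = scale, mu = mu, pri = pri,
      n_surveys_informing = n_surveys_informing, replicates = replicates
    ),
    class = "cohort_curve"
  )
}

#' @export
print.cohort_curve <- function(x, ...) {
  cat(sprintf(
    "<cohort_curve> %s, mu = %g; cohorts %s-%s; peak %s%s\n",
    x$scale, x$mu, names(x$values)[1], names(x$values)[length(x$values)],
    names(which.max(x$values)),
    if (is.null(x$pri)) "" else "; with 95% prediction intervals"
  ))
  invisible(x)
}

#' Tidy a cohort curve
#'
#' @param curve a `cohort_curve`.
#' @return Tibble `cohort_year, n_hat, pri_low, pri_high,
#'   n_surveys_informing, mu, scale`.
#' @export
cohort_curve_df <- function(curve) {
  stopifnot(inherits(curve, "cohort_curve"))
  yrs <- as.integer(names(curve$values))
  tibble::tibble(
    cohort_year = yrs,
    n_hat = unname(curve$values),
    pri_low = if (is.null(curve$pri)) NA_real_ else unname(curve$pri[1, ]),
    pri_high = if (is.null(curve$pri)) NA_real_ else unname(curve$pri[2, ]),
    n_surveys_informing = if (is.null(curve$n_surveys_informing)) {
      NA_integer_
    } else {
      unname(curve$n_surveys_informing)
    },
    mu = curve$mu,
    scale = curve$scale
  )
}

# split a histogram tibble into per-survey count vectors, checking stratum
split_hists <- function(hists) {
  stopifnot(all(c("survey_year", "init_year", "count") %in% names(hists)))
  if ("stratum" %in% names(hists) && length(unique(hists$stratum)) > 1) {
    stop("histograms span multiple strata; back-calculate one stratum at a time")
  }
  if (any(hists$init_year > hists$survey_year)) {
    stop("initiation year after survey year in histogram")
  }
  if (any(hists$count < 0)) stop("negative histogram count")
  lapply(split(hists, hists$survey_year), function(h) {
    counts <- tapply(h$count, h$init_year, sum) # aggregate duplicate cells
    list(
      t = h$survey_year[1],
      counts = setNames(as.numeric(counts), names(counts)),
      total = sum(h$count)
    )
  })
}

#' Back-calculate a relative cohort curve from one survey
#'
#' Inverts a single survey's initiation-year histogram through the survival
#' model: the estimated relative cohort size is
#' `N(c) proportional to n_t(c) / S(t - c)`, i.e. observed counts are
#' inflated by the probability that a member of cohort `c` was still
#' injecting when surveyed. Cohorts with zero observed count get estimate 0;
#' no pseudo-count or smoothing is applied at the single-survey level.
#'
#' @param hist histogram tibble (`survey_year, init_year, count`) for a
#'   single survey year; counts may be real-valued (expected counts).
#' @param model a [survival_model()].
#' @param normalise if `TRUE` (default) the curve is scaled to sum to 1;
#'   `FALSE` returns the raw inflated counts (useful for closed-form checks).
#' @return A relative `cohort_curve` over the survey's observed cohort years.
#' @export
backcalc_single <- function(hist, model, normalise = TRUE) {
  stopifnot(inherits(model, "survival_model"))
  hs <- split_hists(hist)
  if (length(hs) != 1) stop("'hist' must contain exactly one survey year")
  h <- hs[[1]]
  if (h$total <= 0) stop("histogram total must be positive")
  yrs <- as.integer(names(h$counts))
  est <- unname(h$counts) / surv_prob(model, h$t - yrs)
  if (normalise) est <- est / sum(est)
  o <- order(yrs)
  new_cohort_curve(
    values = setNames(est[o], yrs[o]),
    scale = "relative", mu = model$mu,
    n_surveys_informing = setNames(rep(1L, length(yrs)), yrs[o])
  )
}

#' Combine evidence from all survey years by Monte Carlo
#'
#' Point estimate: each survey's histogram is inverted as in
#' [backcalc_single()] and normalised over the cohort years that survey can
#' see (at most `d_max` years before it); each cohort's estimate is then the
#' mean of the per-survey relative estimates across all surveys informing it,
#' weighted by survey totals (larger surveys carry more precise
#' proportions), and the combined curve is renormalised to sum to 1.
#'
#' Prediction intervals: each Monte-Carlo replicate redraws every survey's
#' counts from a multinomial with the observed total and proportions,
#' re-inverts and re-combines; the interval is the 2.5th-97.5th percentile of
#' the replicates per cohort. Cohorts seen by few surveys (especially the
#' most recent years) therefore get wide intervals. The random stream is
#' derived from `(seed, mu)`, so sensitivity runs over several `mu` values
#' with one master seed are mutually independent and individually
#' reproducible.
#'
#' @param hists histogram tibble from [initiation_histograms()] (one
#'   stratum), covering one or more survey years.
#' @param model a [survival_model()].
#' @param n_mc number of Monte-Carlo replicates (0 disables intervals).
#' @param seed master integer seed; required when `n_mc > 0`.
#' @param d_max cohorts more than `d_max` years before a survey are invisible
#'   to it; default `ceiling(5 * mu)`, beyond which `S(d) < exp(-5)` and the
#'   inflation factor is numerically explosive.
#' @param smooth if `TRUE`, add half a count to every cohort a survey covers
#'   before inverting (off by default; the default estimator is transparent).
#' @return A relative `cohort_curve` with `pri` (if `n_mc > 0`),
#'   `n_surveys_informing`, and the replicate matrix retained for downstream
#'   calibration.
#' @export
combine_surveys <- function(hists, model, n_mc = 1000, seed = NULL,
                            d_max = ceiling(5 * model$mu), smooth = FALSE) {
  stopifnot(inherits(model, "survival_model"))
  if (n_mc > 0 && n_mc < 100) stop("'n_mc' must be 0 or >= 100")
  if (n_mc > 0 && is.null(seed)) stop("'seed' is required when n_mc > 0")
  hs <- split_hists(hists)
  if (length(hs) == 0) stop("no histograms supplied")

  first_obs <- min(vapply(
    hs, function(h) min(as.integer(names(h$counts))), 1
  ))
  last_t <- max(vapply(hs, function(h) h$t, 1))
  support <- first_obs:last_t
  # which surveys inform each cohort year: c <= t and t - c <= d_max
  informs <- vapply(hs, function(h) {
    support <= h$t & h$t - support <= d_max
  }, logical(length(support)))
  informs <- matrix(informs, nrow = length(support))
  n_informing <- rowSums(informs)
  keep <- n_informing >= 1
  support <- support[keep]
  informs <- informs[keep, , drop = FALSE]
  n_informing <- n_informing[keep]

  # per-survey inversion: counts over its covered support -> relative curve
  invert_one <- function(h, counts_on_support, covered) {
    est <- numeric(length(support))
    s <- surv_prob(model, pmax(h$t - support, 0))
    cnt <- counts_on_support
    if (smooth) cnt[covered] <- cnt[covered] + 0.5
    est[covered] <- cnt[covered] / s[covered]
    tot <- sum(est[covered])
    if (tot > 0) est[covered] <- est[covered] / tot
    est
  }
  counts_matrix <- vapply(hs, function(h) {
    v <- numeric(length(support))
    idx <- match(as.integer(names(h$counts)), support)
    ok <- !is.na(idx)
    v[idx[ok]] <- unname(h$counts)[ok]
    v
  }, numeric(length(support)))
  counts_matrix <- matrix(counts_matrix, nrow = length(support))

  weights <- vapply(hs, function(h) h$total, numeric(1))
  combine_once <- function(cm) {
    ests <- vapply(seq_along(hs), function(j) {
      invert_one(hs[[j]], cm[, j], informs[, j])
    }, numeric(length(support)))
    ests <- matrix(ests, nrow = length(support))
    num <- as.vector(ests %*% weights) # informs handled via zero estimates
    den <- as.vector(informs %*% weights)
    point <- ifelse(den > 0, num / den, 0)
    point / sum(point)
  }
  point <- combine_once(counts_matrix)

  pri <- NULL
  replicates <- NULL
  if (n_mc > 0) {
    set.seed(child_seed(seed, "combine", format(model$mu)))
    draws <- lapply(seq_along(hs), function(j) {
      h <- hs[[j]]
      p <- counts_matrix[, j]
      if (sum(p) == 0 || h$total == 0) {
        matrix(0, length(support), n_mc)
      } else {
        rmultinom(n_mc, round(h$total), p / sum(p))
      }
    })
    replicates <- vapply(seq_len(n_mc), function(b) {
      cm <- vapply(
        seq_along(hs), function(j) draws[[j]][, b],
        numeric(length(support))
      )
      combine_once(matrix(cm, nrow = length(support)))
    }, numeric(length(support)))
    replicates <- matrix(replicates,
      nrow = length(support),
      dimnames = list(support, NULL)
    )
    pri <- apply(replicates, 1, quantile, probs = c(0.025, 0.975))
    dimnames(pri) <- list(c("low", "high"), support)
  }
  new_cohort_curve(
    values = setNames(point, support),
    scale = "relative", mu = model$mu, pri = pri,
    n_surveys_informing = setNames(as.integer(n_informing), support),
    replicates = replicates
  )
}

#' External prevalence anchor for absolute calibration
#'
#' @param ref_year calendar year of the prevalence estimate.
#' @param prevalence estimated number currently injecting in `ref_year`.
#' @param source free-text citation for the estimate.
#' @param prevalence_low,prevalence_high optional interval for the anchor;
#'   when supplied, calibration propagates anchor uncertainty into the
#'   prediction intervals by drawing a uniform prevalence per Monte-Carlo
#'   replicate.
#' @return An object of class `calibration_anchor`.
#' @export
calibration_anchor <- function(ref_year, prevalence, source = "",
                               prevalence_low = NULL, prevalence_high = NULL) {
  if (prevalence <= 0) stop("'prevalence' must be positive")
  if (!is.null(prevalence_low) || !is.null(prevalence_high)) {
    if (is.null(prevalence_low) || is.null(prevalence_high) ||
      prevalence_low > prevalence || prevalence_high < prevalence) {
      stop("anchor interval must satisfy low <= prevalence <= high")
    }
  }
  structure(
    list(
      ref_year = as.integer(ref_year), prevalence = prevalence,
      source = source, prevalence_low = prevalence_low,
      prevalence_high = prevalence_high
    ),
    class = "calibration_anchor"
  )
}

#' Calibrate a relative cohort curve to an external prevalence estimate
#'
#' A relative curve fixes only the shape of the initiation history. An
#' external estimate of the number currently injecting in a reference year
#' `t*` pins the scale: the curve is multiplied by
#' `k = P / sum_{c <= t*} N(c) * S(t* - c)` so that the number still
#' injecting at `t*` implied by the calibrated curve equals the anchor
#' prevalence exactly. Point estimate and prediction-interval bounds are
#' scaled by the same `k`; if the anchor carries an interval and Monte-Carlo
#' replicates are available, each replicate instead receives its own `k`
#' computed from a uniform draw between the anchor bounds, so anchor
#' uncertainty widens the intervals.
#'
#' @param curve a relative `cohort_curve`.
#' @param anchor a [calibration_anchor()].
#' @param model a [survival_model()]; defaults to the one the curve was
#'   built with.
#' @param seed seed for anchor-interval draws (only used when the anchor has
#'   an interval and the curve has replicates).
#' @return An absolute `cohort_curve` (persons per year).
#' @export
calibrate <- function(curve, anchor, model = survival_model(curve$mu),
                      seed = NULL) {
  stopifnot(
    inherits(curve, "cohort_curve"), inherits(anchor, "calibration_anchor"),
    inherits(model, "survival_model")
  )
  if (curve$scale != "relative") stop("'curve' must be on the relative scale")
  yrs <- as.integer(names(curve$values))
  if (anchor$ref_year < min(yrs)) {
    stop("anchor year precedes all cohort years")
  }
  past <- yrs <= anchor$ref_year
  implied <- function(v) {
    sum(v[past] * surv_prob(model, anchor$ref_year - yrs[past]))
  }
  p0 <- implied(curve$values)
  if (p0 <= 0) stop("implied prevalence at the anchor year is zero")
  k <- anchor$prevalence / p0
  values <- curve$values * k
  pri <- if (!is.null(curve$pri)) curve$pri * k else NULL
  replicates <- if (!is.null(curve$replicates)) curve$replicates * k else NULL
  has_interval <- !is.null(anchor$prevalence_low)
  if (has_interval && !is.null(curve$replicates)) {
    n_mc <- ncol(curve$replicates)
    set.seed(child_seed(seed %||% 0, "anchor", anchor$ref_year))
    p_draw <- runif(n_mc, anchor$prevalence_low, anchor$prevalence_high)
    k_b <- p_draw / apply(curve$replicates, 2, implied)
    replicates <- sweep(curve$replicates, 2, k_b, `*`)
    pri <- apply(replicates, 1, quantile, probs = c(0.025, 0.975))
    dimnames(pri) <- list(c("low", "high"), names(curve$values))
  } else if (has_interval) {
    warning("anchor interval ignored: curve has no Monte-Carlo replicates")
  }
  new_cohort_curve(
    values = values, scale = "absolute", mu = curve$mu, pri = pri,
    n_surveys_informing = curve$n_surveys_informing, replicates = replicates
  )
}

#' Sensitivity of the initiation curve to the assumed mean duration
#'
#' Re-runs [combine_surveys()] (and, if an anchor is given, [calibrate()])
#' once per assumed mean duration. Shorter assumed durations inflate the
#' estimated size of early cohorts relative to recent ones, and longer
#' durations do the opposite, because the inversion weight `1 / S(t - c)`
#' grows faster in `t - c` when `mu` is small. All runs share one master
#' seed; each `mu` draws an independent child stream, so adding a value to
#' `mus` never changes the others' results.
#'
#' @param hists histogram tibble (one stratum).
#' @param mus vector of mean durations to try, all > 0.
#' @param anchor optional [calibration_anchor()] for absolute curves.
#' @param n_mc Monte-Carlo replicates per run.
#' @param seed master integer seed.
#' @return Named list of `cohort_curve`s, one per `mu` (names like `"15"`).
#' @export
duration_sensitivity <- function(hists, mus, anchor = NULL, n_mc = 1000,
                                 seed = NULL) {
  if (length(mus) == 0 || any(mus <= 0)) stop("'mus' must be positive")
  out <- lapply(mus, function(mu) {
    cv <- combine_surveys(hists, survival_model(mu), n_mc = n_mc, seed = seed)
    if (!is.null(anchor)) cv <- calibrate(cv, anchor, seed = seed)
    cv
  })
  setNames(out, format(mus, trim = TRUE))
}
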