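#' Configuration for a full pipeline run
#'
#' Bundles every analysis setting. The defaults are the primary analysis
#' settings: mean duration 15 years, a 3-year recency window for age at
#' first injection, quartile trends, and a 10-20-year duration sensitivity
#' grid.
#'
#' @param seed master integer seed for every random stage.
#' @param recency_mode recency rule for [apply_exclusions()].
#' @param taus quantile levels for trend fits.
#' @param window recency window (years) for [recent_initiates()].
#' @param mu primary mean injecting duration (years).
#' @param mus_sensitivity mean durations for [duration_sensitivity()].
#' @param n_mc Monte-Carlo replicates for prediction intervals (0 disables).
#' @param anchors `NULL`, a single [calibration_anchor()], or a named list
#'   mapping stratum label to anchor (name `"all"` for unstratified runs).
#' @param strata optional column name to stratify trends and incidence by.
#' @param ci if `TRUE`, bootstrap confidence intervals for trend fits.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, recency_mode = "strict",
                       taus = c(0.25, 0.5, 0.75), window = 3, mu = 15,
                       mus_sensitivity = c(10, 12.5, 15, 17.5, 20),
                       n_mc = 1000, anchors = NULL, strata = NULL,
                       ci = FALSE) {
  if (inherits(anchors, "calibration_anchor")) anchors <- list(all = anchors)
  if (!is.null(anchors)) {
    stopifnot(all(vapply(anchors, inherits, TRUE, "calibration_anchor")))
  }
  structure(
    list(
      seed = as.integer(seed), recency_mode = recency_mode, taus = taus,
      window = as.integer(window), mu = mu,
      mus_sensitivity = mus_sensitivity, n_mc = as.integer(n_mc),
      anchors = anchors, strata = strata, ci = isTRUE(ci)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; `anchors` is a named map of
#' stratum label to `{ref_year, prevalence, source, prevalence_low,
#' prevalence_high}`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- read_config_file(path)
  if (!is.null(cfg$anchors)) {
    cfg$anchors <- lapply(cfg$anchors, function(a) {
      do.call(calibration_anchor, a)
    })
  }
  do.call(run_config, cfg)
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a synthetic-scenario configuration from YAML or JSON
#'
#' The file has two maps: `scenario` (arguments of [make_scenario()], with
#' `years` given as `[first, last]`) and `design` (arguments of
#' [survey_design()], with `corruption` as a nested map of
#' [corruption_params()] arguments). A missing design seed inherits the
#' run seed at pipeline time.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `scenario` (an `initiation_scenario`) and
#'   `design_args` (list, for [survey_design()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$scenario)) stop("scenario config lacks a 'scenario' map")
  sc_args <- cfg$scenario
  if (!is.null(sc_args$years) && length(sc_args$years) == 2) {
    sc_args$years <- sc_args$years[1]:sc_args$years[2]
  }
  scenario <- do.call(make_scenario, sc_args)
  design_args <- cfg$design %||% list()
  if (!is.null(design_args$corruption)) {
    design_args$corruption <- do.call(corruption_params, design_args$corruption)
  }
  list(scenario = scenario, design_args = design_args)
}

#' Run the full pipeline and write an output bundle
#'
#' Orchestrates simulate (for scenario inputs) - clean - quantile trends -
#' initiation histograms - incidence back-calculation - duration
#' sensitivity, writing every product to `output_dir`:
#'
#' * `survey.csv`, `truth.json` - simulated records and the true initiation
#'   curve (scenario inputs only);
#' * `clean.csv`, `exclusion_log.json` - cleaned table and Figure-1-style
#'   exclusion accounting;
#' * `trend_age.csv`, `trend_duration.csv` - quartiles by survey year;
#' * `trend_age_first_inj.csv` - quartiles of age at first injection by year
#'   of initiation, restricted to recent initiates;
#' * `histograms.csv`, `modes.csv` - initiation-year distributions;
#' * `incidence.csv` - back-calculated cohort curve at the primary `mu`
#'   (absolute where an anchor is configured, else relative);
#' * `sensitivity.csv` - the same across `mus_sensitivity`;
#' * `manifest.json` - configuration, input description and package version;
#'   rerunning with this manifest reproduces the bundle byte for byte.
#'
#' Progress and the exclusion accounting are logged to stderr. On error,
#' files already written to a previously non-existing `output_dir` are
#' removed.
#'
#' @param input path to a participant CSV ([read_survey_csv()] schema), or a
#'   path to / list from [read_scenario_config()].
#' @param config a [run_config()].
#' @param output_dir directory for the bundle (created if absent).
#' @return Invisibly, a list with the principal in-memory objects
#'   (`clean`, `log`, `trends`, `hists`, `incidence`, `sensitivity`).
#' @export
run_pipeline <- function(input, config = run_config(), output_dir) {
  stopifnot(inherits(config, "run_config"))
  fresh_dir <- !dir.exists(output_dir)
  if (fresh_dir) dir.create(output_dir, recursive = TRUE)
  written <- character()
  out_path <- function(name) {
    p <- file.path(output_dir, name)
    written <<- c(written, p)
    p
  }
  tryCatch(
    run_pipeline_impl(input, config, out_path),
    error = function(e) {
      unlink(written)
      if (fresh_dir) unlink(output_dir, recursive = TRUE)
      stop(e)
    }
  )
}

run_pipeline_impl <- function(input, config, out_path) {
  inf <- function(...) message(sprintf(...))

  # --- input stage: read survey CSV, or simulate from a scenario ----------
  truth <- NULL
  if (is.character(input) && grepl("\\.csv$", input, ignore.case = TRUE)) {
    raw <- read_survey_csv(input)
    input_desc <- list(type = "survey_csv", path = input)
    inf("read %d records from %s", nrow(raw), input)
  } else {
    sc <- if (is.character(input)) read_scenario_config(input) else input
    stopifnot(inherits(sc$scenario, "initiation_scenario"))
    da <- sc$design_args
    da$seed <- da$seed %||% config$seed
    da$corruption <- da$corruption %||% corruption_params()
    design <- do.call(survey_design, da)
    pop <- simulate_population(sc$scenario,
      mu = config$mu,
      seed = child_seed(config$seed, "population")
    )
    raw <- simulate_surveys(pop, design)
    truth <- list(
      rate = as.list(sc$scenario$rate),
      relative = as.list(scenario_relative_curve(sc$scenario)),
      mu = config$mu
    )
    input_desc <- list(
      type = "scenario",
      path = if (is.character(input)) input else "in-memory scenario"
    )
    write_survey_csv(raw, out_path("survey.csv"))
    jsonlite::write_json(truth, out_path("truth.json"),
      auto_unbox = TRUE, digits = NA
    )
    inf("simulated %d records across %d surveys", nrow(raw),
      length(design$survey_years))
  }

  # --- cleaning ------------------------------------------------------------
  derived <- derive_fields(raw)
  cleaned <- apply_exclusions(derived, recency_mode = config$recency_mode)
  clean <- cleaned$clean
  log <- cleaned$log
  for (k in names(log)) inf("exclusion log: %s = %d", k, log[[k]])
  write_survey_csv(clean, out_path("clean.csv"))
  jsonlite::write_json(unclass(log), out_path("exclusion_log.json"),
    auto_unbox = TRUE
  )

  # --- quantile trends -----------------------------------------------------
  trends <- list()
  for (outc in c("age", "duration")) {
    tr <- fit_quantile_trend(clean, outc,
      taus = config$taus,
      strata = config$strata, ci = config$ci, seed = config$seed
    )
    trends[[outc]] <- tr
    write.csv(tr$fitted, out_path(paste0("trend_", outc, ".csv")),
      row.names = FALSE, na = ""
    )
  }
  recent <- recent_initiates(clean, window = config$window)
  tr_init <- fit_quantile_trend(recent, "age_first_inj",
    taus = config$taus,
    strata = config$strata, year_var = "year_first_inj",
    ci = config$ci, seed = config$seed
  )
  trends$age_first_inj <- tr_init
  write.csv(tr_init$fitted, out_path("trend_age_first_inj.csv"),
    row.names = FALSE, na = ""
  )
  inf("fitted quantile trends on %d clean records (%d recent initiates)",
    nrow(clean), nrow(recent))

  # --- initiation histograms ----------------------------------------------
  hists <- initiation_histograms(clean, strata = config$strata)
  write.csv(hists, out_path("histograms.csv"), row.names = FALSE)
  write.csv(initiation_modes(hists), out_path("modes.csv"), row.names = FALSE)

  # --- incidence back-calculation and sensitivity -------------------------
  strata_levels <- unique(hists$stratum)
  incidence_rows <- list()
  sensitivity_rows <- list()
  for (st in strata_levels) {
    h_st <- hists[hists$stratum == st, ]
    anchor <- resolve_anchor(config$anchors, st)
    curves <- duration_sensitivity(h_st,
      mus = unique(c(config$mu, config$mus_sensitivity)),
      anchor = anchor, n_mc = config$n_mc, seed = config$seed
    )
    for (nm in names(curves)) {
      df <- cohort_curve_df(curves[[nm]])
      df$stratum <- st
      if (curves[[nm]]$mu == config$mu) incidence_rows[[paste(st, nm)]] <- df
      sensitivity_rows[[paste(st, nm)]] <- df
    }
    inf("back-calculated stratum '%s' (%s scale)", st,
      if (is.null(anchor)) "relative" else "absolute")
  }
  cols <- c(
    "stratum", "mu", "cohort_year", "n_hat", "pri_low", "pri_high",
    "n_surveys_informing"
  )
  incidence <- dplyr::bind_rows(incidence_rows)[, cols]
  sensitivity <- dplyr::bind_rows(sensitivity_rows)[, cols]
  write.csv(incidence, out_path("incidence.csv"), row.names = FALSE, na = "")
  write.csv(sensitivity, out_path("sensitivity.csv"),
    row.names = FALSE, na = ""
  )

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "injectcohort",
    version = as.character(utils::packageVersion("injectcohort")),
    input = input_desc,
    config = serialise_config(config)
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    clean = clean, log = log, trends = trends, hists = hists,
    incidence = incidence, sensitivity = sensitivity, truth = truth
  ))
}

resolve_anchor <- function(anchors, stratum) {
  if (is.null(anchors)) return(NULL)
  anchors[[stratum]] %||% if (length(anchors) == 1 && is.null(names(anchors))) {
    anchors[[1]]
  } else {
    NULL
  }
}

serialise_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$anchors)) {
    out$anchors <- lapply(out$anchors, function(a) {
      Filter(Negate(is.null), unclass(a))
    })
  }
  Filter(Negate(is.null), out)
}
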