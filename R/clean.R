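SURVEY_SCHEMA <- c(
  "survey", "survey_year", "region", "sex", "age", "age_first_inj",
  "year_first_inj", "duration", "recent_inj", "psychoactive"
)

#' Read a participant-level survey CSV
#'
#' The file must carry the exact header
#' `survey,survey_year,region,sex,age,age_first_inj,year_first_inj,duration,recent_inj,psychoactive`
#' (an optional extra `last_inj_year` column is accepted for the
#' year-of-last-injection recency dialect). Empty strings are missing values;
#' `recent_inj` and `psychoactive` are coded 1 / 0 / empty for
#' yes / no / unknown.
#'
#' @param path path to a CSV file.
#' @return A tibble with typed columns; integer years and ages, `NA` for
#'   missing.
#' @export
read_survey_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  extra <- setdiff(header, c(SURVEY_SCHEMA, "last_inj_year"))
  if (!identical(header[seq_along(SURVEY_SCHEMA)], SURVEY_SCHEMA) ||
    length(extra) > 0) {
    stop(
      "malformed survey CSV header; expected columns ",
      paste(SURVEY_SCHEMA, collapse = ","), call. = FALSE
    )
  }
  d <- read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  int_cols <- intersect(
    c(
      "survey_year", "age", "age_first_inj", "year_first_inj", "duration",
      "recent_inj", "psychoactive", "last_inj_year"
    ),
    names(d)
  )
  for (cl in int_cols) {
    v <- d[[cl]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf(
        "column '%s' is not numeric (e.g. row %d: '%s')",
        cl, bad[1], v[bad[1]]
      ), call. = FALSE)
    }
    d[[cl]] <- as.integer(v)
  }
  if (anyNA(d$survey_year)) {
    stop(sprintf(
      "missing survey_year at row(s) %s",
      paste(utils::head(which(is.na(d$survey_year)), 5), collapse = ", ")
    ), call. = FALSE)
  }
  d$survey <- as.character(d$survey)
  d$region <- as.character(d$region)
  d$sex <- as.character(d$sex)
  tibble::as_tibble(d)
}

#' Write a participant-level survey CSV
#'
#' Inverse of [read_survey_csv()]: missing values become empty strings.
#'
#' @param table survey-record tibble.
#' @param path output path.
#' @export
write_survey_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Derive missing variables from the ones observed
#'
#' Uses the identities `duration = age - age_first_inj` and
#' `year_first_inj = survey_year - duration` to fill any of `age`,
#' `age_first_inj`, `year_first_inj`, `duration` computable from the others.
#' When duration is derivable both from ages and from years, the age
#' difference is preferred (ages are the primary questionnaire items).
#' Observed values are never overwritten; rows where nothing is derivable are
#' returned unchanged. Records that remain incomplete are handled later by
#' [apply_exclusions()].
#'
#' @param table survey-record tibble with non-missing `survey_year`.
#' @return The table with derivable fields filled in.
#' @examples
#' derive_fields(tibble::tibble(
#'   survey = "x", survey_year = 2019L, region = NA, sex = NA,
#'   age = 40L, age_first_inj = 22L, year_first_inj = NA_integer_,
#'   duration = NA_integer_, recent_inj = 1L, psychoactive = 1L
#' ))
#' @export
derive_fields <- function(table) {
  stopifnot(all(c("survey_year", "age", "age_first_inj", "year_first_inj",
    "duration") %in% names(table)))
  if (anyNA(table$survey_year)) stop("survey_year must be non-missing")
  repeat {
    filled <- FALSE
    fill <- function(cur, new) {
      i <- is.na(cur) & !is.na(new)
      if (any(i)) {
        cur[i] <- new[i]
        filled <<- TRUE
      }
      cur
    }
    table$duration <- fill(table$duration, table$age - table$age_first_inj)
    table$duration <- fill(table$duration, table$survey_year - table$year_first_inj)
    table$age_first_inj <- fill(table$age_first_inj, table$age - table$duration)
    table$age <- fill(table$age, table$age_first_inj + table$duration)
    table$year_first_inj <- fill(table$year_first_inj, table$survey_year - table$duration)
    if (!filled) break
  }
  table
}

#' Apply the exclusion cascade and produce an auditable log
#'
#' Removes records in a fixed order, counting each record once at the first
#' rule it violates:
#'
#' 1. **Not recent**: `recent_inj` is "no", or "unknown" unless retained by
#'    `recency_mode` (see below).
#' 2. **Performance-only**: `psychoactive` is "no" (image-and-performance-
#'    enhancing drugs only). Records with `psychoactive` unknown are retained,
#'    matching surveys that lack the question.
#' 3. **Insufficient data**: any of `age`, `age_first_inj`, `year_first_inj`,
#'    `duration` still missing after [derive_fields()].
#' 4. **Implausible**: `age_first_inj > age`, `year_first_inj > survey_year`,
#'    `duration < 0`, or `|duration - (survey_year - year_first_inj)| > 1`
#'    (ages and years are reported at whole-year granularity, so a one-year
#'    arithmetic slack is allowed before declaring a record inconsistent).
#'
#' `recency_mode` controls how "unknown" recency is treated:
#' * `"strict"` — dropped;
#' * `"assume_recent_pre1993"` — retained when `survey_year <= 1992` (eras
#'   whose questionnaires had no recency item but where ~90% of participants
#'   injected recently);
#' * `"last_inj_year"` — retained when a `last_inj_year` column reports the
#'   survey year or the year before (the 1990s year-of-last-injection
#'   question dialect).
#'
#' @param table survey-record tibble, already passed through
#'   [derive_fields()].
#' @param recency_mode one of `"strict"`, `"assume_recent_pre1993"`,
#'   `"last_inj_year"`.
#' @return A list with `clean` (the retained records) and `log` (an
#'   `exclusion_log`: counts `input`, `excluded_not_recent`,
#'   `excluded_performance_only`, `excluded_insufficient`,
#'   `excluded_implausible`, `retained`, which always reconcile).
#' @export
apply_exclusions <- function(table,
                             recency_mode = c(
                               "strict", "assume_recent_pre1993",
                               "last_inj_year"
                             )) {
  recency_mode <- match.arg(recency_mode)
  n <- nrow(table)
  if (n == 0) {
    log <- exclusion_log(0L, 0L, 0L, 0L, 0L)
    return(list(clean = table, log = log))
  }
  keep_unknown <- switch(recency_mode,
    strict = rep(FALSE, n),
    assume_recent_pre1993 = table$survey_year <= 1992,
    last_inj_year = {
      if (!"last_inj_year" %in% names(table)) {
        stop("recency_mode 'last_inj_year' needs a 'last_inj_year' column")
      }
      !is.na(table$last_inj_year) &
        table$last_inj_year >= table$survey_year - 1
    }
  )
  recent_ok <- ifelse(is.na(table$recent_inj), keep_unknown,
    table$recent_inj == 1L
  )
  not_recent <- !recent_ok
  perf_only <- !not_recent &
    !is.na(table$psychoactive) & table$psychoactive == 0L
  insufficient <- !not_recent & !perf_only &
    (is.na(table$age) | is.na(table$age_first_inj) |
      is.na(table$year_first_inj) | is.na(table$duration))
  implausible <- !not_recent & !perf_only & !insufficient &
    (table$age_first_inj > table$age |
      table$year_first_inj > table$survey_year |
      table$duration < 0 |
      abs(table$duration - (table$survey_year - table$year_first_inj)) > 1)
  retained <- !(not_recent | perf_only | insufficient | implausible)
  log <- exclusion_log(
    input = n,
    excluded_not_recent = sum(not_recent),
    excluded_performance_only = sum(perf_only),
    excluded_insufficient = sum(insufficient),
    excluded_implausible = sum(implausible)
  )
  list(clean = table[retained, , drop = FALSE], log = log)
}

exclusion_log <- function(input, excluded_not_recent,
                          excluded_performance_only, excluded_insufficient,
                          excluded_implausible) {
  log <- list(
    input = as.integer(input),
    excluded_not_recent = as.integer(excluded_not_recent),
    excluded_performance_only = as.integer(excluded_performance_only),
    excluded_insufficient = as.integer(excluded_insufficient),
    excluded_implausible = as.integer(excluded_implausible)
  )
  log$retained <- log$input - log$excluded_not_recent -
    log$excluded_performance_only - log$excluded_insufficient -
    log$excluded_implausible
  stopifnot(all(unlist(log) >= 0))
  structure(log, class = "exclusion_log")
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("<exclusion_log>\n")
  for (k in names(x)) cat(sprintf("  %-26s %d\n", k, x[[k]]))
  invisible(x)
}
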