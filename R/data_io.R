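#' Base-10 log transform of a CA19-9 concentration
#'
#' All analyses in this package work with CA19-9 on the log10 scale, so a
#' coefficient of 1 corresponds to a 10-fold increase in the marker.
#'
#' @param value Numeric vector of CA19-9 concentrations in U/mL. Must be
#'   strictly positive.
#' @return Numeric vector, `log10(value)`.
#' @examples
#' log_ca199(c(1, 1000, 532.5))
#' @export
log_ca199 <- function(value) {
  if (!is.numeric(value)) abort("`value` must be numeric.")
  if (any(!is.finite(value)) || any(value <= 0)) {
    abort("CA19-9 values must be finite and > 0 U/mL.")
  }
  log10(value)
}

# days per month used for every day<->month conversion in the package
DAYS_PER_MONTH <- 30.4375
WEEK_MONTHS <- 7 / DAYS_PER_MONTH

#' Collapse repeated CA19-9 measurements within one week
#'
#' When a patient has several measurements inside a 7-day window, only the
#' first is retained. The window is anchored greedily at each retained
#' measurement: scanning left to right, a measurement is kept when it falls
#' at least 7 days after the last retained one.
#'
#' @param measurements A data frame with columns `patient_id`, `time_months`
#'   and `ca199_u_ml`, sorted by time within patient.
#' @return A tibble with the retained rows, same columns as the input.
#' @examples
#' x <- tibble::tibble(
#'   patient_id = "p1",
#'   time_months = c(0, 3, 10) / 30.4375,
#'   ca199_u_ml = c(100, 120, 150)
#' )
#' dedup_weekly(x) # drops the day-3 measurement
#' @export
dedup_weekly <- function(measurements) {
  measurements <- as_tibble(measurements)
  check_columns(measurements, c("patient_id", "time_months"), "measurements")
  unsorted <- measurements |>
    group_by(.data$patient_id) |>
    summarise(bad = is.unsorted(.data$time_months), .groups = "drop")
  if (any(unsorted$bad)) {
    abort("`measurements` must be sorted by time within each patient.")
  }
  measurements |>
    group_by(.data$patient_id) |>
    filter(keep_weekly(.data$time_months)) |>
    ungroup()
}

# greedy left-to-right scan: keep a time when it is >= 7 days after the last
# retained time
keep_weekly <- function(times) {
  keep <- logical(length(times))
  if (length(times) == 0L) return(keep)
  keep[1] <- TRUE
  last <- times[1]
  for (i in seq_along(times)[-1]) {
    if (times[i] >= last + WEEK_MONTHS) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}

#' Select the pretreatment measurement for each patient
#'
#' The pretreatment CA19-9 is defined as the last measurement taken at or
#' before the start of chemotherapy (time 0).
#'
#' @param measurements A data frame with columns `patient_id`, `time_months`
#'   and `ca199_u_ml`.
#' @param strict If `TRUE` (default) an error is raised when a patient has no
#'   measurement at time <= 0; if `FALSE` such patients are silently absent
#'   from the result.
#' @return A tibble with one row per patient: the pretreatment measurement.
#' @export
select_pretreatment <- function(measurements, strict = TRUE) {
  measurements <- as_tibble(measurements)
  check_columns(measurements, c("patient_id", "time_months", "ca199_u_ml"),
                "measurements")
  pre <- measurements |>
    filter(.data$time_months <= 0) |>
    group_by(.data$patient_id) |>
    slice(which.max(.data$time_months)) |>
    ungroup()
  if (strict) {
    missing <- setdiff(unique(measurements$patient_id), pre$patient_id)
    if (length(missing) > 0) {
      abort(paste0("No pretreatment (time <= 0) measurement for patient(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  pre
}

#' Assemble a validated cohort from the three input tables
#'
#' Applies the measurement-preparation rules to a long table of serial CA19-9
#' measurements, a one-row-per-patient survival table and a baseline
#' covariate table: log10 transform, within-week deduplication, selection of
#' the last-before-treatment (pretreatment) value, and the inclusion rule
#' that the pretreatment CA19-9 must exceed 5 U/mL (patients below it are
#' CA19-9 non-secretors and are excluded). Excluded patients are recorded,
#' with reasons, in the `exclusions` attribute of the result.
#'
#' @param measurements Data frame (or CSV path) with columns
#'   `patient_id,time_months,ca199_u_ml`; times are months since
#'   chemotherapy start (pretreatment rows have time <= 0).
#' @param survival Data frame (or CSV path) with columns
#'   `patient_id,os_months,event` (event: 1 = death, 0 = censored).
#' @param baseline Data frame (or CSV path) with columns
#'   `patient_id,age_years,sex,chemo_group` (sex and chemo_group coded 0/1).
#' @param time_unit Unit of the measurement time column: `"months"`
#'   (default) or `"days"` (converted at 30.4375 days/month).
#' @param dedup Apply [dedup_weekly()] (default `TRUE`).
#' @return An object of class `ca19_cohort`: a list with tibbles `baseline`
#'   (including `pretreatment_log_ca199`), `measurements` and `survival`,
#'   plus an `exclusions` attribute.
#' @export
load_cohort <- function(measurements, survival, baseline,
                        time_unit = c("months", "days"), dedup = TRUE) {
  time_unit <- arg_match(time_unit)
  measurements <- read_table_arg(measurements)
  survival <- read_table_arg(survival)
  baseline <- read_table_arg(baseline)

  check_columns(measurements, c("patient_id", "time_months", "ca199_u_ml"),
                "measurements")
  check_columns(survival, c("patient_id", "os_months", "event"), "survival")
  check_columns(baseline, c("patient_id", "age_years", "sex", "chemo_group"),
                "baseline")

  if (any(!is.finite(measurements$ca199_u_ml)) ||
      any(measurements$ca199_u_ml <= 0)) {
    abort("CA19-9 values must be finite and > 0 U/mL.")
  }
  if (any(survival$os_months <= 0)) abort("`os_months` must be > 0.")
  if (!all(survival$event %in% c(0, 1))) abort("`event` must be 0 or 1.")

  ids_m <- unique(measurements$patient_id)
  ids_s <- unique(survival$patient_id)
  ids_b <- unique(baseline$patient_id)
  if (anyDuplicated(survival$patient_id) || anyDuplicated(baseline$patient_id)) {
    abort("survival and baseline tables must have one row per patient.")
  }
  if (!setequal(ids_m, ids_s) || !setequal(ids_m, ids_b)) {
    abort(paste0(
      "patient-id sets differ across the three tables; e.g. ",
      paste(head(c(setdiff(ids_s, ids_m), setdiff(ids_m, ids_s),
                   setdiff(ids_b, ids_m), setdiff(ids_m, ids_b)), 3),
            collapse = ", ")))
  }

  if (time_unit == "days") {
    measurements$time_months <- measurements$time_months / DAYS_PER_MONTH
  }
  measurements <- measurements |>
    arrange(.data$patient_id, .data$time_months) |>
    mutate(log_ca199 = log_ca199(.data$ca199_u_ml))
  if (dedup) measurements <- dedup_weekly(measurements)

  pre <- select_pretreatment(measurements, strict = FALSE)
  no_pre <- setdiff(ids_m, pre$patient_id)
  low_pre <- pre$patient_id[pre$ca199_u_ml <= 5]
  exclusions <- bind_rows(
    tibble(patient_id = no_pre, reason = "no pretreatment measurement"),
    tibble(patient_id = low_pre, reason = "pretreatment CA19-9 <= 5 U/mL")
  )
  keep <- setdiff(ids_m, exclusions$patient_id)
  if (nrow(exclusions) > 0) {
    inform(paste0("Excluded ", length(unique(exclusions$patient_id)),
                  " patient(s): ",
                  paste(paste0(exclusions$patient_id, " (", exclusions$reason,
                               ")"), collapse = "; ")))
  }

  baseline <- baseline |>
    filter(.data$patient_id %in% keep) |>
    left_join(pre |>
                select("patient_id", pretreatment_ca199 = "ca199_u_ml") |>
                mutate(pretreatment_log_ca199 =
                         log_ca199(.data$pretreatment_ca199)),
              by = "patient_id")
  measurements <- filter(measurements, .data$patient_id %in% keep)
  survival <- filter(survival, .data$patient_id %in% keep)

  new_cohort(baseline, measurements, survival, exclusions = exclusions)
}

#' Construct and validate a cohort object
#'
#' @param baseline,measurements,survival Tibbles as produced by
#'   [load_cohort()].
#' @param exclusions Optional tibble of excluded patients with reasons.
#' @return A `ca19_cohort` object.
#' @export
new_cohort <- function(baseline, measurements, survival, exclusions = NULL) {
  cohort <- structure(
    list(baseline = as_tibble(baseline),
         measurements = as_tibble(measurements),
         survival = as_tibble(survival)),
    exclusions = exclusions %||% tibble(patient_id = character(),
                                        reason = character()),
    class = "ca19_cohort")
  validate_cohort(cohort)
  cohort
}

#' @rdname new_cohort
#' @param cohort A `ca19_cohort` object.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ca19_cohort"))
  ids <- cohort$baseline$patient_id
  if (!setequal(ids, cohort$survival$patient_id) ||
      !setequal(ids, unique(cohort$measurements$patient_id))) {
    abort("cohort components do not cover an identical patient-id set.")
  }
  pre <- cohort$measurements |>
    group_by(.data$patient_id) |>
    summarise(has_pre = any(.data$time_months <= 0), .groups = "drop")
  if (!all(pre$has_pre)) {
    abort("every patient needs a measurement at time <= 0 (pretreatment).")
  }
  if ("log_ca199" %in% names(cohort$measurements)) {
    stopifnot(max(abs(cohort$measurements$log_ca199 -
                        log10(cohort$measurements$ca199_u_ml))) < 1e-12)
  }
  invisible(cohort)
}

#' @export
print.ca19_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  nev <- sum(x$survival$event)
  nmeas <- nrow(x$measurements)
  cat("<ca19_cohort> ", n, " patients, ", nev, " deaths, ",
      nmeas, " CA19-9 measurements\n", sep = "")
  cat("  median OS: ", round(median(x$survival$os_months), 2), " months; ",
      "median pretreatment CA19-9: ",
      round(median(x$baseline$pretreatment_ca199), 1), " U/mL\n", sep = "")
  nexc <- nrow(attr(x, "exclusions"))
  if (nexc > 0) cat("  ", nexc, " exclusion(s) recorded\n", sep = "")
  invisible(x)
}

#' Write a cohort back to the three CSV files
#'
#' @param cohort A `ca19_cohort` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ca19_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "survival.csv", "baseline.csv"))
  utils::write.csv(cohort$measurements[, c("patient_id", "time_months",
                                           "ca199_u_ml")],
                   paths[1], row.names = FALSE)
  utils::write.csv(cohort$survival[, c("patient_id", "os_months", "event")],
                   paths[2], row.names = FALSE)
  utils::write.csv(cohort$baseline[, c("patient_id", "age_years", "sex",
                                       "chemo_group")],
                   paths[3], row.names = FALSE)
  invisible(paths)
}

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("file not found: ", x))
    as_tibble(utils::read.csv(x, stringsAsFactors = FALSE))
  } else {
    as_tibble(x)
  }
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("`", what, "` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
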