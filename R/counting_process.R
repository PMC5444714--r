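#' Expand a cohort into counting-process episodes
#'
#' Each patient's follow-up is split into `(start, stop]` sub-observations at
#' the times their CA19-9 was re-measured, with the last observed log10
#' value carried forward (LOCF) across each episode. The pretreatment value
#' opens the first episode at time 0; the final episode ends at `os_months`
#' and carries the patient's death indicator. Measurements at or after
#' `os_months` cannot open an episode and are discarded (with a warning when
#' one coincides exactly with a death time).
#'
#' @param cohort A `ca19_cohort` object (see [load_cohort()]).
#' @return A tibble of episodes with columns `patient_id`, `start`, `stop`,
#'   `event`, `log_ca199`, `age_years`, `sex`, `chemo_group`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 20), seed = 1)$cohort
#' ep <- expand_counting_process(cohort)
#' head(ep)
#' @export
expand_counting_process <- function(cohort) {
  stopifnot(inherits(cohort, "ca19_cohort"))
  meas <- cohort$measurements
  surv <- cohort$survival

  # pretreatment (last value at time <= 0) is anchored at covariate time 0;
  # any earlier time <= 0 values are collapsed into it
  pre <- select_pretreatment(meas) |>
    mutate(time = 0) |>
    select("patient_id", "time", "log_ca199")

  post <- meas |>
    filter(.data$time_months > 0) |>
    left_join(surv, by = "patient_id")
  at_death <- post$time_months == post$os_months & post$event == 1
  if (any(at_death)) {
    warn(paste0(sum(at_death), " measurement(s) at the exact death time ",
                "discarded (cannot open a zero-length episode)."))
  }
  post <- post |>
    filter(.data$time_months < .data$os_months) |>
    select("patient_id", time = "time_months", "log_ca199")

  changes <- bind_rows(pre, post) |> arrange(.data$patient_id, .data$time)
  dup <- changes |>
    group_by(.data$patient_id) |>
    summarise(dup = anyDuplicated(.data$time) > 0, .groups = "drop")
  if (any(dup$dup)) {
    abort("duplicate measurement times within a patient; run dedup_weekly().")
  }

  episodes <- changes |>
    left_join(surv, by = "patient_id") |>
    group_by(.data$patient_id) |>
    mutate(start = .data$time,
           stop = dplyr::lead(.data$time, default = NA_real_),
           stop = ifelse(is.na(.data$stop), .data$os_months, .data$stop),
           event = ifelse(row_number() == n(), .data$event, 0L)) |>
    ungroup() |>
    select("patient_id", "start", "stop", "event", "log_ca199") |>
    left_join(cohort$baseline |>
                select("patient_id", "age_years", "sex", "chemo_group"),
              by = "patient_id")
  check_episodes(episodes)
  episodes
}

#' Split episodes at extra time points
#'
#' Every episode straddling a split time is divided in two at that time;
#' covariates are copied and the event indicator stays on the terminal
#' fragment. The Cox partial likelihood is invariant to this operation.
#'
#' @param episodes An episode tibble (see [expand_counting_process()]).
#' @param times Numeric vector of strictly positive split times (months).
#' @return The refined episode tibble.
#' @export
split_episodes <- function(episodes, times) {
  if (any(times <= 0)) abort("split `times` must be strictly positive.")
  for (s in sort(unique(times))) {
    hit <- episodes$start < s & s < episodes$stop
    if (!any(hit)) next
    first_half <- episodes[hit, ]
    first_half$stop <- s
    first_half$event <- 0L
    second_half <- episodes[hit, ]
    second_half$start <- s
    episodes <- bind_rows(episodes[!hit, ], first_half, second_half) |>
      arrange(.data$patient_id, .data$start)
  }
  episodes
}

#' Merge contiguous episodes that share identical covariates
#'
#' Inverse of [split_episodes()] for splits that did not coincide with a
#' covariate change: adjacent episodes of one patient with equal covariate
#' values are fused, keeping the later fragment's event indicator.
#'
#' @inheritParams split_episodes
#' @param covariates Covariate columns that must agree for two episodes to be
#'   merged.
#' @return The coarsened episode tibble.
#' @export
merge_episodes <- function(episodes,
                           covariates = setdiff(names(episodes),
                                                c("patient_id", "start",
                                                  "stop", "event"))) {
  episodes |>
    arrange(.data$patient_id, .data$start) |>
    group_by(.data$patient_id) |>
    mutate(.grp = cumsum(change_flag(dplyr::pick(dplyr::all_of(covariates))))) |>
    group_by(.data$patient_id, .data$.grp) |>
    summarise(event = .data$event[which.max(.data$stop)],
              start = min(.data$start), stop = max(.data$stop),
              dplyr::across(dplyr::all_of(covariates), dplyr::first),
              .groups = "drop") |>
    select(-".grp") |>
    select(dplyr::all_of(c("patient_id", "start", "stop", "event", covariates)))
}

# TRUE where a row starts a new run of covariate values
change_flag <- function(df) {
  if (nrow(df) <= 1) return(rep(TRUE, nrow(df)))
  same <- rep(TRUE, nrow(df) - 1)
  for (col in names(df)) {
    same <- same & df[[col]][-1] == df[[col]][-nrow(df)]
  }
  c(TRUE, !same)
}

#' Validate episode-table invariants
#'
#' Checks that episodes are well formed: `start < stop`, contiguous per
#' patient starting at 0, and at most one event carried on the final episode.
#'
#' @inheritParams split_episodes
#' @return The input, invisibly; errors describe the first violation found.
#' @export
check_episodes <- function(episodes) {
  check_columns(episodes, c("patient_id", "start", "stop", "event"),
                "episodes")
  if (any(episodes$start >= episodes$stop)) {
    abort("episodes must have start < stop.")
  }
  bad <- episodes |>
    arrange(.data$patient_id, .data$start) |>
    group_by(.data$patient_id) |>
    summarise(
      first0 = .data$start[1] == 0,
      contiguous = all(abs(.data$start[-1] - .data$stop[-n()]) < 1e-12),
      one_event = sum(.data$event) <= 1,
      terminal = all(.data$event[-n()] == 0),
      .groups = "drop")
  if (!all(bad$first0)) abort("each patient's first episode must start at 0.")
  if (!all(bad$contiguous)) abort("episodes must be contiguous per patient.")
  if (!all(bad$one_event & bad$terminal)) {
    abort("at most one event per patient, on the final episode only.")
  }
  invisible(episodes)
}
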