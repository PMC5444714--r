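#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimate of overall survival, optionally by group. Subjects
#' censored at an event time are counted at risk for that event (censorings
#' follow events at ties). The median is the smallest step time at which the
#' survival curve reaches 0.5 or below, with no interpolation; it is
#' undefined (NA) when the curve never reaches 0.5.
#'
#' @param data A data frame of one row per subject.
#' @param time,event Column names (strings) for the follow-up time in months
#'   and the death indicator (1 = death, 0 = censored).
#' @param group Optional column name defining comparison groups.
#' @return A tibble of class `km_curve` with columns `group` (if any),
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, carrying a `medians`
#'   attribute (per-group `n`, `n_events`, `median`); retrieve it with
#'   [km_median()].
#' @examples
#' d <- tibble::tibble(os = c(1, 2, 3, 4), dead = 1)
#' km <- km_estimate(d, time = "os", event = "dead")
#' km_median(km) # median 2
#' @export
km_estimate <- function(data, time = "os_months", event = "event",
                        group = NULL) {
  data <- as_tibble(data)
  check_columns(data, c(time, event, group), "data")
  if (nrow(data) == 0) abort("no subjects supplied.")
  if (any(data[[time]] <= 0)) abort("follow-up times must be > 0.")
  grp <- if (is.null(group)) factor(rep("all", nrow(data))) else
    factor(data[[group]])
  sf <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ grp, conf.type = "none")
  strata <- if (is.null(sf$strata)) {
    rep(levels(grp)[1], length(sf$time))
  } else {
    rep(sub("^grp=", "", names(sf$strata)), sf$strata)
  }
  curve <- tibble(group = strata, time = sf$time, n_risk = sf$n.risk,
                  n_event = sf$n.event, n_censor = sf$n.censor,
                  surv = sf$surv)
  if (is.null(group)) curve$group <- NULL
  medians <- curve |>
    group_by(group = if (is.null(group)) "all" else .data$group) |>
    summarise(median = {
      hit <- .data$surv <= 0.5 + 1e-12
      if (any(hit)) min(.data$time[hit]) else NA_real_
    }, .groups = "drop") |>
    left_join(tibble(group = levels(grp),
                     n = as.vector(table(grp)),
                     n_events = as.vector(tapply(data[[event]], grp, sum))),
              by = "group") |>
    select("group", "n", "n_events", "median")
  structure(curve, medians = medians, class = c("km_curve", class(curve)))
}

#' @rdname km_estimate
#' @param km A `km_curve` object.
#' @export
km_median <- function(km) {
  med <- attr(km, "medians")
  if (is.null(med)) abort("`km` must come from km_estimate().")
  med
}

#' Log-rank test for survival differences between groups
#'
#' Standard (unweighted) log-rank test built from the per-event
#' hypergeometric observed-minus-expected counts, with
#' `df = number of groups - 1`.
#'
#' @inheritParams km_estimate
#' @param group Column name defining the groups (required, >= 2 non-empty
#'   groups).
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p.value`, and a
#'   list-column `counts` with per-group `n`, `observed` and `expected`
#'   events.
#' @export
logrank_test <- function(data, time = "os_months", event = "event",
                         group = "group") {
  data <- as_tibble(data)
  check_columns(data, c(time, event, group), "data")
  grp <- factor(data[[group]])
  if (nlevels(grp) < 2) abort("log-rank test needs at least two groups.")
  if (any(table(grp) == 0)) abort("every group needs at least one subject.")
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ grp)
  df <- nlevels(grp) - 1L
  tibble(statistic = sd$chisq, df = df,
         p.value = pchisq(sd$chisq, df, lower.tail = FALSE),
         counts = list(tibble(group = levels(grp), n = as.vector(sd$n),
                              observed = as.vector(sd$obs),
                              expected = as.vector(sd$exp))))
}
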