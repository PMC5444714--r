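#' Dichotomise patients by their CA19-9 level at a landmark month
#'
#' A patient is evaluable at landmark month `k` when they are still at risk
#' (`os_months > k`) and have a CA19-9 measurement within `window` months of
#' the landmark; the measurement nearest to the landmark is used and the
#' patient is assigned to the `>= cutoff` or `< cutoff` group.
#'
#' @param cohort A `ca19_cohort` object.
#' @param month Landmark month (>= 1).
#' @param cutoff CA19-9 cutoff in U/mL (default 1000).
#' @param window Half-width of the measurement window in months
#'   (default 0.5).
#' @return A tibble `patient_id`, `landmark_value`, `group` (factor
#'   `"<cutoff"`, `">=cutoff"`), with a `diagnostics` attribute counting the
#'   patients at risk and those with a window measurement.
#' @export
landmark_classify <- function(cohort, month, cutoff = 1000, window = 0.5) {
  stopifnot(inherits(cohort, "ca19_cohort"))
  if (month < 1) abort("`month` must be >= 1.")
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  at_risk <- cohort$survival |> filter(.data$os_months > month)
  meas <- cohort$measurements |>
    semi_join(at_risk, by = "patient_id") |>
    mutate(dist = abs(.data$time_months - month)) |>
    filter(.data$dist <= window) |>
    group_by(.data$patient_id) |>
    slice(which.min(.data$dist)) |>
    ungroup()
  out <- meas |>
    mutate(group = factor(ifelse(.data$ca199_u_ml >= cutoff,
                                 ">=cutoff", "<cutoff"),
                          levels = c("<cutoff", ">=cutoff"))) |>
    select("patient_id", landmark_value = "ca199_u_ml", "group")
  structure(out,
            diagnostics = tibble(month = month,
                                 n_at_risk = nrow(at_risk),
                                 n_with_measurement = nrow(out)))
}

#' Landmark subgroup analysis at one month and cutoff
#'
#' Among patients evaluable at the landmark (see [landmark_classify()]),
#' compares the `>= cutoff` and `< cutoff` groups: Kaplan-Meier medians and
#' log-rank p, the crude hazard ratio from a univariate Cox model on the
#' group indicator, and the adjusted hazard ratio after adding the baseline
#' covariates. By default survival is re-anchored at the landmark
#' (conditional survival, `anchor = "landmark"`), which avoids immortal-time
#' bias; `anchor = "origin"` reports medians on the original time scale
#' (risk sets, tests and HRs are identical because all evaluable patients
#' enter at the same landmark time).
#'
#' @inheritParams landmark_classify
#' @param adjust Baseline covariates for the adjusted model.
#' @param anchor `"landmark"` (default) or `"origin"`.
#' @param ties Tie handling for the Cox fits.
#' @return A one-row tibble: group sizes, medians, log-rank p, crude and
#'   adjusted HRs with 95% CIs and Wald p-values, and a `flag` column
#'   (`"ok"`, `"empty_group"` or `"divergent"`).
#' @export
landmark_analysis <- function(cohort, month, cutoff = 1000,
                              adjust = c("age_years", "sex", "chemo_group",
                                         "pretreatment_log_ca199"),
                              window = 0.5,
                              anchor = c("landmark", "origin"),
                              ties = c("efron", "breslow")) {
  anchor <- arg_match(anchor)
  ties <- arg_match(ties)
  cls <- landmark_classify(cohort, month, cutoff, window)
  base <- tibble(month = month, cutoff = cutoff,
                 n = nrow(cls), n_low = sum(cls$group == "<cutoff"),
                 n_high = sum(cls$group == ">=cutoff"),
                 median_low = NA_real_, median_high = NA_real_,
                 logrank_p = NA_real_,
                 hr_crude = NA_real_, crude_lo = NA_real_,
                 crude_hi = NA_real_, crude_p = NA_real_,
                 hr_adj = NA_real_, adj_lo = NA_real_, adj_hi = NA_real_,
                 adj_p = NA_real_, flag = "ok")
  if (base$n_low == 0 || base$n_high == 0) {
    base$flag <- "empty_group"
    return(base)
  }
  d <- cls |>
    left_join(cohort$survival, by = "patient_id") |>
    left_join(cohort$baseline, by = "patient_id") |>
    mutate(time_lm = .data$os_months - month,
           group_high = as.numeric(.data$group == ">=cutoff"))

  shift <- if (anchor == "origin") month else 0
  med <- km_median(km_estimate(d, time = "time_lm", group = "group"))
  base$median_low <- med$median[med$group == "<cutoff"] + shift
  base$median_high <- med$median[med$group == ">=cutoff"] + shift
  base$logrank_p <- logrank_test(d, time = "time_lm", group = "group")$p.value

  ep <- d |>
    mutate(start = 0, stop = .data$time_lm, event = as.integer(.data$event))
  crude <- safe_hr(ep, "group_high", ties)
  base[c("hr_crude", "crude_lo", "crude_hi", "crude_p")] <- crude$hr
  adj <- safe_hr(ep, c("group_high", adjust), ties)
  base[c("hr_adj", "adj_lo", "adj_hi", "adj_p")] <- adj$hr
  if (crude$flag != "ok" || adj$flag != "ok") base$flag <- "divergent"
  base
}

# fit, exponentiate the group coefficient, flag divergence instead of
# reporting an unusable HR
safe_hr <- function(episodes, covariates, ties) {
  fit <- tryCatch(
    suppressWarnings(fit_tvcox(episodes, covariates = covariates,
                               ties = ties, robust = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || fit$divergent || !fit$converged) {
    return(list(hr = as.list(rep(NA_real_, 4)), flag = "divergent"))
  }
  b <- fit$coefficients[[1]]
  se <- sqrt(fit$var[1, 1])
  list(hr = list(exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se),
                 2 * pnorm(-abs(b / se))),
       flag = "ok")
}

#' Landmark analyses across several months
#'
#' Runs [landmark_analysis()] for each landmark month, reproducing the
#' month-by-month layout (crude and adjusted HRs for the `>= cutoff` vs
#' `< cutoff` comparison).
#'
#' @inheritParams landmark_analysis
#' @param months Landmark months (default 1:6).
#' @return A tibble with one row per month.
#' @export
landmark_table <- function(cohort, months = 1:6, cutoff = 1000,
                           adjust = c("age_years", "sex", "chemo_group",
                                      "pretreatment_log_ca199"),
                           window = 0.5,
                           anchor = c("landmark", "origin"),
                           ties = c("efron", "breslow")) {
  anchor <- arg_match(anchor)
  ties <- arg_match(ties)
  purrr::map(months, function(m) {
    landmark_analysis(cohort, m, cutoff, adjust = adjust, window = window,
                      anchor = anchor, ties = ties)
  }) |> bind_rows()
}

#' Combined pretreatment + 2-month grouping
#'
#' Compares the two concordant groups — pretreatment and 2-month CA19-9 both
#' below the cutoff versus both at or above it — by Kaplan-Meier medians,
#' log-rank test and a crude hazard ratio. Discordant patients are excluded
#' (their subgroups are too small to analyse separately). Survival is
#' re-anchored at the 2-month landmark by default.
#'
#' @inheritParams landmark_analysis
#' @param month Landmark month of the on-treatment measurement (default 2).
#' @return A one-row tibble with concordant group sizes, medians, log-rank p,
#'   crude HR with CI, the number of discordant (excluded) patients, and a
#'   `flag`.
#' @export
combined_group_analysis <- function(cohort, cutoff = 1000, month = 2,
                                    window = 0.5,
                                    anchor = c("landmark", "origin"),
                                    ties = c("efron", "breslow")) {
  anchor <- arg_match(anchor)
  ties <- arg_match(ties)
  cls <- landmark_classify(cohort, month, cutoff, window)
  d <- cls |>
    left_join(cohort$baseline |>
                select("patient_id", "pretreatment_ca199"),
              by = "patient_id") |>
    mutate(pre_high = .data$pretreatment_ca199 >= cutoff,
           lm_high = .data$group == ">=cutoff")
  concordant <- d |> filter(.data$pre_high == .data$lm_high)
  n_discordant <- nrow(d) - nrow(concordant)
  base <- tibble(cutoff = cutoff, month = month,
                 n_low = sum(!concordant$pre_high),
                 n_high = sum(concordant$pre_high),
                 n_discordant = n_discordant,
                 median_low = NA_real_, median_high = NA_real_,
                 logrank_p = NA_real_, hr_crude = NA_real_,
                 crude_lo = NA_real_, crude_hi = NA_real_,
                 crude_p = NA_real_, flag = "ok")
  if (base$n_low == 0 || base$n_high == 0) {
    base$flag <- "empty_group"
    return(base)
  }
  dd <- concordant |>
    left_join(cohort$survival, by = "patient_id") |>
    mutate(time_lm = .data$os_months - month,
           cgroup = factor(ifelse(.data$pre_high, "both>=", "both<"),
                           levels = c("both<", "both>=")),
           group_high = as.numeric(.data$pre_high),
           start = 0, stop = .data$time_lm,
           event = as.integer(.data$event))
  shift <- if (anchor == "origin") month else 0
  med <- km_median(km_estimate(dd, time = "time_lm", group = "cgroup"))
  base$median_low <- med$median[med$group == "both<"] + shift
  base$median_high <- med$median[med$group == "both>="] + shift
  base$logrank_p <- logrank_test(dd, time = "time_lm",
                                 group = "cgroup")$p.value
  crude <- safe_hr(dd, "group_high", ties)
  base[c("hr_crude", "crude_lo", "crude_hi", "crude_p")] <- crude$hr
  if (crude$flag != "ok") base$flag <- "divergent"
  base
}

#' Pretreatment-only dichotomisation analysis
#'
#' Splits the full cohort by pretreatment CA19-9 at a cutoff (no landmark;
#' every patient is evaluable from time 0) and compares the groups by
#' Kaplan-Meier medians, log-rank test and a crude Cox HR.
#'
#' @inheritParams landmark_analysis
#' @return A one-row tibble in the same shape as
#'   [combined_group_analysis()].
#' @export
pretreatment_group_analysis <- function(cohort, cutoff = 1000,
                                        ties = c("efron", "breslow")) {
  ties <- arg_match(ties)
  d <- cohort$baseline |>
    left_join(cohort$survival, by = "patient_id") |>
    mutate(pre_high = .data$pretreatment_ca199 >= cutoff,
           group = factor(ifelse(.data$pre_high, ">=cutoff", "<cutoff"),
                          levels = c("<cutoff", ">=cutoff")),
           group_high = as.numeric(.data$pre_high),
           start = 0, stop = .data$os_months,
           event = as.integer(.data$event))
  base <- tibble(cutoff = cutoff,
                 n_low = sum(!d$pre_high), n_high = sum(d$pre_high),
                 median_low = NA_real_, median_high = NA_real_,
                 logrank_p = NA_real_, hr_crude = NA_real_,
                 crude_lo = NA_real_, crude_hi = NA_real_,
                 crude_p = NA_real_, flag = "ok")
  if (base$n_low == 0 || base$n_high == 0) {
    base$flag <- "empty_group"
    return(base)
  }
  med <- km_median(km_estimate(d, time = "os_months", group = "group"))
  base$median_low <- med$median[med$group == "<cutoff"]
  base$median_high <- med$median[med$group == ">=cutoff"]
  base$logrank_p <- logrank_test(d, time = "os_months",
                                 group = "group")$p.value
  crude <- safe_hr(d, "group_high", ties)
  base[c("hr_crude", "crude_lo", "crude_hi", "crude_p")] <- crude$hr
  if (crude$flag != "ok") base$flag <- "divergent"
  base
}

#' Cutoff sensitivity sweep
#'
#' Repeats the pretreatment-only and combined pretreatment + 2-month
#' analyses across a descending ladder of CA19-9 cutoffs, to check that
#' conclusions do not hinge on the particular literature cutoff. Per-cutoff
#' failures (empty groups, divergent fits) are carried as flags; the sweep
#' never aborts.
#'
#' @inheritParams combined_group_analysis
#' @param cutoffs Cutoff levels in U/mL, default `c(1000, 800, 600, 400,
#'   200)`.
#' @return A tibble with one row per cutoff: `pre_*` columns for the
#'   pretreatment-only comparison and `comb_*` columns for the combined
#'   grouping (medians, log-rank p, crude HR with CI).
#' @export
sensitivity_sweep <- function(cohort, cutoffs = c(1000, 800, 600, 400, 200),
                              month = 2, window = 0.5,
                              anchor = c("landmark", "origin"),
                              ties = c("efron", "breslow")) {
  anchor <- arg_match(anchor)
  ties <- arg_match(ties)
  if (any(cutoffs <= 0)) abort("`cutoffs` must be positive.")
  purrr::map(cutoffs, function(ct) {
    pre <- pretreatment_group_analysis(cohort, ct, ties = ties)
    comb <- combined_group_analysis(cohort, ct, month = month,
                                    window = window, anchor = anchor,
                                    ties = ties)
    tibble(cutoff = ct,
           pre_n_low = pre$n_low, pre_n_high = pre$n_high,
           pre_median_low = pre$median_low,
           pre_median_high = pre$median_high,
           pre_p = pre$logrank_p, pre_hr = pre$hr_crude,
           pre_hr_lo = pre$crude_lo, pre_hr_hi = pre$crude_hi,
           pre_flag = pre$flag,
           comb_n_low = comb$n_low, comb_n_high = comb$n_high,
           comb_median_low = comb$median_low,
           comb_median_high = comb$median_high,
           comb_p = comb$logrank_p, comb_hr = comb$hr_crude,
           comb_hr_lo = comb$crude_lo, comb_hr_hi = comb$crude_hi,
           comb_flag = comb$flag)
  }) |> bind_rows()
}
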