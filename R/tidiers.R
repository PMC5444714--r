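#' Tidy a fitted Cox model
#'
#' @param x A `tvcox` fit.
#' @param exponentiate Report hazard ratios instead of log-hazard
#'   coefficients (default `FALSE`).
#' @param conf.level Confidence level (default 0.95).
#' @param robust Use the clustered sandwich SE when available (default).
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.tvcox <- function(x, exponentiate = FALSE, conf.level = 0.95,
                       robust = !is.null(x$robust_var), ...) {
  V <- if (robust && !is.null(x$robust_var)) x$robust_var else x$var
  se <- sqrt(diag(V))
  est <- x$coefficients
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(term = names(est), estimate = unname(est),
                std.error = unname(se),
                statistic = unname(est / se),
                p.value = 2 * pnorm(-abs(unname(est / se))),
                conf.low = unname(est - z * se),
                conf.high = unname(est + z * se))
  if (exponentiate) {
    out <- out |>
      mutate(estimate = exp(.data$estimate),
             conf.low = exp(.data$conf.low),
             conf.high = exp(.data$conf.high))
  }
  out
}

#' Model-level summary of a fitted Cox model
#'
#' @param x A `tvcox` fit.
#' @param ... Unused.
#' @return A one-row tibble: episode/patient/event counts, null and
#'   maximised log partial likelihood, likelihood-ratio statistic and
#'   p-value, iteration count, convergence and tie method.
#' @export
glance.tvcox <- function(x, ...) {
  lr <- 2 * (x$loglik[["max"]] - x$loglik[["null"]])
  df <- length(x$coefficients)
  tibble(n = x$n, n_clusters = x$n_clusters, n_events = x$n_events,
         loglik_null = x$loglik[["null"]], loglik = x$loglik[["max"]],
         statistic_lr = lr, p.value_lr = pchisq(lr, df, lower.tail = FALSE),
         iter = x$iter, converged = x$converged, divergent = x$divergent,
         ties = x$ties)
}

#' Plot a smoothed beta(t) curve with its pointwise estimates
#'
#' @param object A `beta_curve`.
#' @param level Confidence level for the band.
#' @param ... Unused.
#' @return A ggplot: smoothed log-hazard coefficient over follow-up time,
#'   95% band, and the windowed pointwise estimates with error bars.
#' @export
autoplot.beta_curve <- function(object, level = 0.95, ...) {
  pred <- predict(object, level = level)
  pts <- object$pointwise |> filter(.data$used)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$time, y = .data$beta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_pointrange(
      data = pts,
      ggplot2::aes(y = .data$estimate,
                   ymin = .data$estimate - 1.96 * .data$se,
                   ymax = .data$estimate + 1.96 * .data$se),
      colour = "grey40", fatten = 2) +
    ggplot2::labs(x = "Months since start of chemotherapy",
                  y = expression(beta(t) ~ "per log10 unit")) +
    ggplot2::theme_minimal()
}

#' Plot a hazard-ratio curve
#'
#' HR(t) as a solid line with a dashed 95% band, a horizontal reference
#' level and a vertical marker at the curve's peak.
#'
#' @param object An `hr_curve` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hr_curve <- function(object, ...) {
  ref <- attr(object, "reference")
  peak <- attr(object, "peak")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_months, y = .data$hr)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_lo), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_hi), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = ref, colour = "grey50") +
    ggplot2::geom_vline(xintercept = peak$time, colour = "grey50") +
    ggplot2::labs(x = "Months since start of chemotherapy",
                  y = "Hazard ratio per log10 unit of CA19-9") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of the survival step functions (by group when present).
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  has_group <- "group" %in% names(df)
  start <- if (has_group) {
    df |> distinct(.data$group) |> mutate(time = 0, surv = 1)
  } else {
    tibble(time = 0, surv = 1)
  }
  df <- bind_rows(start, df)
  aes <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$surv)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival") +
    ggplot2::theme_minimal()
}
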