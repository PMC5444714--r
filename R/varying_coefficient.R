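#' Pointwise estimates of the time-varying biomarker effect
#'
#' Estimates the log-hazard coefficient beta(t) of the (log10) biomarker on a
#' grid of follow-up times. For each grid time `t` a Cox model is fitted in
#' which only the deaths inside the window `[t - window/2, t + window/2)`
#' contribute event terms (all episodes still feed the risk sets), giving a
#' local-in-time partial-likelihood estimate with a clustered sandwich SE.
#' Windows with fewer than `min_events` deaths, or where the local fit
#' diverges, are returned with a missing estimate.
#'
#' @param episodes Episode tibble (see [expand_counting_process()]).
#' @param grid Grid times in months; default monthly from 0.5 to
#'   `min(12, 95th percentile of event times)`.
#' @param window Window width in months (default 2).
#' @param min_events Minimum deaths per window (default 5).
#' @param biomarker Column with the time-varying log10 marker.
#' @param adjust Baseline adjustment covariates; refitted inside each window
#'   when `gamma = "local"` (default), or held at their full-data estimates
#'   via an offset when `gamma = "global"`.
#' @param gamma `"local"` or `"global"` (see `adjust`).
#' @param ties Tie-handling method passed to [fit_tvcox()].
#' @return A tibble of class `pointwise_beta`: `time`, `n_events`,
#'   `estimate`, `se`, `used`; event times carried in an attribute for knot
#'   placement by [smooth_beta()].
#' @export
pointwise_beta <- function(episodes, grid = NULL, window = 2, min_events = 5,
                           biomarker = "log_ca199",
                           adjust = c("age_years", "sex", "chemo_group"),
                           gamma = c("local", "global"),
                           ties = c("efron", "breslow")) {
  gamma <- arg_match(gamma)
  ties <- arg_match(ties)
  if (window <= 0) abort("`window` must be > 0.")
  check_columns(episodes, c("start", "stop", "event", biomarker, adjust),
                "episodes")
  etimes <- episodes$stop[episodes$event == 1]
  if (length(etimes) == 0) abort("no events in the episode table.")
  if (is.null(grid)) {
    top <- min(12, quantile(etimes, 0.95, names = FALSE))
    grid <- seq(0.5, top, by = 1)
  }
  if (any(grid <= 0)) abort("grid times must lie in (0, max follow-up).")

  offset <- NULL
  if (gamma == "global" && length(adjust) > 0) {
    full <- fit_tvcox(episodes, covariates = c(biomarker, adjust),
                      ties = ties, robust = FALSE)
    Z <- as.matrix(episodes[, adjust, drop = FALSE])
    offset <- drop(Z %*% full$coefficients[adjust])
  }
  local_covs <- if (gamma == "local") c(biomarker, adjust) else biomarker

  rows <- purrr::map(grid, function(t0) {
    lo <- t0 - window / 2
    hi <- t0 + window / 2
    ep <- episodes
    in_win <- ep$event == 1 & ep$stop >= lo & ep$stop < hi
    ne <- sum(in_win)
    out <- tibble(time = t0, n_events = ne, estimate = NA_real_,
                  se = NA_real_, used = FALSE)
    if (ne < min_events) return(out)
    ep$event <- as.integer(in_win)
    fit <- tryCatch(
      suppressWarnings(fit_tvcox(ep, covariates = local_covs, ties = ties,
                                 robust = TRUE, offset = offset)),
      error = function(e) NULL)
    if (is.null(fit) || fit$divergent || !fit$converged) return(out)
    out$estimate <- fit$coefficients[[biomarker]]
    out$se <- sqrt(fit$robust_var[biomarker, biomarker])
    out$used <- TRUE
    out
  })
  res <- bind_rows(rows)
  if (!any(res$used)) {
    abort(paste0("all windows underpowered or divergent (events per window: ",
                 paste(res$n_events, collapse = ", "), ")."))
  }
  structure(res, event_times = etimes,
            class = c("pointwise_beta", class(res)))
}

#' Smooth pointwise beta(t) estimates with a natural cubic spline
#'
#' Weighted natural-cubic-spline regression of the pointwise estimates on
#' grid time, with weights `1/SE^2`. The smoothed curve is twice continuously
#' differentiable inside the boundary knots and linear beyond them (the
#' natural-spline boundary condition); its pointwise 95% confidence band
#' comes from the delta method on the spline coefficient covariance.
#'
#' @param pointwise A `pointwise_beta` tibble (or any tibble with `time`,
#'   `estimate`, `se`).
#' @param df Spline degrees of freedom (default 4); interior knots are
#'   placed at event-time quantiles when the event times are available,
#'   otherwise at grid-time quantiles.
#' @param knots,boundary_knots Optional explicit interior/boundary knots
#'   (months), overriding `df`.
#' @return An object of class `beta_curve`; evaluate it with
#'   [predict.beta_curve()] or turn it into a hazard-ratio table with
#'   [hr_curve()].
#' @export
smooth_beta <- function(pointwise, df = 4, knots = NULL,
                        boundary_knots = NULL) {
  check_columns(pointwise, c("time", "estimate", "se"), "pointwise")
  pts <- pointwise |>
    filter(is.finite(.data$estimate), is.finite(.data$se), .data$se > 0)
  if (is.null(knots)) {
    if (nrow(pts) < df + 1) {
      abort(paste0("need at least df + 1 = ", df + 1,
                   " non-missing pointwise estimates, got ", nrow(pts), "."))
    }
    src <- attr(pointwise, "event_times") %||% pts$time
    boundary_knots <- boundary_knots %||% range(pts$time)
    src <- src[src >= boundary_knots[1] & src <= boundary_knots[2]]
    if (length(src) < 2) src <- pts$time
    probs <- seq_len(df - 1) / df
    knots <- unique(quantile(src, probs, names = FALSE))
  } else {
    boundary_knots <- boundary_knots %||% range(pts$time)
  }
  basis <- splines::ns(pts$time, knots = knots,
                       Boundary.knots = boundary_knots)
  Xmat <- cbind(1, basis)
  w <- 1 / pts$se^2
  fit <- lm.wfit(Xmat, pts$estimate, w)
  if (fit$rank < ncol(Xmat)) {
    abort("spline basis rank-deficient for the requested df; reduce df.")
  }
  XtWX <- crossprod(Xmat * sqrt(w))
  vcov_coef <- solve(XtWX)   # weights are inverse variances (known scale)
  structure(
    list(coefficients = fit$coefficients,
         vcov = vcov_coef,
         knots = knots,
         boundary_knots = boundary_knots,
         df = ncol(basis),
         pointwise = pointwise),
    class = "beta_curve")
}

#' Evaluate a smoothed beta(t) curve
#'
#' @param object A `beta_curve` from [smooth_beta()].
#' @param times Months at which to evaluate; defaults to a fine grid over
#'   the pointwise range.
#' @param level Confidence level for the band (default 0.95).
#' @param ... Unused.
#' @return A tibble `time`, `beta`, `se`, `lower`, `upper`.
#' @export
predict.beta_curve <- function(object, times = NULL, level = 0.95, ...) {
  times <- times %||% seq(object$boundary_knots[1], object$boundary_knots[2],
                          length.out = 101)
  basis <- splines::ns(times, knots = object$knots,
                       Boundary.knots = object$boundary_knots)
  Xmat <- cbind(1, basis)
  est <- drop(Xmat %*% object$coefficients)
  se <- sqrt(rowSums((Xmat %*% object$vcov) * Xmat))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(time = times, beta = est, se = se,
         lower = est - z * se, upper = est + z * se)
}

#' @export
print.beta_curve <- function(x, ...) {
  pk <- curve_peak(x)
  cat("<beta_curve> natural cubic spline, ", x$df,
      " df; interior knots at ", paste(round(x$knots, 2), collapse = ", "),
      " months\n", sep = "")
  cat("  peak: beta = ", round(pk$beta, 3), " (HR = ",
      round(exp(pk$beta), 2), ") at ", round(pk$time, 2), " months\n",
      sep = "")
  invisible(x)
}

# argmax of the smoothed curve on a fine grid
curve_peak <- function(curve, times = NULL) {
  pred <- predict(curve, times = times %||%
                    seq(curve$boundary_knots[1], curve$boundary_knots[2],
                        length.out = 501))
  pred[which.max(pred$beta), c("time", "beta")]
}

#' Hazard-ratio curve table from a smoothed beta(t)
#'
#' Exponentiates the smoothed curve and its confidence band, giving the
#' HR(t) display: solid HR line, 95% band, a horizontal reference level
#' (default 1.56, the adjusted pretreatment-marker HR used as the reference
#' in the cohort this package models), and a vertical marker at the curve's
#' peak.
#'
#' @param curve A `beta_curve`.
#' @param reference Reference HR level for plotting (default 1.56).
#' @param times Optional evaluation grid (months).
#' @return A tibble `t_months`, `beta`, `hr`, `hr_lo`, `hr_hi` with
#'   attributes `reference` and `peak` (time and HR of the maximum).
#' @export
hr_curve <- function(curve, reference = 1.56, times = NULL) {
  stopifnot(inherits(curve, "beta_curve"))
  pred <- predict(curve, times = times)
  pk <- curve_peak(curve)
  out <- tibble(t_months = pred$time, beta = pred$beta,
                hr = exp(pred$beta), hr_lo = exp(pred$lower),
                hr_hi = exp(pred$upper))
  structure(out, reference = reference,
            peak = tibble(time = pk$time, hr = exp(pk$beta)),
            class = c("hr_curve", class(out)))
}
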