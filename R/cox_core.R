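#' Cox partial likelihood on counting-process episodes
#'
#' Log partial likelihood for a set of `(start, stop]` episodes at a fixed
#' coefficient vector, with Efron or Breslow handling of tied event times.
#' The risk set at an event time `t` comprises episodes with
#' `start < t <= stop`; the baseline hazard cancels.
#'
#' @param beta Numeric coefficient vector, one per covariate.
#' @param episodes Episode tibble (see [expand_counting_process()]).
#' @param covariates Character vector naming the covariate columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return The log partial likelihood (a scalar).
#' @export
cox_partial_loglik <- function(beta, episodes,
                               covariates = "log_ca199",
                               ties = c("efron", "breslow")) {
  ties <- arg_match(ties)
  dat <- cox_data(episodes, covariates)
  cox_quantities(beta, dat, ties, what = "loglik")$loglik
}

#' Fit a Cox model on counting-process episodes
#'
#' Newton-Raphson maximiser of the partial likelihood, written from first
#' principles for episode data. The naive covariance is the inverse observed
#' information; with `robust = TRUE` a clustered sandwich covariance
#' \eqn{A^{-1} B A^{-1}} is added, where `B` is the cross-product of
#' per-patient summed score residuals — this corrects the variance for the
#' correlation between the sub-observations of one patient.
#'
#' @inheritParams cox_partial_loglik
#' @param robust Compute the clustered sandwich covariance (default `TRUE`).
#' @param cluster Column naming the cluster (default `"patient_id"`).
#' @param init Starting coefficient vector (default all zero).
#' @param tol_loglik,tol_score,max_iter,max_coef Convergence control:
#'   iteration stops when the relative log-likelihood change is below
#'   `tol_loglik` and the score's max norm is below `tol_score`; a
#'   coefficient exceeding `max_coef` in absolute value flags monotone
#'   likelihood (divergence) instead of returning a silently huge estimate.
#' @return An object of class `tvcox` with elements `coefficients`, `var`
#'   (naive), `robust_var`, `loglik` (null and maximised), `score`, `iter`,
#'   `converged`, `divergent`, `n`, `n_events`, `n_clusters`, `ties`.
#'   Methods: [tidy.tvcox()], [glance.tvcox()], `print`, `coef`, `vcov`.
#' @examples
#' ep <- tibble::tibble(
#'   patient_id = c("a", "b", "c"), start = 0, stop = c(1, 2, 3),
#'   event = 1L, x = c(1, 0, 1)
#' )
#' fit <- fit_tvcox(ep, covariates = "x")
#' coef(fit) # -log(2)/2
#' @export
fit_tvcox <- function(episodes, covariates = "log_ca199",
                      ties = c("efron", "breslow"),
                      robust = TRUE, cluster = "patient_id",
                      offset = NULL, init = NULL,
                      tol_loglik = 1e-9, tol_score = 1e-8,
                      max_iter = 50L, max_coef = 15) {
  ties <- arg_match(ties)
  dat <- cox_data(episodes, covariates, cluster = cluster, offset = offset)
  p <- ncol(dat$X)

  sds <- apply(dat$X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("covariate(s) constant across episodes (no information): ",
                 paste(covariates[sds == 0], collapse = ", ")))
  }

  beta <- init %||% rep(0, p)
  stopifnot(length(beta) == p)
  q0 <- cox_quantities(beta, dat, ties, what = "fit")
  ll <- q0$loglik
  loglik_null <- cox_quantities(rep(0, p), dat, ties, what = "loglik")$loglik
  score <- q0$score
  info <- q0$info
  converged <- FALSE
  divergent <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(info, score), error = function(e) {
      abort("singular information matrix (rank-deficient design).")
    })
    halving <- 0L
    repeat {
      beta_new <- beta + step
      q_new <- cox_quantities(beta_new, dat, ties, what = "fit")
      if (is.finite(q_new$loglik) && q_new$loglik >= ll - 1e-12) break
      halving <- halving + 1L
      if (halving > 25L) break
      step <- step / 2
    }
    rel_change <- abs(q_new$loglik - ll) / (abs(ll) + 0.1)
    beta <- beta_new
    ll <- q_new$loglik
    score <- q_new$score
    info <- q_new$info
    if (any(abs(beta) > max_coef)) {
      divergent <- TRUE
      warn(paste0("monotone likelihood suspected: |coefficient| > ", max_coef,
                  " for ", paste(covariates[abs(beta) > max_coef],
                                 collapse = ", ")))
      break
    }
    if (rel_change < tol_loglik && max(abs(score)) < tol_score) {
      converged <- TRUE
      break
    }
  }

  var_naive <- solve(info)
  dimnames(var_naive) <- list(covariates, covariates)
  fit <- structure(
    list(coefficients = setNames(beta, covariates),
         var = var_naive,
         robust_var = NULL,
         loglik = c(null = loglik_null, max = ll),
         score = setNames(score, covariates),
         info = info,
         iter = iter, converged = converged, divergent = divergent,
         ties = ties, covariates = covariates,
         n = nrow(dat$X), n_events = dat$n_events,
         n_clusters = length(unique(dat$cluster)),
         data = dat),
    class = "tvcox")
  if (robust) fit$robust_var <- sandwich_variance(fit)
  fit
}

#' Clustered sandwich covariance for a fitted Cox model
#'
#' Computes \eqn{A^{-1} B A^{-1}}, where `A` is the observed information at
#' the optimum and `B` the cross-product of per-cluster summed score
#' residuals. With one episode per patient and each patient its own cluster
#' this is the ordinary (unclustered) robust variance.
#'
#' @param fit A `tvcox` fit.
#' @param cluster Optional replacement cluster vector, one entry per episode
#'   (must partition the episodes); defaults to the clustering used at fit
#'   time.
#' @return A symmetric covariance matrix.
#' @export
sandwich_variance <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "tvcox"))
  dat <- fit$data
  cluster <- cluster %||% dat$cluster
  if (length(cluster) != nrow(dat$X) || anyNA(cluster)) {
    abort("`cluster` must label every episode (a partition of the rows).")
  }
  r <- score_residuals_mat(fit)
  dfbeta <- rowsum(r, group = cluster, reorder = FALSE) %*% fit$var
  rob <- crossprod(dfbeta)
  dimnames(rob) <- dimnames(fit$var)
  rob
}

#' Per-episode score residuals
#'
#' @param fit A `tvcox` fit.
#' @return A matrix (episodes x covariates) of score residuals; their
#'   cluster sums feed the sandwich estimator.
#' @export
score_residuals <- function(fit) {
  r <- score_residuals_mat(fit)
  colnames(r) <- fit$covariates
  as_tibble(r)
}

#' Schoenfeld residuals of a fitted Cox model
#'
#' One row per death: the difference between the covariate of the subject
#' failing at that time and the risk-set weighted covariate mean (under
#' Efron ties, the mean of the step-wise means across the tied group).
#' Scaled residuals follow the Grambsch-Therneau convention
#' `m * V * r + beta`, with `m` the number of deaths and `V` the naive
#' covariance.
#'
#' @param fit A `tvcox` fit.
#' @return A tibble with `time`, one raw-residual column per covariate and
#'   matching `scaled_*` columns.
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "tvcox"))
  sch <- schoenfeld_mat(fit)
  m <- nrow(sch$resid)
  scaled <- m * (sch$resid %*% fit$var) +
    matrix(fit$coefficients, m, length(fit$coefficients), byrow = TRUE)
  out <- as_tibble(sch$resid)
  names(out) <- fit$covariates
  scaled <- as_tibble(scaled)
  names(scaled) <- paste0("scaled_", fit$covariates)
  dplyr::bind_cols(tibble(time = sch$time), out, scaled)
}

#' Grambsch-Therneau test of the proportional-hazards assumption
#'
#' Score test for a linear association of the scaled Schoenfeld residuals
#' with a transform of event time; a significant slope indicates a
#' time-varying coefficient. Note that a quadratic (rise-then-fall) shape of
#' `beta(t)` can be visible on the residual plot yet leave the linear-slope
#' test non-significant, which is why the smoothed `beta(t)` curve — not the
#' test alone — is the primary diagnostic in this package.
#'
#' @param fit A `tvcox` fit with at least two events.
#' @param transform Time transform for the test: `"km"` (default,
#'   left-continuous Kaplan-Meier scale), `"identity"`, `"rank"` or `"log"`.
#' @return A tibble with one row per covariate plus a `GLOBAL` row:
#'   `term`, `chisq`, `df`, `p.value`, and the transform used.
#' @export
ph_test <- function(fit, transform = c("km", "identity", "rank", "log")) {
  stopifnot(inherits(fit, "tvcox"))
  transform <- arg_match(transform)
  sch <- schoenfeld_mat(fit)
  m <- nrow(sch$resid)
  if (m < 2) abort("at least two events are required for the PH test.")
  g <- transform_times(sch$time, transform, fit$data)
  gc <- g - mean(g)
  V <- fit$var
  p <- length(fit$coefficients)
  gr <- colSums(gc * sch$resid)              # sum_k (g_k - gbar) r_k
  denom <- m * sum(gc^2)
  if (denom == 0 || all(abs(sch$resid) < 1e-300)) {
    chisq <- rep(0, p)
    global <- 0
  } else {
    svr <- as.vector(V %*% gr)
    chisq <- (m * svr)^2 / (diag(V) * denom)
    global <- m * sum(gr * svr) / sum(gc^2)
  }
  stat <- unname(c(chisq, global))
  dfs <- c(rep(1L, p), p)
  tibble(term = c(fit$covariates, "GLOBAL"),
         chisq = stat, df = dfs,
         p.value = pchisq(stat, df = dfs, lower.tail = FALSE),
         transform = transform)
}

#' Score test at zero for the covariate effect
#'
#' Cox score statistic `U(0)' I(0)^{-1} U(0)`; for a single binary group
#' indicator with Breslow ties this equals the two-group log-rank statistic.
#'
#' @inheritParams cox_partial_loglik
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
cox_score_test <- function(episodes, covariates = "log_ca199",
                           ties = c("efron", "breslow")) {
  ties <- arg_match(ties)
  dat <- cox_data(episodes, covariates)
  q <- cox_quantities(rep(0, ncol(dat$X)), dat, ties, what = "fit")
  stat <- drop(crossprod(q$score, solve(q$info, q$score)))
  tibble(statistic = stat, df = length(covariates),
         p.value = pchisq(stat, df = length(covariates), lower.tail = FALSE))
}

# ---------------------------------------------------------------------------
# internal machinery

# assemble validated vectors/matrices once per fit
cox_data <- function(episodes, covariates, cluster = "patient_id",
                     offset = NULL) {
  check_columns(episodes, c("start", "stop", "event", covariates), "episodes")
  if (any(episodes$start >= episodes$stop)) {
    abort("episodes must have start < stop.")
  }
  if (sum(episodes$event) == 0) {
    abort("no events in the episode table; partial likelihood undefined.")
  }
  X <- as.matrix(episodes[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  clus <- if (!is.null(cluster) && cluster %in% names(episodes)) {
    episodes[[cluster]]
  } else {
    seq_len(nrow(X))
  }
  ev <- episodes$event == 1
  etimes <- sort(unique(episodes$stop[ev]))
  if (!is.null(offset)) stopifnot(length(offset) == nrow(X))
  list(X = X, start = episodes$start, stop = episodes$stop,
       event = ev, cluster = clus, etimes = etimes,
       offset = offset %||% numeric(nrow(X)),
       n_events = sum(ev))
}

# suffix sums of `vals` (a matrix) over rows with key >= each etime
suffix_sums <- function(keys, vals, etimes) {
  ord <- order(keys)
  cs <- apply(vals[ord, , drop = FALSE], 2, cumsum)
  cs <- rbind(0, cs)
  totals <- cs[nrow(cs), ]
  cnt_lt <- findInterval(etimes, keys[ord], left.open = TRUE)
  sweep(-cs[cnt_lt + 1L, , drop = FALSE], 2, totals, `+`)
}

# risk-set sums S0, S1, S2 and tied-death sums at each unique event time;
# the Efron correction enters through `frac` = l/d per death step, so Breslow
# is simply frac = 0
cox_quantities <- function(beta, dat, ties, what = "fit") {
  X <- dat$X
  p <- ncol(X)
  n <- nrow(X)
  eta <- drop(X %*% beta) + dat$offset
  eta_c <- eta - max(eta)               # guard exp overflow
  w <- exp(eta_c)
  etimes <- dat$etimes
  K <- length(etimes)

  pair_i <- pair_j <- integer(0)
  for (a in seq_len(p)) for (b in a:p) {
    pair_i <- c(pair_i, a); pair_j <- c(pair_j, b)
  }
  X2 <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE]

  vals <- cbind(w, w * X, w * X2)
  S_stop <- suffix_sums(dat$stop, vals, etimes)
  S_start <- suffix_sums(dat$start, vals, etimes)
  S <- S_stop - S_start                 # at risk: start < t <= stop
  S0 <- S[, 1]
  S1 <- S[, 1 + seq_len(p), drop = FALSE]
  S2 <- S[, 1 + p + seq_along(pair_i), drop = FALSE]

  # tied-death sums, aligned with etimes (rowsum sorts groups numerically)
  ev <- dat$event
  dvals <- cbind(1, w[ev], w[ev] * X[ev, , drop = FALSE],
                 w[ev] * X2[ev, , drop = FALSE], eta_c[ev],
                 X[ev, , drop = FALSE])
  D <- rowsum(dvals, group = dat$stop[ev], reorder = TRUE)
  d <- D[, 1]
  S0d <- D[, 2]
  S1d <- D[, 2 + seq_len(p), drop = FALSE]
  S2d <- D[, 2 + p + seq_along(pair_i), drop = FALSE]
  sum_eta_d <- sum(D[, 3 + p + length(pair_i)])
  sumXd <- D[, 3 + p + length(pair_i) + seq_len(p), drop = FALSE]

  # (k, l) expansion: one row per death step
  idx <- rep.int(seq_len(K), d)
  frac <- if (ties == "efron") {
    unlist(lapply(d, function(dd) seq(0, dd - 1) / dd), use.names = FALSE)
  } else {
    numeric(length(idx))
  }
  S0_l <- S0[idx] - frac * S0d[idx]
  loglik <- sum_eta_d - sum(log(S0_l))
  if (what == "loglik") return(list(loglik = loglik))

  S1_l <- S1[idx, , drop = FALSE] - frac * S1d[idx, , drop = FALSE]
  S2_l <- S2[idx, , drop = FALSE] - frac * S2d[idx, , drop = FALSE]
  xbar_l <- S1_l / S0_l
  score <- colSums(sumXd) - colSums(xbar_l)
  info_pp <- colSums(S2_l / S0_l -
                       xbar_l[, pair_i, drop = FALSE] *
                       xbar_l[, pair_j, drop = FALSE])
  info <- matrix(0, p, p)
  for (m in seq_along(pair_i)) {
    info[pair_i[m], pair_j[m]] <- info_pp[m]
    info[pair_j[m], pair_i[m]] <- info_pp[m]
  }

  out <- list(loglik = loglik, score = score, info = info)
  if (what == "resid") {
    d_idx <- d[idx]
    out$etimes <- etimes
    out$d <- d
    out$w <- w
    # mean step-wise covariate mean per event time (Schoenfeld centre)
    out$xbarbar <- rowsum(xbar_l, group = idx, reorder = TRUE) / d
    # accumulators for score residuals
    out$a_tilde <- drop(rowsum(1 / S0_l, idx, reorder = TRUE))
    out$b_tilde <- rowsum(xbar_l / S0_l, idx, reorder = TRUE)
    out$c0 <- drop(rowsum((1 - frac) / S0_l, idx, reorder = TRUE))
    out$c1 <- rowsum((1 - frac) * xbar_l / S0_l, idx, reorder = TRUE)
  }
  out
}

score_residuals_mat <- function(fit) {
  dat <- fit$data
  q <- cox_quantities(fit$coefficients, dat, fit$ties, what = "resid")
  X <- dat$X
  p <- ncol(X)
  etimes <- q$etimes
  w <- q$w

  A_cum <- c(0, cumsum(q$a_tilde))
  B_cum <- rbind(0, apply(q$b_tilde, 2, cumsum))
  k_lo <- findInterval(dat$start, etimes)
  k_hi <- findInterval(dat$stop, etimes)
  rangeA <- A_cum[k_hi + 1L] - A_cum[k_lo + 1L]
  rangeB <- B_cum[k_hi + 1L, , drop = FALSE] - B_cum[k_lo + 1L, , drop = FALSE]
  r <- -w * (X * rangeA - rangeB)

  ev <- dat$event
  k_ev <- match(dat$stop[ev], etimes)
  Xe <- X[ev, , drop = FALSE]
  we <- w[ev]
  r[ev, ] <- r[ev, , drop = FALSE] +
    (Xe - q$xbarbar[k_ev, , drop = FALSE]) +
    we * (Xe * q$a_tilde[k_ev] - q$b_tilde[k_ev, , drop = FALSE]) -
    we * (Xe * q$c0[k_ev] - q$c1[k_ev, , drop = FALSE])
  r
}

schoenfeld_mat <- function(fit) {
  dat <- fit$data
  q <- cox_quantities(fit$coefficients, dat, fit$ties, what = "resid")
  ev <- dat$event
  times <- dat$stop[ev]
  ord <- order(times)
  k_ev <- match(times, q$etimes)
  resid <- dat$X[ev, , drop = FALSE] - q$xbarbar[k_ev, , drop = FALSE]
  list(time = times[ord], resid = resid[ord, , drop = FALSE])
}

transform_times <- function(times, transform, dat) {
  switch(transform,
    identity = times,
    log = log(times),
    rank = rank(times),
    km = {
      # left-continuous KM of overall survival across patients
      os <- tapply(dat$stop, dat$cluster, max)
      evp <- tapply(dat$event, dat$cluster, any)
      km <- survival::survfit(survival::Surv(os, as.numeric(evp)) ~ 1)
      1 - vapply(times, function(t) {
        prior <- km$surv[km$time < t]
        if (length(prior) == 0) 1 else min(prior)
      }, numeric(1))
    })
}

#' @export
print.tvcox <- function(x, ...) {
  cat("<tvcox> Cox model on counting-process episodes (",
      x$ties, " ties)\n", sep = "")
  cat("  ", x$n, " episodes, ", x$n_clusters, " patients, ",
      x$n_events, " events\n", sep = "")
  print(tidy(x))
  if (!x$converged) {
    cat(if (x$divergent) "  WARNING: divergent (monotone likelihood)\n"
        else "  WARNING: not converged\n")
  }
  invisible(x)
}

#' @export
coef.tvcox <- function(object, ...) object$coefficients

#' @export
vcov.tvcox <- function(object, robust = !is.null(object$robust_var), ...) {
  if (robust) object$robust_var else object$var
}

#' @export
logLik.tvcox <- function(object, ...) {
  structure(object$loglik[["max"]], df = length(object$coefficients),
            class = "logLik")
}
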