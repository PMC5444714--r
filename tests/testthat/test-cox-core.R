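test_that("log partial likelihood matches hand enumeration on the 3-subject fixture", {
  ep <- three_subject_episodes()
  # at beta = 0 the risk sets have sizes 3, 2, 1
  expect_equal(cox_partial_loglik(0, ep, "x"),
               log(1 / 3) + log(1 / 2) + log(1), tolerance = 1e-12)
  expect_equal(cox_partial_loglik(0, ep, "x"), -1.7918, tolerance = 1e-4)
})

test_that("at zero coefficients the log likelihood is sum of -log risk-set sizes", {
  ep <- random_episodes(n = 40, seed = 2, tie = FALSE)
  etimes <- ep$stop[ep$event == 1]
  expected <- sum(vapply(etimes, function(t) {
    -log(sum(ep$start < t & t <= ep$stop))
  }, numeric(1)))
  expect_equal(cox_partial_loglik(c(0, 0), ep, c("x", "z")), expected,
               tolerance = 1e-10)
})

test_that("vectorised likelihood agrees with brute-force enumeration, both tie methods", {
  for (seed in 1:5) {
    ep <- random_episodes(n = 30, seed = seed, tie = TRUE)
    beta <- rnorm(2, 0, 0.5)
    for (ties in c("efron", "breslow")) {
      expect_equal(cox_partial_loglik(beta, ep, c("x", "z"), ties = ties),
                   brute_force_loglik(beta, ep, c("x", "z"), ties = ties),
                   tolerance = 1e-10)
    }
  }
  # duplicating every episode as a new subject still matches brute force
  ep <- random_episodes(n = 15, seed = 9, tie = TRUE)
  dup <- dplyr::bind_rows(ep, dplyr::mutate(ep, patient_id = paste0(patient_id, "_dup")))
  expect_equal(cox_partial_loglik(c(0.3, -0.2), dup, c("x", "z")),
               brute_force_loglik(c(0.3, -0.2), dup, c("x", "z")),
               tolerance = 1e-10)
})

test_that("the 3-subject fixture has the closed-form maximiser -log(2)/2", {
  fit <- fit_tvcox(three_subject_episodes(), covariates = "x",
                   robust = FALSE)
  # score equation reduces to 2 u^2 = 1 with u = exp(beta)
  expect_equal(unname(coef(fit)), -0.5 * log(2), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$score)), 1e-8)
})

test_that("a constant covariate is rejected as rank-deficient", {
  ep <- three_subject_episodes()
  ep$x <- 1
  expect_error(fit_tvcox(ep, covariates = "x"), "constant")
})

test_that("no-event tables are rejected", {
  ep <- three_subject_episodes()
  ep$event <- 0L
  expect_error(cox_partial_loglik(0, ep, "x"), "no events")
})

test_that("monotone likelihood is flagged as divergent, not returned silently", {
  # perfectly separated covariate: every death has the largest x in its risk set
  ep <- tibble::tibble(
    patient_id = sprintf("s%d", 1:6),
    start = 0, stop = c(1, 2, 3, 4, 5, 6),
    event = c(1L, 1L, 1L, 0L, 0L, 0L),
    x = c(3, 2.5, 2, 0.5, 0.2, 0))
  expect_warning(fit <- fit_tvcox(ep, covariates = "x", robust = FALSE),
                 "monotone")
  expect_true(fit$divergent)
})

test_that("coefficients, variances and log-likelihood match the survival package", {
  for (seed in 1:6) {
    for (ties in c("efron", "breslow")) {
      ep <- random_episodes(n = 60, seed = seed, tie = seed %% 2 == 0)
      fit <- fit_tvcox(ep, covariates = c("x", "z"), ties = ties)
      oracle <- survival::coxph(
        survival::Surv(start, stop, event) ~ x + z + cluster(patient_id),
        data = ep, ties = ties)
      expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-7)
      expect_equal(unname(fit$var), unname(oracle$naive.var),
                   tolerance = 1e-7)
      expect_equal(unname(fit$robust_var), unname(oracle$var),
                   tolerance = 1e-7)
      expect_equal(fit$loglik[["max"]], oracle$loglik[2], tolerance = 1e-9)
    }
  }
})

test_that("score residuals match the survival package and sum to zero", {
  ep <- random_episodes(n = 50, seed = 4, tie = TRUE)
  for (ties in c("efron", "breslow")) {
    fit <- fit_tvcox(ep, covariates = c("x", "z"), ties = ties)
    oracle <- survival::coxph(
      survival::Surv(start, stop, event) ~ x + z,
      data = ep, ties = ties)
    expect_equal(as.matrix(score_residuals(fit)),
                 unname(as.matrix(residuals(oracle, type = "score"))),
                 ignore_attr = TRUE, tolerance = 1e-6)
    expect_lt(max(abs(colSums(score_residuals(fit)))), 1e-6)
  }
})

test_that("sandwich variance with singleton clusters equals the unclustered robust variance", {
  # one episode per patient, each its own cluster
  set.seed(10)
  ep <- tibble::tibble(
    patient_id = sprintf("s%02d", 1:40), start = 0,
    stop = sort(runif(40, 0.5, 10)), event = rbinom(40, 1, 0.7),
    x = rnorm(40))
  fit <- fit_tvcox(ep, covariates = "x")
  oracle <- survival::coxph(
    survival::Surv(stop, event) ~ x + cluster(patient_id), data = ep)
  expect_equal(unname(fit$robust_var), unname(oracle$var), tolerance = 1e-7)
})

test_that("sandwich variance rejects a cluster vector that is not a partition", {
  fit <- fit_tvcox(three_subject_episodes(), covariates = "x")
  expect_error(sandwich_variance(fit, cluster = c("a", "b")), "partition")
})

test_that("Schoenfeld residuals equal covariate minus risk-set weighted mean", {
  # two events among three subjects: hand-computable weighted means
  ep <- tibble::tibble(
    patient_id = c("a", "b", "c"), start = 0, stop = c(1, 2, 3),
    event = c(1L, 1L, 0L), x = c(1, 0, 2))
  fit <- fit_tvcox(ep, covariates = "x", robust = FALSE)
  b <- coef(fit)[[1]]
  w <- exp(b * ep$x)
  xbar1 <- sum(ep$x * w) / sum(w)            # risk set {a, b, c} at t = 1
  xbar2 <- sum(ep$x[2:3] * w[2:3]) / sum(w[2:3])  # risk set {b, c} at t = 2
  sch <- schoenfeld_residuals(fit)
  expect_equal(sch$x, c(1 - xbar1, 0 - xbar2), tolerance = 1e-8)
  # score-zero identity at the optimum
  expect_lt(abs(sum(sch$x)), 1e-8)
})

test_that("Schoenfeld residuals match the survival package on untied data", {
  ep <- random_episodes(n = 50, seed = 6, tie = FALSE)
  fit <- fit_tvcox(ep, covariates = c("x", "z"))
  oracle <- survival::coxph(survival::Surv(start, stop, event) ~ x + z,
                            data = ep)
  osch <- residuals(oracle, type = "schoenfeld")
  osch <- osch[order(as.numeric(rownames(osch))), ]
  mine <- schoenfeld_residuals(fit)
  expect_equal(as.matrix(mine[, c("x", "z")]), unname(osch),
               ignore_attr = TRUE, tolerance = 1e-7)
})

test_that("residual magnitudes are stable under relabelling of exchangeable subjects", {
  ep <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"), start = 0, stop = c(1, 2, 3, 4),
    event = c(1L, 1L, 1L, 1L), x = c(1, 0, 1, 0))
  fit <- fit_tvcox(ep, covariates = "x", robust = FALSE)
  flipped <- ep
  flipped$patient_id <- rev(ep$patient_id)
  fit2 <- fit_tvcox(flipped, covariates = "x", robust = FALSE)
  expect_equal(abs(schoenfeld_residuals(fit)$x),
               abs(schoenfeld_residuals(fit2)$x), tolerance = 1e-10)
})

test_that("the PH test is well formed and detects a strongly increasing effect", {
  x <- sim_episodes(n = 400, seed = 21,
                    beta = list(knots = c(0, 8), values = c(-0.6, 1.2)))
  fit <- fit_tvcox(x$episodes, covariates = "log_ca199")
  for (tr in c("km", "identity", "rank", "log")) {
    res <- ph_test(fit, transform = tr)
    expect_equal(nrow(res), 2)  # one covariate + GLOBAL
    expect_true(all(res$p.value >= 0 & res$p.value <= 1))
    expect_true(all(res$chisq >= 0))
  }
  # a steep increase in beta(t) should be flagged
  expect_lt(ph_test(fit, "km")$p.value[1], 0.05)
  expect_error(ph_test(fit, transform = "nope"))
})

test_that("likelihood-ratio, score and Wald statistics agree asymptotically", {
  x <- sim_episodes(n = 2000, seed = 31, beta = beta_constant(log(1.56)))
  fit <- fit_tvcox(x$episodes, covariates = "log_ca199", robust = FALSE)
  lr <- 2 * (fit$loglik[["max"]] - fit$loglik[["null"]])
  wald <- coef(fit)[[1]]^2 / fit$var[1, 1]
  score <- cox_score_test(x$episodes, "log_ca199")$statistic
  stats <- c(lr = lr, wald = wald, score = score)
  expect_lt(diff(range(stats)) / mean(stats), 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_tvcox(random_episodes(n = 60, seed = 12),
                   covariates = c("x", "z"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(td$term, c("x", "z"))
  expect_equal(tidy(fit, exponentiate = TRUE)$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 60)
  expect_true(gl$converged)
})
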