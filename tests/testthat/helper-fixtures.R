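# shared fixtures, all built in code

# the classic 3-subject single-covariate fixture: events at t = 1, 2, 3
three_subject_episodes <- function() {
  tibble::tibble(
    patient_id = c("a", "b", "c"),
    start = 0, stop = c(1, 2, 3), event = 1L,
    x = c(1, 0, 1))
}

# random counting-process episode table (optionally with tied event times)
random_episodes <- function(n = 50, seed = 1, tie = FALSE, p_event = 0.7) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    bounds <- sort(c(0, runif(k - 1, 0, 5), runif(1, 0.5, 6)))
    if (tie) bounds[k + 1] <- round(bounds[k + 1] * 4) / 4 + 0.25
    tibble::tibble(
      patient_id = sprintf("s%03d", i),
      start = bounds[1:k], stop = bounds[2:(k + 1)],
      event = c(rep(0L, k - 1), rbinom(1, 1, p_event)),
      x = rnorm(k), z = rbinom(1, 1, 0.5))
  })
  dplyr::bind_rows(rows)
}

# three-table cohort fixture with hand-chosen values
cohort_tables <- function() {
  measurements <- tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    time_months = c(-0.5, 1, 2.5, -0.2, 1.5, -0.8),
    ca199_u_ml = c(100, 250, 800, 1500, 900, 40))
  survival <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    os_months = c(8, 5, 12), event = c(1L, 1L, 0L))
  baseline <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    age_years = c(60, 70, 55), sex = c(1, 0, 1),
    chemo_group = c(1, 0, 1))
  list(measurements = measurements, survival = survival, baseline = baseline)
}

small_cohort <- function() {
  tb <- cohort_tables()
  suppressMessages(load_cohort(tb$measurements, tb$survival, tb$baseline))
}

# simulated cohort + expanded episodes in one call
sim_episodes <- function(n = 200, seed = 1, beta = beta_rise_fall(), ...) {
  cfg <- sim_config(n = n, beta = beta, ...)
  sc <- simulate_cohort(cfg, seed = seed)
  list(sim = sc, cohort = sc$cohort,
       episodes = expand_counting_process(sc$cohort))
}

# brute-force partial log-likelihood by direct enumeration of risk sets
# (independent oracle for the vectorised implementation; Breslow and Efron)
brute_force_loglik <- function(beta, episodes, covariates, ties = "efron") {
  X <- as.matrix(episodes[, covariates, drop = FALSE])
  eta <- drop(X %*% beta)
  ll <- 0
  etimes <- sort(unique(episodes$stop[episodes$event == 1]))
  for (t in etimes) {
    at_risk <- which(episodes$start < t & t <= episodes$stop)
    deaths <- which(episodes$stop == t & episodes$event == 1)
    d <- length(deaths)
    ll <- ll + sum(eta[deaths])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(eta[at_risk])))
    } else {
      s0 <- sum(exp(eta[at_risk]))
      s0d <- sum(exp(eta[deaths]))
      for (l in seq_len(d) - 1) ll <- ll - log(s0 - (l / d) * s0d)
    }
  }
  ll
}
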