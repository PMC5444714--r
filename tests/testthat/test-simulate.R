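test_that("a noiseless flat configuration yields constant trajectories", {
  cfg <- sim_config(noise_sd = 0, slope_sd = 0, slope_mean = 0, ou_sd = 0)
  set.seed(1)
  traj <- simulate_trajectory(cfg, intercept = 2.5)
  expect_true(all(traj$log_values == 2.5))
})

test_that("simulation is deterministic and stable under cohort enlargement", {
  cfg <- sim_config(n = 40)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$latent, b$latent)
  big <- simulate_cohort(sim_config(n = 60), seed = 5)
  expect_identical(a$cohort$survival,
                   big$cohort$survival[seq_len(40), ])
  expect_false(identical(simulate_cohort(cfg, seed = 6)$cohort, a$cohort))
})

test_that("the default configuration reproduces the cohort-scale facts", {
  sc <- simulate_cohort(sim_config(n = 4000), seed = 2)
  surv <- sc$cohort$survival
  expect_equal(median(surv$os_months), 7.4, tolerance = 0.08)
  counts <- table(sc$cohort$measurements$patient_id)
  expect_true(abs(median(counts) - 3) <= 1)
  expect_lte(max(counts), 16)
  expect_gte(mean(counts >= 2), 0.65)
  pre <- sc$cohort$baseline$pretreatment_log_ca199
  expect_equal(median(pre), 2.7264, tolerance = 0.03)
  expect_true(all(sc$cohort$baseline$pretreatment_ca199 > 5))
})

test_that("with no covariate effects survival is exponential", {
  cfg <- sim_config(lambda0 = 0.1, beta = beta_constant(0),
                    gamma = c(age_years = 0, sex = 0, chemo_group = 0),
                    dropout_rate = 0, horizon = 1e6)
  set.seed(3)
  draws <- replicate(2000, simulate_survival_time(
    0, 2.5, cfg, baseline_lp = 0))
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("doubling the baseline hazard exactly halves every survival time", {
  cfg1 <- sim_config(lambda0 = 0.05, beta = beta_constant(0),
                     dropout_rate = 0, horizon = 1e6)
  cfg2 <- sim_config(lambda0 = 0.10, beta = beta_constant(0),
                     dropout_rate = 0, horizon = 1e6)
  for (E in c(0.2, 1, 3)) {
    t1 <- simulate_survival_time(0, 2, cfg1, baseline_lp = 0.3, E = E)
    t2 <- simulate_survival_time(0, 2, cfg2, baseline_lp = 0.3, E = E)
    expect_equal(t1 / t2, 2, tolerance = 1e-10)
  }
})

test_that("the inverted time satisfies H(T) = E against numeric quadrature", {
  cfg <- sim_config()
  bfun <- beta_function(cfg$beta)
  for (seed in 1:10) {
    set.seed(seed)
    x_times <- c(0, sort(runif(3, 0.5, 10)))
    x_values <- runif(4, 1, 4)
    lp <- rnorm(1, 0, 0.3)
    E <- rexp(1)
    T <- simulate_survival_time(x_times, x_values, cfg, lp, E)
    # trapezoid quadrature of the hazard on a fine grid
    tt <- seq(0, T, length.out = 20001)
    x_t <- x_values[findInterval(tt, x_times)]
    h <- cfg$lambda0 * exp(lp + bfun(tt) * x_t)
    H <- sum((h[-1] + h[-length(h)]) / 2 * diff(tt))
    expect_equal(H, E, tolerance = 1e-4)
  }
})

test_that("piecewise-constant baseline hazards are honoured", {
  l0 <- data.frame(time = c(0, 5), rate = c(0.1, 0.4))
  cfg <- sim_config(lambda0 = l0, beta = beta_constant(0),
                    dropout_rate = 0, horizon = 1e6)
  # H(t) = 0.1 t for t <= 5, then 0.5 + 0.4 (t - 5); E = 0.9 -> T = 6
  expect_equal(simulate_survival_time(0, 2, cfg, 0, E = 0.9), 6,
               tolerance = 1e-10)
  # E = 0.25 -> T = 2.5, inside the first piece
  expect_equal(simulate_survival_time(0, 2, cfg, 0, E = 0.25), 2.5,
               tolerance = 1e-10)
})

test_that("the configured rise-fall truth is stored in the simulation object", {
  sc <- simulate_cohort(sim_config(n = 10), seed = 1)
  expect_equal(sc$config$beta$knots, c(0, 2, 4))
  expect_equal(sc$config$beta$values, log(c(1.56, 2, 1.56)))
  bfun <- beta_function(sc$config$beta)
  expect_equal(bfun(2), log(2))
  expect_equal(bfun(c(0, 4, 30)), log(c(1.56, 1.56, 1.56)))
})

test_that("observable tables pass cohort validation and hide the latent truth", {
  sc <- simulate_cohort(sim_config(n = 60), seed = 8)
  expect_silent(validate_cohort(sc$cohort))
  # round trip through the CSV interface
  dir <- withr::local_tempdir()
  write_cohort(sc$cohort, dir)
  back <- suppressMessages(load_cohort(
    file.path(dir, "measurements.csv"), file.path(dir, "survival.csv"),
    file.path(dir, "baseline.csv")))
  expect_equal(nrow(back$baseline), 60)
  expect_equal(nrow(attr(back, "exclusions")), 0)
  # no information-leaking columns in the observable part
  latent_cols <- c("intercept", "slope", "visit_rate", "baseline_lp",
                   "latent_death", "dropout", "path")
  for (tb in sc$cohort) expect_length(intersect(latent_cols, names(tb)), 0)
  expect_true(all(latent_cols %in% names(sc$latent)))
})

test_that("measurements stop at the observed end of follow-up", {
  sc <- simulate_cohort(sim_config(n = 200), seed = 9)
  joined <- dplyr::left_join(sc$cohort$measurements, sc$cohort$survival,
                             by = "patient_id")
  expect_true(all(joined$time_months < joined$os_months))
})

test_that("configs can be read from YAML and JSON", {
  skip_if_not_installed("yaml")
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n: 25", "lambda0: 0.05",
               "beta:", "  hr: [1.5, 2.0, 1.5]", "  knots: [0, 2, 4]"),
             yml)
  cfg <- read_sim_config(yml)
  expect_equal(cfg$n, 25)
  expect_equal(cfg$lambda0, 0.05)
  expect_equal(cfg$beta$values, log(c(1.5, 2, 1.5)))

  skip_if_not_installed("jsonlite")
  js <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n = 12, beta = list(loghr = 0.3, knots = 0)),
                       js, auto_unbox = TRUE)
  cfg2 <- read_sim_config(js)
  expect_equal(cfg2$n, 12)
  expect_equal(cfg2$beta$values, 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(lambda0 = -1), "> 0")
  expect_error(sim_config(n = 0), ">= 1")
  expect_error(sim_config(noise_sd = -0.1), ">= 0")
  expect_error(sim_config(ou_theta = 0), "ou_theta")
})
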