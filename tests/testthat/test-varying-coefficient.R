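test_that("constant pointwise estimates are reproduced exactly by the smoother", {
  pw <- tibble::tibble(time = seq(0.5, 10.5, 1), n_events = 20,
                       estimate = 0.4, se = 0.1, used = TRUE)
  curve <- smooth_beta(pw, df = 4)
  pred <- predict(curve, times = seq(1, 10, 0.5))
  expect_equal(pred$beta, rep(0.4, nrow(pred)), tolerance = 1e-9)
  # band symmetric about the constant
  expect_equal(pred$upper - 0.4, 0.4 - pred$lower, tolerance = 1e-9)
})

test_that("pointwise estimates on a straight line are reproduced exactly", {
  # natural spline space contains all linear functions
  pw <- tibble::tibble(time = seq(0.5, 10.5, 1), n_events = 20,
                       estimate = 0.1 + 0.05 * seq(0.5, 10.5, 1),
                       se = c(rep(0.1, 6), rep(0.2, 5)), used = TRUE)
  curve <- smooth_beta(pw, df = 4)
  pred <- predict(curve, times = seq(0.5, 10.5, 0.25))
  expect_equal(pred$beta, 0.1 + 0.05 * pred$time, tolerance = 1e-9)
})

test_that("the smoothed curve is linear beyond its boundary knots", {
  set.seed(2)
  pw <- tibble::tibble(time = seq(0.5, 11.5, 1), n_events = 20,
                       estimate = 0.4 + 0.2 * sin(seq(0.5, 11.5, 1)),
                       se = 0.1, used = TRUE)
  curve <- smooth_beta(pw, df = 4)
  # second differences vanish at and beyond the boundary knots
  for (t0 in list(seq(11.5, 14, 0.5), seq(-2, 0.5, 0.5))) {
    pred <- predict(curve, times = t0)
    second_diff <- diff(diff(pred$beta))
    expect_lt(max(abs(second_diff)), 1e-8)
  }
  # but it is genuinely curved inside
  inner <- predict(curve, times = seq(3, 9, 0.5))
  expect_gt(max(abs(diff(diff(inner$beta)))), 1e-4)
})

test_that("the confidence band always contains the smoothed estimate", {
  set.seed(3)
  pw <- tibble::tibble(time = seq(0.5, 11.5, 1), n_events = 20,
                       estimate = rnorm(12, 0.4, 0.15),
                       se = runif(12, 0.05, 0.3), used = TRUE)
  pred <- predict(smooth_beta(pw, df = 4))
  expect_true(all(pred$lower <= pred$beta & pred$beta <= pred$upper))
})

test_that("too few usable pointwise estimates is a configuration error", {
  pw <- tibble::tibble(time = c(1, 2, 3), n_events = 10,
                       estimate = c(0.1, 0.2, 0.3), se = 0.1, used = TRUE)
  expect_error(smooth_beta(pw, df = 4), "df \\+ 1")
})

test_that("hazard-ratio curve is the exponential of the beta curve", {
  pw <- tibble::tibble(time = seq(0.5, 10.5, 1), n_events = 20,
                       estimate = 0, se = 0.1, used = TRUE)
  flat <- hr_curve(smooth_beta(pw, df = 3))
  expect_equal(flat$hr, rep(1, nrow(flat)), tolerance = 1e-9)

  set.seed(4)
  pw$estimate <- rnorm(11, 0.3, 0.2)
  curve <- smooth_beta(pw, df = 3)
  hrc <- hr_curve(curve, reference = 1.56)
  expect_equal(hrc$hr, exp(hrc$beta), tolerance = 1e-12)
  expect_equal(attr(hrc, "reference"), 1.56)
  # exp is monotone: HR ordering matches beta ordering
  expect_equal(order(hrc$hr), order(hrc$beta))
  # the peak marker is the argmax, and exp(peak beta) is the peak HR
  pk <- attr(hrc, "peak")
  expect_equal(pk$hr, max(hr_curve(curve, times = pk$time)$hr),
               tolerance = 1e-9)
})

test_that("a peak of log 2 in beta gives a hazard ratio of 2", {
  pw <- tibble::tibble(time = seq(0.5, 8.5, 1), n_events = 20,
                       estimate = log(2) - 0.05 * (seq(0.5, 8.5, 1) - 3)^2,
                       se = 0.05, used = TRUE)
  hrc <- hr_curve(smooth_beta(pw, df = 5))
  expect_equal(max(hrc$hr), 2, tolerance = 0.02)
})

test_that("grid windows beyond the last event return a missing flag", {
  x <- sim_episodes(n = 150, seed = 14)
  last_event <- max(x$episodes$stop[x$episodes$event == 1])
  pb <- pointwise_beta(x$episodes,
                       grid = c(1, 2, last_event + 5), window = 2)
  expect_false(pb$used[3])
  expect_true(is.na(pb$estimate[3]))
  expect_true(any(pb$used[1:2]))
})

test_that("underpowered windows are flagged and an all-missing grid errors", {
  x <- sim_episodes(n = 150, seed = 15)
  expect_error(
    pointwise_beta(x$episodes, grid = c(50, 60), window = 0.5),
    "underpowered")
})

test_that("pointwise estimates track a constant truth within their errors", {
  hits <- total <- 0
  for (r in 1:5) {
    x <- sim_episodes(n = 400, seed = 40 + r,
                      beta = beta_constant(log(1.56)))
    pb <- pointwise_beta(x$episodes, window = 2)
    ok <- pb$used
    hits <- hits + sum(abs(pb$estimate[ok] - log(1.56)) <= 2 * pb$se[ok])
    total <- total + sum(ok)
  }
  expect_gte(hits / total, 0.85)
})

test_that("smoothing reduces integrated squared error against the true curve", {
  bt <- beta_function(beta_rise_fall())
  wins <- 0
  for (r in 1:8) {
    x <- sim_episodes(n = 400, seed = 60 + r)
    pb <- pointwise_beta(x$episodes, window = 2)
    ok <- pb$used
    curve <- smooth_beta(pb, df = 4)
    smoothed <- predict(curve, times = pb$time[ok])$beta
    ise_raw <- mean((pb$estimate[ok] - bt(pb$time[ok]))^2)
    ise_smooth <- mean((smoothed - bt(pb$time[ok]))^2)
    wins <- wins + (ise_smooth < ise_raw)
  }
  expect_gte(wins, 6)
})

test_that("global-gamma mode agrees with local refits to first order", {
  x <- sim_episodes(n = 400, seed = 70)
  pb_local <- pointwise_beta(x$episodes, window = 3)
  pb_global <- pointwise_beta(x$episodes, window = 3, gamma = "global")
  ok <- pb_local$used & pb_global$used
  expect_gt(sum(ok), 5)
  expect_lt(median(abs(pb_local$estimate[ok] - pb_global$estimate[ok])),
            0.05)
})
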