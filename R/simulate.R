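#' Time-varying coefficient specifications for the generator
#'
#' `beta_rise_fall()` is the generator's default effect shape: continuous
#' piecewise-linear in log-HR, rising from HR 1.56 at the start of
#' chemotherapy to a peak of HR 2 at 2 months, falling back to 1.56 at
#' 4 months and constant thereafter. `beta_constant()` gives a
#' proportional-hazards truth for calibration and null checks.
#'
#' @param hr Hazard ratios (per log10 unit of the marker) at the knots.
#' @param knots Knot times in months.
#' @return A beta specification list (`knots`, `values` in log-HR), linear
#'   between knots and constant outside them.
#' @export
beta_rise_fall <- function(hr = c(1.56, 2, 1.56), knots = c(0, 2, 4)) {
  stopifnot(length(hr) == length(knots), !is.unsorted(knots))
  list(knots = knots, values = log(hr))
}

#' @rdname beta_rise_fall
#' @param loghr Constant log hazard ratio per log10 unit.
#' @export
beta_constant <- function(loghr = log(1.56)) {
  list(knots = 0, values = loghr)
}

#' @rdname beta_rise_fall
#' @param spec A beta specification.
#' @return `beta_function()`: the corresponding function of time (months).
#' @export
beta_function <- function(spec) {
  knots <- spec$knots
  values <- spec$values
  function(t) {
    if (length(knots) == 1) return(rep(values, length(t)))
    stats::approx(knots, values, xout = pmin(pmax(t, min(knots)), max(knots)),
                  rule = 2)$y
  }
}

#' Generative specification for a synthetic cohort
#'
#' Encodes the full data-generating model: baseline covariates, log10-scale
#' marker trajectories observed at irregular visit times, and survival times
#' drawn from the hazard
#' `lambda0(t) * exp(gamma' mu + beta(t) * X(t))`, where `X(t)` is the
#' last-observation-carried-forward path of the observed log10 marker —
#' exactly the covariate path the analysis modules later reconstruct, so
#' fitted coefficients are directly comparable to the configured truth.
#' Defaults are calibrated to the cohort structure this package targets:
#' n = 109 patients, pretreatment log10 CA19-9 median ~2.73 on a 5.1-10000
#' U/mL range, 1-16 measurements per patient (median 3, ~77% with two or
#' more) and marginal median OS ~7.4 months, with administrative censoring
#' at 34.1 months.
#'
#' @param n Number of patients.
#' @param lambda0 Baseline hazard: a constant rate (months^-1) or a data
#'   frame `time, rate` for a piecewise-constant hazard (rate applies from
#'   `time` to the next change point).
#' @param gamma Named log-hazard coefficients for the baseline covariates
#'   (`age_years` enters centred at `age_center`).
#' @param beta A specification from [beta_rise_fall()] or [beta_constant()].
#' @param age_mean,age_sd,age_range,p_female,p_combined Baseline covariate
#'   distributions (age truncated to `age_range`; `sex` 1 = female,
#'   `chemo_group` 1 = gemcitabine combined with other drugs).
#' @param age_center Centring constant for age in the hazard.
#' @param intercept_mean,intercept_sd,slope_mean,slope_sd,noise_sd Trajectory
#'   model on the log10 scale: per-patient random intercept and (optional)
#'   linear drift per month, plus i.i.d. measurement noise.
#' @param ou_theta,ou_sd Mean-reverting (Ornstein-Uhlenbeck) component of
#'   the trajectory: on-treatment excursions around the patient's level with
#'   stationary SD `ou_sd` (log10 units) decaying at rate `ou_theta`
#'   (months^-1). This captures response-then-rebound marker dynamics, which
#'   make a landmark measurement predictive mainly of the hazard near that
#'   landmark; set `ou_sd = 0` for purely linear trajectories.
#' @param clip Observed log10 values are clipped to this range (the observed
#'   assay range, 5.1-12777 U/mL).
#' @param visit_gap_min Minimum gap between visits in months (emulates data
#'   already deduplicated to at most one measurement per week).
#' @param visit_rate_shape,visit_rate_mean Per-patient visit rate
#'   (visits/month) drawn from a gamma distribution; gaps are
#'   `visit_gap_min + Exp(rate)`.
#' @param max_measurements Cap on total measurements per patient (incl. the
#'   pretreatment one).
#' @param horizon Administrative censoring time in months.
#' @param dropout_rate Rate of independent exponential dropout (months^-1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 109,
                       lambda0 = 0.023,
                       gamma = c(age_years = 0.01, sex = -0.1,
                                 chemo_group = -0.2),
                       beta = beta_rise_fall(),
                       age_mean = 64, age_sd = 10, age_range = c(39, 86),
                       age_center = 64,
                       p_female = 0.459, p_combined = 0.624,
                       intercept_mean = 2.7264, intercept_sd = 0.4,
                       slope_mean = 0, slope_sd = 0,
                       ou_theta = 0.8, ou_sd = 0.7,
                       noise_sd = 0.15,
                       clip = c(log10(5.1), log10(12777)),
                       visit_gap_min = 0.25,
                       visit_rate_shape = 1.2, visit_rate_mean = 0.65,
                       max_measurements = 16,
                       horizon = 34.1, dropout_rate = 0.01) {
  cfg <- list(n = n, lambda0 = lambda0, gamma = gamma, beta = beta,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              age_center = age_center, p_female = p_female,
              p_combined = p_combined,
              intercept_mean = intercept_mean, intercept_sd = intercept_sd,
              slope_mean = slope_mean, slope_sd = slope_sd,
              ou_theta = ou_theta, ou_sd = ou_sd,
              noise_sd = noise_sd, clip = clip,
              visit_gap_min = visit_gap_min,
              visit_rate_shape = visit_rate_shape,
              visit_rate_mean = visit_rate_mean,
              max_measurements = max_measurements,
              horizon = horizon, dropout_rate = dropout_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- if (is.data.frame(cfg$lambda0)) cfg$lambda0$rate else cfg$lambda0
  if (any(rates <= 0)) abort("baseline hazard rates must be > 0.")
  if (cfg$n < 1) abort("`n` must be >= 1.")
  sds <- c(cfg$intercept_sd, cfg$slope_sd, cfg$ou_sd, cfg$noise_sd)
  if (cfg$ou_theta <= 0) abort("`ou_theta` must be > 0.")
  if (any(sds < 0)) abort("trajectory SDs must be >= 0.")
  if (cfg$horizon <= 0) abort("`horizon` must be > 0.")
  if (cfg$dropout_rate < 0) abort("`dropout_rate` must be >= 0.")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Any field of [sim_config()] may be given; the rest keep their defaults.
#' `beta` is specified as a list with `hr` (or `loghr`) and `knots`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("the jsonlite package is required to read JSON configs.")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml/.yml or .json file.")
  }
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back, and accept
  # the unambiguous alias n_patients
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  names(raw)[names(raw) == "n_patients"] <- "n"
  if (!is.null(raw$beta)) {
    raw$beta <- if (!is.null(raw$beta$hr)) {
      beta_rise_fall(hr = unlist(raw$beta$hr), knots = unlist(raw$beta$knots))
    } else {
      list(knots = unlist(raw$beta$knots %||% 0),
           values = unlist(raw$beta$loghr))
    }
  }
  if (!is.null(raw$gamma)) raw$gamma <- unlist(raw$gamma)
  do.call(sim_config, raw)
}

#' Simulate one patient's marker trajectory
#'
#' Draws the visit schedule and observed log10 marker values for a single
#' patient using the current RNG state: a pretreatment measurement at a
#' uniform time in the month before chemotherapy, then visits at cumulative
#' random gaps up to the horizon or the measurement cap. The observed value
#' at time t is `intercept + slope * t + noise`, clipped to the configured
#' assay range.
#'
#' @param config A `sim_config`.
#' @param intercept,slope,visit_rate Optional fixed patient-level
#'   parameters; drawn from the config's distributions when `NULL`.
#' @return A list: `pre_time` (<= 0), `times` (pretreatment + post visits),
#'   `log_values` (observed), plus the patient parameters.
#' @export
simulate_trajectory <- function(config, intercept = NULL, slope = NULL,
                                visit_rate = NULL) {
  stopifnot(inherits(config, "sim_config"))
  intercept <- intercept %||%
    rnorm(1, config$intercept_mean, config$intercept_sd)
  slope <- slope %||% rnorm(1, config$slope_mean, config$slope_sd)
  visit_rate <- visit_rate %||%
    rgamma(1, shape = config$visit_rate_shape,
           rate = config$visit_rate_shape / config$visit_rate_mean)
  pre_time <- -runif(1)
  n_post <- config$max_measurements - 1L
  gaps <- config$visit_gap_min + rexp(n_post, rate = visit_rate)
  post_times <- cumsum(gaps)
  post_times <- post_times[post_times <= config$horizon]
  times <- c(pre_time, post_times)
  # mean-reverting excursion around the patient's level, sampled exactly at
  # the (irregular) visit times
  u <- numeric(length(times))
  if (config$ou_sd > 0) {
    u[1] <- rnorm(1, 0, config$ou_sd)
    if (length(times) > 1) {
      for (j in 2:length(times)) {
        rho <- exp(-config$ou_theta * (times[j] - times[j - 1]))
        u[j] <- rho * u[j - 1] +
          rnorm(1, 0, config$ou_sd * sqrt(1 - rho^2))
      }
    }
  }
  noise <- rnorm(length(times), 0, config$noise_sd)
  log_values <- pmin(pmax(intercept + slope * times + u + noise,
                          config$clip[1]), config$clip[2])
  list(pre_time = pre_time, times = times, log_values = log_values,
       intercept = intercept, slope = slope, visit_rate = visit_rate)
}

# baseline hazard rate lookup and piecewise change points
lambda0_pieces <- function(config) {
  if (is.data.frame(config$lambda0)) {
    list(times = config$lambda0$time, rates = config$lambda0$rate)
  } else {
    list(times = 0, rates = config$lambda0)
  }
}

#' Draw a survival time under the time-varying hazard
#'
#' Solves `H(T) = E`, `E ~ Exp(1)`, by exact piecewise integration of
#' `lambda0(t) * exp(lp + beta(t) * x(t))`: on every piece where the
#' baseline hazard and the covariate path are constant and `beta(t)` is
#' linear the cumulative hazard has a closed form (an exponential integral),
#' and the crossing piece is inverted analytically.
#'
#' @param x_times,x_values Covariate change points (first must be 0) and the
#'   piecewise-constant log10 marker values carried on them.
#' @param config A `sim_config`.
#' @param baseline_lp Scalar `gamma' mu` for the patient.
#' @param E Unit-exponential deviate (drawn from the current RNG state when
#'   missing).
#' @return The latent death time `T` in months (may exceed the censoring
#'   horizon; censoring is applied by the caller).
#' @export
simulate_survival_time <- function(x_times, x_values, config,
                                   baseline_lp = 0, E = rexp(1)) {
  stopifnot(inherits(config, "sim_config"),
            length(x_times) == length(x_values), x_times[1] == 0)
  bfun <- beta_function(config$beta)
  l0 <- lambda0_pieces(config)
  bknots <- config$beta$knots
  # far end: beyond it beta and x are constant, so the tail is closed form
  t_end <- max(config$horizon, max(x_times), max(bknots), max(l0$times)) + 1
  brk <- sort(unique(c(x_times, bknots[bknots > 0], l0$times[l0$times > 0],
                       t_end)))
  brk <- brk[brk >= 0]
  if (brk[1] != 0) brk <- c(0, brk)

  # vectorised piecewise cumulative hazard over all segments
  a <- brk[-length(brk)]
  b <- brk[-1]
  x <- x_values[findInterval(a, x_times)]
  rate <- l0$rates[findInterval(a, l0$times)]
  bvals <- bfun(brk)
  ba <- bvals[-length(bvals)]
  slope <- (bvals[-1] - ba) / (b - a)
  h_a <- rate * exp(baseline_lp + ba * x)
  sx <- slope * x
  lin <- abs(sx) < 1e-12
  H_piece <- ifelse(lin, h_a * (b - a), h_a * (expm1(sx * (b - a))) / sx)
  cumH <- cumsum(H_piece)
  k <- which(cumH >= E)[1]
  if (!is.na(k)) {
    E_rem <- E - if (k == 1) 0 else cumH[k - 1]
    t_in <- if (lin[k]) E_rem / h_a[k] else
      log1p(E_rem * sx[k] / h_a[k]) / sx[k]
    return(a[k] + t_in)
  }
  # constant hazard beyond the last breakpoint
  last <- brk[length(brk)]
  x_l <- x_values[findInterval(last, x_times)]
  rate_l <- l0$rates[findInterval(last, l0$times)]
  h_l <- rate_l * exp(baseline_lp + bfun(last) * x_l)
  last + (E - cumH[length(cumH)]) / h_l
}

#' Simulate a full synthetic cohort
#'
#' Generates `n` independent patients: baseline covariates, marker
#' trajectory, and a survival time drawn from the configured hazard acting
#' on the LOCF path of the observed marker values. Measurements at or after
#' the observed end of follow-up are dropped from the observable tables.
#' Each patient uses a deterministic RNG substream derived from `seed`, so
#' results are reproducible and enlarging `n` does not reshuffle earlier
#' patients.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A `sim_cohort` object: `cohort` (a `ca19_cohort` with the three
#'   observable tables), `latent` (per-patient truth: trajectory parameters,
#'   linear predictor, latent death/dropout times and the full covariate
#'   path), `config` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })

  ids <- sprintf("p%04d", seq_len(config$n))
  patients <- lapply(seq_len(config$n), function(i) {
    set.seed(substream_seed(seed, i))
    age <- pmin(pmax(rnorm(1, config$age_mean, config$age_sd),
                     config$age_range[1]), config$age_range[2])
    sex <- rbinom(1, 1, config$p_female)
    chemo <- rbinom(1, 1, config$p_combined)
    traj <- simulate_trajectory(config)
    lp <- sum(config$gamma * c(age - config$age_center, sex, chemo))

    # hazard acts on the LOCF path of the observed values, anchored at 0
    x_times <- c(0, traj$times[traj$times > 0])
    x_values <- traj$log_values[c(1L, which(traj$times > 0))]
    E <- rexp(1)
    death <- simulate_survival_time(x_times, x_values, config, lp, E)
    dropout <- if (config$dropout_rate > 0) rexp(1, config$dropout_rate)
               else Inf
    cens <- min(config$horizon, dropout)
    os <- min(death, cens)
    event <- as.integer(death <= cens)

    obs_keep <- traj$times < os
    list(age = age, sex = sex, chemo = chemo, lp = lp, death = death,
         dropout = dropout, os = os, event = event,
         obs_times = traj$times[obs_keep],
         obs_log = traj$log_values[obs_keep],
         intercept = traj$intercept, slope = traj$slope,
         visit_rate = traj$visit_rate,
         path = tibble::new_tibble(list(time = x_times, x = x_values),
                                   nrow = length(x_times)))
  })

  num <- function(field) vapply(patients, `[[`, numeric(1), field)
  n_obs <- vapply(patients, function(p) length(p$obs_times), integer(1))
  obs_log <- unlist(lapply(patients, `[[`, "obs_log"), use.names = FALSE)
  baseline <- tibble(patient_id = ids, age_years = num("age"),
                     sex = num("sex"), chemo_group = num("chemo"))
  measurements <- tibble(
    patient_id = rep(ids, n_obs),
    time_months = unlist(lapply(patients, `[[`, "obs_times"),
                         use.names = FALSE),
    ca199_u_ml = 10^obs_log, log_ca199 = obs_log)
  survival <- tibble(patient_id = ids, os_months = num("os"),
                     event = as.integer(num("event")))
  latent <- tibble(patient_id = ids, intercept = num("intercept"),
                   slope = num("slope"), visit_rate = num("visit_rate"),
                   baseline_lp = num("lp"), latent_death = num("death"),
                   dropout = num("dropout"),
                   path = lapply(patients, `[[`, "path"))

  pre <- select_pretreatment(measurements)
  baseline <- baseline |>
    left_join(pre |>
                select("patient_id", pretreatment_ca199 = "ca199_u_ml") |>
                mutate(pretreatment_log_ca199 =
                         log_ca199(.data$pretreatment_ca199)),
              by = "patient_id")

  structure(
    list(cohort = new_cohort(baseline, measurements, survival),
         latent = latent, config = config, seed = seed),
    class = "sim_cohort")
}

# deterministic per-patient substream seed, kept inside 32-bit range
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 1000003 + i * 7919) %% 2147483629
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> seed ", x$seed, "\n", sep = "")
  print(x$cohort)
  invisible(x)
}
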