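#' Configuration for the synthetic EHR cohort generator
#'
#' Defaults emulate the analyzed study population: UK primary-care adults
#' with type 2 diabetes, preserved eGFR (>= 60 ml/min per 1.73 m2) and
#' uACR < 30 mg/mmol, starting either an SGLT2 inhibitor or a DPP4
#' inhibitor/sulfonylurea, 2013-2020. Covariate distributions follow the
#' published baseline table (age 58 +/- 11 years, 59% male, BMI 33 +/- 7,
#' systolic BP 132 +/- 13, HbA1c 76 +/- 18 mmol/mol, eGFR 96 +/- 14,
#' uACR median 1.1 mg/mmol with IQR 0.6-2.5, i.e. log-normal with log-SD
#' about 1.06). Treatment assignment is confounded (insulin use, regimen
#' intensity, HbA1c, BMI, calendar year), the comparator-arm event rate is
#' 3.8 per 1000 person-years and the true treatment hazard ratio is 0.62.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param seed integer seed; identical (config, seed) pairs reproduce
#'   byte-identical cohorts
#' @param covariate_params list of per-variable distribution parameters;
#'   see [default_covariate_params()]
#' @param treatment_model list with `intercept` and named `coefficients`
#'   (log-odds per [covariate_frame()] column) and matching `centers`
#' @param true_log_hr true log hazard ratio of treatment on the primary
#'   outcome (default `log(0.62)`)
#' @param baseline_rate comparator-arm marginal event rate, events per 1000
#'   person-years (default 3.8)
#' @param risk_spec [risk_score_spec()] providing the outcome log-hazard
#'   linear predictor (default [default_risk_score()])
#' @param hazard_shape Weibull shape of the event-time model; 1 (default)
#'   gives exponential event times
#' @param censoring_rates per-cause annual rates: `deregistration`,
#'   `nonkidney_death`, `glp1_start`, `crossover` (comparator -> SGLT2i)
#' @param kidney_death_fraction fraction of composite events realised as
#'   kidney-related death (default 0.05)
#' @param missingness_rates per-variable missingness fractions (defaults
#'   follow the reported missing-data rates: IMD 0.1%, BMI 3.1%, BP 0.2%,
#'   cholesterol 0.3%, HbA1c 0.2%, diabetes duration 5.8%, smoking 0.6%)
#' @param horizon_years administrative follow-up cap (default 3)
#' @param egfr_noise_sd within-person eGFR measurement SD (ml/min per
#'   1.73 m2); reading frequency and noise are generator parameters, not
#'   quantities with an empirical anchor
#' @param egfr_interval_days days between scheduled eGFR readings
#' @param ineligible_fractions fractions of deliberately ineligible
#'   subjects, used to exercise the eligibility filter: `hf_ascvd`, `esrd`,
#'   `no_uacr`, `short_registration`
#' @return a validated `synthetic_config` object
#' @export
synthetic_config <- function(n_subjects = 10000L,
                             seed = 1L,
                             covariate_params = default_covariate_params(),
                             treatment_model = default_treatment_model(),
                             true_log_hr = log(0.62),
                             baseline_rate = 3.8,
                             risk_spec = default_risk_score(),
                             hazard_shape = 1,
                             censoring_rates = list(deregistration = 0.05,
                                                    nonkidney_death = 0.01,
                                                    glp1_start = 0.03,
                                                    crossover = 0.08),
                             kidney_death_fraction = 0.05,
                             missingness_rates = list(imd_quintile = 0.001,
                                                      bmi = 0.031,
                                                      sbp = 0.002,
                                                      total_chol = 0.003,
                                                      hba1c = 0.002,
                                                      diabetes_duration = 0.058,
                                                      smoking = 0.006),
                             horizon_years = 3,
                             egfr_noise_sd = 3,
                             egfr_interval_days = 120,
                             ineligible_fractions = list(hf_ascvd = 0.02,
                                                         esrd = 0.002,
                                                         no_uacr = 0.01,
                                                         short_registration = 0.02)) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stopf("configuration error: 'n_subjects' must be >= 1")
  cp <- covariate_params
  for (nm in c("age_sd", "bmi_sd", "sbp_sd", "chol_sd", "hba1c_sd",
               "egfr_sd", "uacr_sdlog", "duration_sdlog"))
    check_pos(cp[[nm]], nm)
  check_prob(cp$p_male, "p_male")
  check_prob(unlist(missingness_rates), "missingness_rates")
  check_prob(unlist(ineligible_fractions), "ineligible_fractions")
  check_prob(kidney_death_fraction, "kidney_death_fraction")
  check_pos(unlist(censoring_rates), "censoring_rates", strict = FALSE)
  check_pos(baseline_rate, "baseline_rate")
  check_pos(hazard_shape, "hazard_shape")
  check_pos(horizon_years, "horizon_years")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 covariate_params = cp, treatment_model = treatment_model,
                 true_log_hr = true_log_hr, baseline_rate = baseline_rate,
                 risk_spec = risk_spec, hazard_shape = hazard_shape,
                 censoring_rates = censoring_rates,
                 kidney_death_fraction = kidney_death_fraction,
                 missingness_rates = missingness_rates,
                 horizon_years = horizon_years,
                 egfr_noise_sd = egfr_noise_sd,
                 egfr_interval_days = egfr_interval_days,
                 ineligible_fractions = ineligible_fractions),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_covariate_params <- function() {
  list(age_mean = 58, age_sd = 11, age_min = 20, age_max = 80,
       p_male = 0.59,
       ethnicity_probs = c(white = 0.74, south_asian = 0.15, black = 0.06,
                           mixed = 0.01, other = 0.04),
       imd_probs = c(0.165, 0.18, 0.19, 0.225, 0.24),
       height_mean = 1.70, height_sd = 0.10,
       bmi_mean = 33, bmi_sd = 7, bmi_min = 16,
       sbp_mean = 132, sbp_sd = 13,
       chol_mean = 4.4, chol_sd = 1.1,
       hba1c_mean = 76, hba1c_sd = 18, hba1c_min = 42,
       egfr_mean = 96, egfr_sd = 14, egfr_min = 55, egfr_max = 140,
       uacr_medlog = log(1.1), uacr_sdlog = 1.06, uacr_reading_sdlog = 0.25,
       duration_medlog = log(7), duration_sdlog = 0.76,
       smoking_probs = c(non = 0.53, ex = 0.31, current = 0.16),
       p_hypertension = 0.52, p_af = 0.02, p_prior_hosp = 0.19,
       year_range = 2013:2020,
       year_probs = c(0.118, 0.127, 0.144, 0.130, 0.131, 0.136, 0.138, 0.076),
       ngl_probs = c(0.10, 0.57, 0.33),
       p_statin = 0.82, p_insulin = 0.055, p_acei_arb = 0.60)
}

#' @rdname synthetic_config
#' @export
default_treatment_model <- function() {
  list(intercept = -1.0,
       coefficients = c(insulin = 1.6, ngl_3 = 1.2, hba1c = 0.007,
                        bmi = 0.025, egfr = 0.012, diabetes_duration = 0.035,
                        total_chol = -0.18, age = -0.01, prior_hosp = -0.10,
                        smoking_current = -0.10, year_num = 0.35),
       centers = c(insulin = 0, ngl_3 = 0, hba1c = 76, bmi = 33, egfr = 96,
                   diabetes_duration = 7, total_chol = 4.4, age = 58,
                   prior_hosp = 0, smoking_current = 0, year_num = 2016.5))
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cohort of subject records
#'
#' Draws baseline covariates for `n_subjects` subjects from the
#' distributions in `config$covariate_params` and builds the pre-baseline
#' laboratory reading history (two uACR readings and one eGFR reading in
#' the two years before the index date, day 0). Treatment arms and
#' outcomes are added by [assign_treatment()] and [simulate_outcomes()].
#'
#' @param config a [synthetic_config()]
#' @return a `kb_cohort`: list with `subjects` (one row per subject),
#'   `readings` (long format: id, day, measure, value), `latent`
#'   (generator truths, never read by analysis code) and `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cp <- config$covariate_params
  n <- config$n_subjects
  set.seed(stage_seed(config$seed, 1L))

  age <- rtnorm(n, cp$age_mean, cp$age_sd, cp$age_min, cp$age_max)
  sex <- ifelse(runif(n) < cp$p_male, "male", "female")
  ethnicity <- sample(names(cp$ethnicity_probs), n, TRUE, cp$ethnicity_probs)
  imd_quintile <- sample(1:5, n, TRUE, cp$imd_probs)
  height <- rtnorm(n, cp$height_mean, cp$height_sd, 1.4, 2.1)
  bmi <- rtnorm(n, cp$bmi_mean, cp$bmi_sd, cp$bmi_min, Inf)
  weight <- bmi * height^2
  sbp <- rtnorm(n, cp$sbp_mean, cp$sbp_sd, 80, 230)
  total_chol <- rtnorm(n, cp$chol_mean, cp$chol_sd, 1.5, 12)
  hba1c <- rtnorm(n, cp$hba1c_mean, cp$hba1c_sd, cp$hba1c_min, Inf)
  egfr_true <- rtnorm(n, cp$egfr_mean, cp$egfr_sd, cp$egfr_min, cp$egfr_max)
  uacr_true <- rlnorm(n, cp$uacr_medlog, cp$uacr_sdlog)
  diabetes_duration <- rlnorm(n, cp$duration_medlog, cp$duration_sdlog)
  smoking <- sample(names(cp$smoking_probs), n, TRUE, cp$smoking_probs)
  hypertension <- runif(n) < cp$p_hypertension
  atrial_fibrillation <- runif(n) < cp$p_af
  prior_hospitalisation <- runif(n) < cp$p_prior_hosp
  calendar_year <- sample(cp$year_range, n, TRUE, cp$year_probs)
  n_glucose_lowering <- sample(c("1", "2", "3+"), n, TRUE, cp$ngl_probs)
  statin <- runif(n) < cp$p_statin
  insulin <- runif(n) < cp$p_insulin
  acei_arb <- runif(n) < cp$p_acei_arb

  inel <- config$ineligible_fractions
  hf_chd <- runif(n) < inel$hf_ascvd
  esrd_prior <- runif(n) < inel$esrd
  no_uacr <- runif(n) < inel$no_uacr
  registration_days <- ifelse(runif(n) < inel$short_registration,
                              floor(runif(n, 0, 91)),
                              floor(runif(n, 91, 4000)))

  subjects <- data.frame(
    id = seq_len(n), age = age, sex = sex, ethnicity = ethnicity,
    imd_quintile = imd_quintile, height = height, weight = weight, bmi = bmi,
    sbp = sbp, total_chol = total_chol, hba1c = hba1c,
    diabetes_duration = diabetes_duration, smoking = smoking,
    hypertension = hypertension, atrial_fibrillation = atrial_fibrillation,
    prior_hospitalisation = prior_hospitalisation,
    calendar_year = calendar_year, n_glucose_lowering = n_glucose_lowering,
    statin = statin, insulin = insulin, acei_arb = acei_arb,
    hf_chd = hf_chd, esrd_prior = esrd_prior,
    registration_days = registration_days,
    stringsAsFactors = FALSE
  )

  # Pre-baseline lab history: two uACR readings (supports the
  # two-consecutive-readings albuminuria rule) and a baseline eGFR reading.
  uacr_day1 <- -floor(runif(n, 100, 400))
  uacr_day2 <- -floor(runif(n, 10, 90))
  uacr_v1 <- uacr_true * exp(rnorm(n, 0, cp$uacr_reading_sdlog))
  uacr_v2 <- uacr_true * exp(rnorm(n, 0, cp$uacr_reading_sdlog))
  egfr_day0 <- -floor(runif(n, 1, 30))
  keep <- !no_uacr
  readings <- rbind(
    data.frame(id = subjects$id[keep], day = uacr_day1[keep],
               measure = "uacr", value = uacr_v1[keep]),
    data.frame(id = subjects$id[keep], day = uacr_day2[keep],
               measure = "uacr", value = uacr_v2[keep]),
    data.frame(id = subjects$id, day = egfr_day0,
               measure = "egfr", value = egfr_true)
  )
  readings <- readings[order(readings$id, readings$measure, readings$day), ]
  rownames(readings) <- NULL

  latent <- data.frame(id = subjects$id, egfr_true = egfr_true,
                       uacr_true = uacr_true)
  structure(list(subjects = subjects, readings = readings, latent = latent,
                 config = config),
            class = "kb_cohort")
}

#' Assign treatment arms with confounding
#'
#' Arm membership is drawn `Bernoulli(expit(intercept + sum(coef * (x -
#' center))))` over the named covariate-frame columns, emulating channelled
#' prescribing (insulin-treated, intensively treated, higher-HbA1c and
#' later-calendar-year subjects are more likely to receive an SGLT2
#' inhibitor). The propensity truth is kept in the latent store only.
#'
#' @param cohort a `kb_cohort`
#' @param treatment_model as in [synthetic_config()]; defaults to the
#'   cohort's configured model
#' @param seed integer seed
#' @return the cohort with an `arm` column (`"sglt2i"` / `"comparator"`),
#'   comparator drug class, and `latent_ps` in the latent store
#' @export
assign_treatment <- function(cohort, treatment_model = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "kb_cohort"))
  tm <- treatment_model %||% cohort$config$treatment_model
  seed <- seed %||% stage_seed(cohort$config$seed, 2L)
  set.seed(seed)
  s <- cohort$subjects
  fr <- covariate_frame(transform(s, egfr = cohort$latent$egfr_true,
                                  uacr = cohort$latent$uacr_true))
  fr$year_num <- s$calendar_year
  lp <- rep(tm$intercept, nrow(s))
  for (nm in names(tm$coefficients)) {
    if (!nm %in% names(fr))
      stopf("configuration error: unknown covariate '%s' in treatment model", nm)
    ctr <- if (!is.null(tm$centers) && nm %in% names(tm$centers)) tm$centers[[nm]] else 0
    lp <- lp + tm$coefficients[[nm]] * (fr[[nm]] - ctr)
  }
  ps <- expit(lp)
  s$arm <- ifelse(runif(nrow(s)) < ps, "sglt2i", "comparator")
  # comparator drug class, for pairwise sensitivity analyses
  s$comparator_drug <- ifelse(s$arm == "comparator",
                              ifelse(runif(nrow(s)) < 0.605, "dpp4i", "su"),
                              NA_character_)
  cohort$subjects <- s
  cohort$latent$latent_ps <- ps
  cohort
}

#' Simulate outcomes, censoring and longitudinal eGFR series
#'
#' Event times follow a Weibull hazard `Lambda(t) = (lambda_i * t)^shape`
#' (exponential when `shape = 1`) with subject rate
#' `lambda_i = lambda0 * exp(LP_i + arm * true_log_hr)`, where `LP_i` is the
#' risk-score linear predictor and `lambda0` normalises the comparator-arm
#' marginal rate to `baseline_rate` per 1000 person-years. A single shared
#' uniform draw per subject generates both counterfactual event times, so
#' the true individual absolute risk reduction is exactly defined; the
#' observed time equals the assigned arm's counterfactual time.
#' Comparator subjects may cross over to SGLT2i on an independent
#' exponential clock; their post-crossover residual event time is redrawn
#' under the treated hazard (memoryless). Composite events are realised as
#' a supporting eGFR reading at 45% of baseline (>= 50% decline) or, for a
#' configurable fraction, a kidney-related death. Competing censoring
#' clocks (deregistration, non-kidney death, GLP-1 start) are exponential.
#'
#' @param cohort a `kb_cohort` with arms assigned
#' @param config optional override of the cohort's config
#' @param seed integer seed
#' @return the cohort with outcome fields, censoring days, follow-up eGFR
#'   readings, and latent counterfactual event times
#' @export
simulate_outcomes <- function(cohort, config = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "kb_cohort"))
  cfg <- config %||% cohort$config
  if (cfg$baseline_rate <= 0)
    stopf("configuration error: 'baseline_rate' must be > 0")
  s <- cohort$subjects
  if (is.null(s$arm)) stopf("input error: arms not assigned; call assign_treatment()")
  seed <- seed %||% stage_seed(cfg$seed, 3L)
  set.seed(seed)
  n <- nrow(s)
  horizon_days <- ceiling(cfg$horizon_years * DAYS_PER_YEAR)

  fr <- covariate_frame(transform(s, egfr = cohort$latent$egfr_true,
                                  uacr = cohort$latent$uacr_true))
  lp <- linear_predictor(cfg$risk_spec, fr)
  lambda0 <- (cfg$baseline_rate / 1000) / mean(exp(lp))
  lam_ctl <- lambda0 * exp(lp)
  lam_trt <- lam_ctl * exp(cfg$true_log_hr)
  shape <- cfg$hazard_shape

  u <- runif(n)
  # Lambda(t) = (lambda * t)^shape  =>  T = (-log u)^(1/shape) / lambda
  t_ctl <- (-log(u))^(1 / shape) / lam_ctl
  t_trt <- (-log(u))^(1 / shape) / lam_trt
  treated <- s$arm == "sglt2i"
  t_obs <- ifelse(treated, t_trt, t_ctl)

  cr <- cfg$censoring_rates
  rexp_or_inf <- function(rate) if (rate > 0) rexp(n, rate) else rep(Inf, n)
  t_dereg <- rexp_or_inf(cr$deregistration)
  t_death_nk <- rexp_or_inf(cr$nonkidney_death)
  t_glp1 <- rexp_or_inf(cr$glp1_start)
  t_cross <- ifelse(treated, Inf, rexp_or_inf(cr$crossover))

  # crossover before the (control-hazard) event: redraw the residual event
  # time under the treated hazard from the crossover day
  crossed <- !treated & t_cross < pmin(t_obs, cfg$horizon_years)
  if (any(crossed)) {
    idx <- which(crossed)
    resid <- (-log(runif(length(idx))))^(1 / shape) / lam_trt[idx]
    t_obs[idx] <- t_cross[idx] + resid
  }

  # event realisation type (kidney death vs eGFR decline)
  kd <- runif(n) < cfg$kidney_death_fraction

  event_day <- floor(t_obs * DAYS_PER_YEAR) + 1
  s$deregistration_day <- floor(t_dereg * DAYS_PER_YEAR) + 1
  s$nonkidney_death_day <- floor(t_death_nk * DAYS_PER_YEAR) + 1
  s$glp1_start_day <- floor(t_glp1 * DAYS_PER_YEAR) + 1
  s$crossover_day <- ifelse(is.finite(t_cross), floor(t_cross * DAYS_PER_YEAR) + 1, NA)
  s$death_day <- NA_real_
  s$kidney_related_death <- FALSE
  s$rrt_day <- NA_real_

  # longitudinal eGFR series; the window covers second (post-crossover)
  # follow-up periods, which can extend to twice the horizon
  max_day <- ceiling(2 * max(cfg$horizon_years, 3) * DAYS_PER_YEAR)
  base <- cohort$latent$egfr_true
  sched <- seq(cfg$egfr_interval_days, max_day, by = cfg$egfr_interval_days)
  ns <- length(sched)
  day_mat <- matrix(rep(sched, each = n), nrow = n)
  drift <- 1 - 0.015 * day_mat / DAYS_PER_YEAR
  val <- base * drift + matrix(rnorm(n * ns, 0, cfg$egfr_noise_sd), nrow = n)
  val <- pmax(val, 0.55 * base)  # non-event trajectories never cross -50%

  ev_decline <- which(!kd & event_day <= max_day &
                        event_day < s$nonkidney_death_day)
  ev_death <- which(kd & event_day <= max_day &
                      event_day < s$nonkidney_death_day)
  # decline events: stable trajectory with an acute drop in the 90 days
  # before the event (held just above the -50% threshold, so the event is
  # dated by its supporting reading), then no readings after the event
  if (length(ev_decline)) {
    for_rows <- ev_decline
    fr_day <- event_day[for_rows]
    dm <- day_mat[for_rows, , drop = FALSE]
    in_drop <- dm >= fr_day - 90 & dm < fr_day
    val[for_rows, ][in_drop] <- (0.52 * base[for_rows] *
                                   matrix(1, length(for_rows), ns))[in_drop]
    val[for_rows, ][dm >= fr_day] <- NA
  }
  if (length(ev_death)) {
    rows <- ev_death
    s$death_day[rows] <- event_day[rows]
    s$kidney_related_death[rows] <- TRUE
    post <- day_mat[rows, , drop = FALSE] >= event_day[rows]
    val[rows, ][post] <- NA
  }
  # non-kidney death truncates the series and sets an unflagged death day
  nk <- which(s$nonkidney_death_day <= pmin(event_day, max_day))
  if (length(nk)) {
    s$death_day[nk] <- s$nonkidney_death_day[nk]
    s$kidney_related_death[nk] <- FALSE
    post <- day_mat[nk, , drop = FALSE] >= s$nonkidney_death_day[nk]
    val[nk, ][post] <- NA
  }

  fu <- data.frame(id = rep(s$id, ns), day = as.vector(day_mat),
                   measure = "egfr", value = as.vector(val))
  fu <- fu[!is.na(fu$value), ]
  if (length(ev_decline)) {
    # the supporting reading must register as a >= 50% decline from the
    # baseline of whichever follow-up period contains the event: for
    # comparators who crossed over, that baseline is re-resolved at the
    # crossover date from the (possibly already reduced) reading history
    ref <- base[ev_decline]
    cross_day <- s$crossover_day[ev_decline]
    has_cross <- !is.na(cross_day) & crossed[ev_decline]
    if (any(has_cross)) {
      idx_sched <- pmin(floor(cross_day / cfg$egfr_interval_days), ns)
      rows <- which(has_cross & idx_sched >= 1)
      if (length(rows)) {
        b2 <- val[cbind(ev_decline[rows], idx_sched[rows])]
        b2[is.na(b2)] <- ref[rows][is.na(b2)]
        ref[rows] <- pmin(ref[rows], b2)
      }
    }
    fu <- rbind(fu, data.frame(id = s$id[ev_decline], day = event_day[ev_decline],
                               measure = "egfr", value = 0.45 * ref))
  }
  readings <- rbind(cohort$readings, fu)
  readings <- readings[order(readings$id, readings$measure, readings$day), ]
  rownames(readings) <- NULL

  lat <- cohort$latent
  lat$lp_risk <- lp
  lat$lambda_control <- lam_ctl
  lat$t_event_control <- t_ctl
  lat$t_event_treated <- t_trt
  h <- cfg$horizon_years
  lat$true_risk_control <- 1 - exp(-(lam_ctl * h)^shape)
  lat$true_risk_treated <- 1 - exp(-(lam_trt * h)^shape)
  lat$true_arr <- lat$true_risk_control - lat$true_risk_treated
  lat$event_day_latent <- event_day

  cohort$subjects <- s
  cohort$readings <- readings
  cohort$latent <- lat
  cohort
}

#' Mask covariate values to emulate missing clinical data
#'
#' Each listed variable is masked independently (MCAR by default). BMI
#' missingness is implemented by masking height or weight (BMI then
#' recomputed as missing), mirroring how BMI goes missing in primary-care
#' records. Optionally missingness can depend on an observed covariate
#' (MAR), with masking probability increasing in that covariate.
#'
#' @param cohort a `kb_cohort`
#' @param missingness_rates named list of per-variable fractions in `[0,1]`
#' @param seed integer seed
#' @param mode `"mcar"` (default) or `"mar"`
#' @param mar_covariate subject column driving MAR missingness
#' @param mar_strength log-odds of masking per SD of the MAR covariate
#' @return the cohort with masked values set to `NA`; original values are
#'   retained in `cohort$masked_original` for imputation-accuracy checks
#' @export
inject_missingness <- function(cohort, missingness_rates = NULL, seed = NULL,
                               mode = c("mcar", "mar"), mar_covariate = "age",
                               mar_strength = 1) {
  stopifnot(inherits(cohort, "kb_cohort"))
  mode <- match.arg(mode)
  rates <- missingness_rates %||% cohort$config$missingness_rates
  check_prob(unlist(rates), "missingness_rates")
  seed <- seed %||% stage_seed(cohort$config$seed, 4L)
  set.seed(seed)
  s <- cohort$subjects
  n <- nrow(s)
  masked <- list()
  mask_prob <- function(rate) {
    if (mode == "mcar") return(rep(rate, n))
    z <- scale(as.numeric(s[[mar_covariate]]))[, 1]
    p <- expit(log(rate / (1 - rate)) + mar_strength * z)
    p
  }
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    hit <- runif(n) < mask_prob(rates[[v]])
    if (!any(hit)) next
    if (v == "bmi") {
      comp <- ifelse(runif(n) < 0.5, "height", "weight")
      for (cc in c("height", "weight")) {
        rows <- which(hit & comp == cc)
        if (!length(rows)) next
        masked[[length(masked) + 1]] <- data.frame(id = s$id[rows], variable = cc,
                                                   value = as.character(s[[cc]][rows]))
        s[[cc]][rows] <- NA
      }
      rows <- which(hit)
      masked[[length(masked) + 1]] <- data.frame(id = s$id[rows], variable = "bmi",
                                                 value = as.character(s$bmi[rows]))
      s$bmi[rows] <- NA
    } else {
      rows <- which(hit)
      masked[[length(masked) + 1]] <- data.frame(id = s$id[rows], variable = v,
                                                 value = as.character(s[[v]][rows]))
      s[[v]][rows] <- NA
    }
  }
  cohort$subjects <- s
  cohort$masked_original <- if (length(masked)) do.call(rbind, masked) else
    data.frame(id = integer(), variable = character(), value = character())
  cohort
}

#' @export
print.kb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d readings%s\n",
              nrow(x$subjects), nrow(x$readings),
              if (!is.null(x$subjects$arm))
                sprintf(", %.1f%% SGLT2i", 100 * mean(x$subjects$arm == "sglt2i"))
              else ""))
  invisible(x)
}
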