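make_subject_cohort <- function(subjects, readings) {
  structure(list(subjects = subjects, readings = readings,
                 latent = data.frame(id = subjects$id), config = NULL),
            class = "kb_cohort")
}

base_subject <- function(id = 1, ...) {
  out <- data.frame(id = id, age = 60, sex = "male", ethnicity = "white",
                    imd_quintile = 3, height = 1.7, weight = 90, bmi = 31.1,
                    sbp = 132, total_chol = 4.4, hba1c = 76,
                    diabetes_duration = 7, smoking = "non",
                    hypertension = FALSE, atrial_fibrillation = FALSE,
                    prior_hospitalisation = FALSE, calendar_year = 2016,
                    n_glucose_lowering = "2", statin = TRUE, insulin = FALSE,
                    acei_arb = TRUE, hf_chd = FALSE, esrd_prior = FALSE,
                    registration_days = 400, arm = "sglt2i",
                    comparator_drug = NA_character_, crossover_day = NA_real_,
                    deregistration_day = 1e6, nonkidney_death_day = 1e6,
                    glp1_start_day = 1e6, death_day = NA_real_,
                    kidney_related_death = FALSE, rrt_day = NA_real_,
                    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) out[[nm]] <- mods[[nm]]
  out
}

std_readings <- function(id = 1, egfr = 90, uacr = 1) {
  data.frame(id = id,
             day = c(-120, -40, -10),
             measure = c("uacr", "uacr", "egfr"),
             value = c(uacr, uacr, egfr))
}

test_that("eligibility excludes by the documented criteria and order", {
  subs <- do.call(rbind, list(
    base_subject(1, age = 60),                         # eligible
    base_subject(2),                                   # eGFR 59.9 below
    base_subject(3),                                   # uACR 30 at baseline
    base_subject(4, hf_chd = TRUE),                    # prior HF/ASCVD
    base_subject(5, weight = 50, bmi = 50 / 1.7^2),    # BMI < 20
    base_subject(6, age = 81),                         # age > 80
    base_subject(7, registration_days = 90),           # registration < 91 d
    base_subject(8),                                   # missing uACR
    # boundary subject: age 80, BMI 20, eGFR 60, uACR 29.9, 91 days
    base_subject(9, age = 80, weight = 20 * 1.7^2, bmi = 20,
                 registration_days = 91),
    base_subject(10, esrd_prior = TRUE)                # prior ESKD
  ))
  rd <- rbind(std_readings(1), std_readings(2, egfr = 59.9),
              std_readings(3, uacr = 30), std_readings(4),
              std_readings(5), std_readings(6), std_readings(7),
              std_readings(8)[3, ],   # eGFR only, no uACR
              std_readings(9, egfr = 60, uacr = 29.9), std_readings(10))
  co <- make_subject_cohort(subs, rd)
  el <- apply_eligibility(co)
  expect_setequal(el$cohort$subjects$id, c(1, 9))
  got <- setNames(el$exclusions$reason, el$exclusions$id)
  expect_equal(unname(got[as.character(c(2, 3, 4, 5, 6, 7, 8, 10))]),
               c("egfr_lt60_or_uacr_ge30", "egfr_lt60_or_uacr_ge30",
                 "prior_hf_ascvd", "bmi_lt20", "age_lt20_or_gt80",
                 "registration_lt91d", "missing_egfr_uacr", "eskd"))
  # every excluded subject carries exactly one reason; counts partition input
  expect_equal(nrow(el$exclusions) + nrow(el$cohort$subjects), nrow(subs))
  expect_equal(sum(el$counts$n), nrow(el$exclusions))
  # first matching criterion wins: HF/ASCVD outranks a low eGFR
  co2 <- make_subject_cohort(base_subject(11, hf_chd = TRUE),
                             std_readings(11, egfr = 40))
  expect_equal(apply_eligibility(co2)$exclusions$reason, "prior_hf_ascvd")
})

test_that("baseline labs use the closest reading in the prior two years", {
  rd <- data.frame(id = 1,
                   day = c(-800, -300, -100, -100, 50),
                   measure = "egfr",
                   value = c(50, 70, 80, 85, 99))
  co <- make_subject_cohort(base_subject(1), rbind(rd, std_readings(1)[1:2, ]))
  el <- apply_eligibility(co)
  # day -10 reading from std_readings absent here; closest is day -100;
  # tie between the two day -100 readings resolves to the later row
  expect_equal(el$cohort$subjects$egfr, 85)
})

test_that("albuminuria classification needs two consecutive in-band readings", {
  expect_equal(classify_albuminuria(c(3.5, 4.0)), "low_level")
  expect_equal(classify_albuminuria(c(2.9, 3.5)), "normal")
  expect_equal(classify_albuminuria(5.0), "normal")
  expect_equal(classify_albuminuria(c(3.5, 2.9, 4.0)), "normal")
  expect_equal(classify_albuminuria(c(29.9, 30.0)), "normal")  # 30 out of band
  co <- make_subject_cohort(base_subject(1), std_readings(1, uacr = 4))
  expect_equal(apply_eligibility(co)$cohort$subjects$albuminuria, "low_level")
})

test_that("kidney progression detection finds the earliest component", {
  # 44/90: 51.1% decline qualifies for the primary composite
  ev <- detect_kidney_progression(c(200, 500), c(70, 44), 90)
  expect_equal(ev, list(day = 500, type = "decline50"))
  # 54/90 is exactly 40%: no primary event, secondary threshold inclusive
  expect_null(detect_kidney_progression(500, 54, 90))
  ev40 <- detect_kidney_progression(500, 54, 90, decline_threshold = 0.4)
  expect_equal(ev40, list(day = 500, type = "decline40"))
  # sustained eGFR < 15: two consecutive readings spanning >= 90 days,
  # event at the second reading
  ev_eskd <- detect_kidney_progression(c(100, 200), c(14, 13), 25)
  expect_equal(ev_eskd, list(day = 200, type = "eskd"))
  expect_null(detect_kidney_progression(c(100, 150), c(14, 13), 25))
  # kidney-related death is a component; earliest component wins
  ev_kd <- detect_kidney_progression(c(500), c(40), 90, death_day = 300,
                                     kidney_related_death = TRUE)
  expect_equal(ev_kd$type, "kidney_death")
  expect_equal(ev_kd$day, 300)
  expect_error(detect_kidney_progression(1, 1, 0), "baseline")
})

test_that("follow-up resolution takes the earliest exit", {
  # event before GLP-1 start
  r <- resolve_followup(0, event = list(day = 200, type = "decline50"),
                        glp1_day = 300)
  expect_equal(r$exit_day, 200)
  expect_equal(r$status, 1L)
  # GLP-1 start before the event censors
  r2 <- resolve_followup(0, event = list(day = 200, type = "decline50"),
                         glp1_day = 100)
  expect_equal(r2$exit_day, 100)
  expect_equal(r2$status, 0L)
  expect_equal(r2$censor_reason, "glp1_start")
  # administrative horizon: 3 x 365.25 days
  r3 <- resolve_followup(0, horizon_years = 3)
  expect_equal(r3$exit_day, 1095.75)
  expect_equal(r3$censor_reason, "horizon")
  expect_equal(r3$followup_years, 3)
  r5 <- resolve_followup(0, horizon_years = 5)
  expect_equal(r5$exit_day, 1826.25)
  expect_error(resolve_followup(0, event = list(day = -1, type = "x"),
                                study_end_day = -5), "exit")
})

test_that("crossover creates two non-overlapping episodes", {
  subs <- rbind(
    base_subject(1, arm = "comparator", comparator_drug = "dpp4i",
                 crossover_day = 400),
    base_subject(2),                                  # SGLT2i only
    base_subject(3, arm = "comparator", comparator_drug = "su"))
  rd <- rbind(std_readings(1), std_readings(2), std_readings(3))
  co <- make_subject_cohort(subs, rd)
  ep <- build_episodes(co)
  e1 <- ep[ep$subject_id == 1, ]
  expect_equal(nrow(e1), 2)
  expect_equal(e1$arm, c("comparator", "sglt2i"))
  expect_equal(e1$entry_day, c(0, 400))
  expect_equal(e1$exit_day[1], 400)
  expect_equal(e1$censor_reason[1], "crossover")
  expect_equal(e1$exit_day[2], 400 + 1095.75)
  # non-overlap and per-subject person-time additivity
  expect_true(all(e1$exit_day > e1$entry_day))
  expect_equal(sum(e1$followup_years),
               (e1$exit_day[2] - 0) / 365.25)
  expect_equal(nrow(ep[ep$subject_id == 2, ]), 1)
  # comparator without crossover: single episode to horizon
  e3 <- ep[ep$subject_id == 3, ]
  expect_equal(nrow(e3), 1)
  expect_equal(e3$censor_reason, "horizon")
  # SGLT2i start on/before a comparator start is rejected
  bad <- make_subject_cohort(base_subject(4, arm = "comparator",
                                          crossover_day = 0),
                             std_readings(4))
  expect_error(build_episodes(bad), "rejected")
})

test_that("episode events respect the within-episode baseline", {
  # decline relative to the re-resolved baseline at crossover entry
  subs <- base_subject(1, arm = "comparator", crossover_day = 400)
  rd <- rbind(std_readings(1, egfr = 90),
              data.frame(id = 1, day = c(300, 600), measure = "egfr",
                         value = c(88, 43)))
  co <- make_subject_cohort(subs, rd)
  ep <- build_episodes(co)
  # episode 2 baseline is the day-300 reading (88); 43 <= 44 qualifies
  e2 <- ep[ep$episode == 2, ]
  expect_equal(e2$status, 1L)
  expect_equal(e2$exit_day, 600)
  expect_equal(e2$event_type, "decline50")
})

test_that("pairwise mode labels episodes by drug class for head-to-head fits", {
  co <- cached_cohort(50000, 101)
  ep <- build_episodes(apply_eligibility(co)$cohort, mode = "pairwise")
  expect_true(all(ep$arm_drug %in% c("sglt2i", "dpp4i", "su")))
  expect_true(all(ep$arm_drug[ep$arm == "sglt2i"] == "sglt2i"))
  # comparator class split roughly reflects the configured DPP4i share
  cmp <- ep$arm_drug[ep$arm == "comparator"]
  expect_gt(mean(cmp == "dpp4i"), 0.55)
  expect_lt(mean(cmp == "dpp4i"), 0.67)
  # head-to-head sensitivity fit: SGLT2i vs DPP4i only
  sub <- ep[ep$arm_drug %in% c("sglt2i", "dpp4i"), ]
  covs <- full_covariate_set(sub)
  ps <- fit_propensity(sub, covariates = covs)
  fit <- suppressWarnings(fit_weighted_cox(sub,
    weights = overlap_weights(ps)$weights, covariates = covs))
  b <- fit$coefficients["arm"]; se <- sqrt(fit$var_robust["arm", "arm"])
  expect_lt(abs(b - log(0.62)), 2.6 * se)
})

test_that("event, exclusion and person-time bookkeeping are consistent", {
  co <- cached_cohort(20000, 77)
  el <- apply_eligibility(co)
  ep <- build_episodes(el$cohort)
  expect_true(all(ep$exit_day > ep$entry_day))
  expect_true(all(ep$followup_years <= 3 + 1e-9))
  expect_true(all(table(ep$subject_id) <= 2))
  # episodes of a subject never overlap
  two <- ep[ep$subject_id %in% ep$subject_id[duplicated(ep$subject_id)], ]
  if (nrow(two)) {
    by_id <- split(two, two$subject_id)
    expect_true(all(vapply(by_id, function(x)
      x$exit_day[1] <= x$entry_day[2], TRUE)))
  }
  # events only at or before exit, with a recorded type
  expect_true(all(!is.na(ep$event_type[ep$status == 1])))
  expect_true(all(is.na(ep$censor_reason[ep$status == 1])))
})
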