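test_that("the fitter matches a brute-force partial-likelihood maximizer", {
  # printed 3-record example: beta-hat = -ln(2)/2
  ep <- mini_episodes(time = c(1, 2, 3), status = c(1, 1, 1), arm = c(1, 0, 1))
  fit <- fit_weighted_cox(ep)
  expect_equal(unname(fit$coefficients["arm"]), -log(2) / 2, tolerance = 1e-6)
  expect_equal(exp(unname(fit$coefficients["arm"])), 1 / sqrt(2),
               tolerance = 1e-6)
  bf <- oracle_cox_beta(ep$followup_years, ep$status,
                        as.numeric(ep$arm == "sglt2i"))
  expect_equal(unname(fit$coefficients["arm"]), bf, tolerance = 1e-6)
  # weight-scale invariance: all weights doubled leave the estimate alone
  fit2 <- fit_weighted_cox(ep, weights = rep(2, 3))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)
  # oracle equivalence on random small weighted datasets (untied times)
  set.seed(11)
  for (r in 1:10) {
    n <- sample(5:10, 1)
    d <- mini_episodes(time = sort(runif(n, 0.1, 3)) + seq_len(n) * 1e-4,
                       status = rbinom(n, 1, 0.8), arm = rbinom(n, 1, 0.5))
    if (sum(d$status) == 0 || length(unique(d$arm)) < 2) next
    w <- runif(n, 0.5, 2)
    f <- tryCatch(fit_weighted_cox(d, weights = w), warning = function(w) NULL)
    if (is.null(f)) next  # monotone likelihood: oracle unbounded too
    bf <- oracle_cox_beta(d$followup_years, d$status,
                          as.numeric(d$arm == "sglt2i"), w)
    if (abs(bf) > 9) next
    expect_equal(unname(f$coefficients["arm"]), bf, tolerance = 1e-5)
  }
  expect_error(fit_weighted_cox(mini_episodes(1:3, c(0, 0, 0), c(1, 0, 1))),
               "no events")
})

test_that("baseline survival follows the Breslow construction", {
  # beta fixed at 0 by symmetry: two pairs with identical outcomes per arm
  ep <- mini_episodes(time = c(1, 1, 2, 2), status = c(1, 1, 0, 0),
                      arm = c(1, 0, 1, 0))
  fit <- fit_weighted_cox(ep)
  expect_equal(unname(fit$coefficients["arm"]), 0, tolerance = 1e-8)
  # at t = 1: two events among four at risk -> Lambda0 = 2/4 (Efron equals
  # Breslow here because the tied subjects fail from the same risk set in
  # the hand calculation below)
  # one event at t=1 among 2 at risk with the coefficient held at zero:
  # Lambda0(1) = 1/2, S0(1) = exp(-1/2)
  ep1 <- mini_episodes(time = c(1, 2), status = c(1, 0), arm = c(1, 0))
  fit1 <- suppressWarnings(fit_weighted_cox(ep1, init = 0, iter_max = 0))
  expect_equal(unname(fit1$coefficients["arm"]), 0)
  expect_equal(baseline_survival(fit1, 0), 1)
  expect_equal(baseline_survival(fit1, 1), exp(-1 / 2), tolerance = 1e-8)
  # monotone non-increasing, warns beyond follow-up
  ts <- c(0, 0.5, 1, 1.5, 2)
  s <- baseline_survival(fit1, ts)
  expect_true(all(diff(s) <= 1e-12))
  expect_warning(baseline_survival(fit1, 10), "beyond")
})

test_that("survival predictions obey the proportional-hazards identity", {
  co <- cached_cohort(20000, 77)
  ep <- build_episodes(apply_eligibility(co)$cohort)
  covs <- c("age", "egfr", "log_uacr", "hba1c")
  fit <- fit_weighted_cox(ep, covariates = covs)
  sub <- ep[1:50, ]
  s_ctl <- predict_survival(fit, sub, arm = 0, t = 3)
  s_trt <- predict_survival(fit, sub, arm = 1, t = 3)
  hr <- exp(unname(fit$coefficients["arm"]))
  expect_equal(s_trt, s_ctl^hr, tolerance = 1e-10)
  # the centering profile reproduces the baseline survival
  ref <- sub[1, ]
  ref$age <- fit$centers["age"]; ref$egfr <- fit$centers["egfr"]
  ref$uacr <- exp(fit$centers["log_uacr"]); ref$hba1c <- fit$centers["hba1c"]
  expect_equal(predict_survival(fit, ref, arm = 0, t = 3),
               baseline_survival(fit, 3), tolerance = 1e-10)
  # survival decreases with the linear predictor at fixed t
  lp <- kidneybenefit:::cox_lp(fit, sub, arm = 0)
  expect_true(all(diff(s_ctl[order(lp)]) <= 1e-12))
})

test_that("the spline basis matches the restricted cubic form", {
  expect_equal(unname(rcs_basis(1, c(0, 1, 2))[, "nl"]), 1 / 4)
  expect_equal(unname(rcs_basis(-3, c(0, 1, 2))[, "nl"]), 0)
  expect_equal(unname(rcs_basis(0, c(0, 1, 2))[, "nl"]), 0)
  # linear beyond the last knot: second differences vanish
  x <- seq(3, 6, by = 0.5)
  nl <- rcs_basis(x, c(0, 1, 2))[, "nl"]
  expect_equal(max(abs(diff(diff(nl)))), 0, tolerance = 1e-10)
  expect_equal(unname(rcs_basis(1.5, c(0, 1, 2))[, "lin"]), 1.5)
  expect_error(rcs_basis(1, c(0, 0, 2)), "strictly increasing")
})

test_that("Wald interaction tests behave at the null and under effect", {
  # coefficient block exactly zero with identity covariance: p = 1
  fake <- list(coefficients = c(a = 0, b = 0), var_robust = diag(2))
  dimnames(fake$var_robust) <- list(c("a", "b"), c("a", "b"))
  expect_equal(interaction_test(fake, c("a", "b"))$p, 1)
  expect_error(interaction_test(fake, "zz"), "not in fit")
  sing <- list(coefficients = c(a = 1, b = 1),
               var_robust = matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(interaction_test(sing, c("a", "b")), "singular")

  # type-I error near nominal when no effect modification exists
  rej <- 0; reps <- 30
  for (r in 1:30) {
    cfg <- synthetic_config(n_subjects = 6000, seed = 500 + r, baseline_rate = 30)
    co <- simulate_outcomes(assign_treatment(generate_cohort(cfg)))
    ep <- build_episodes(apply_eligibility(co)$cohort)
    armn <- as.numeric(ep$arm == "sglt2i")
    alb <- as.numeric(ep$albuminuria == "low_level")
    fit <- fit_weighted_cox(ep, extra_terms = data.frame(alb = alb,
                                                         arm_alb = armn * alb))
    if (interaction_test(fit, "arm_alb")$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.2)

  # power: a strong simulated interaction is detected
  rej_pow <- 0
  for (r in 1:5) {
    cfg <- synthetic_config(n_subjects = 20000, seed = 600 + r, baseline_rate = 30)
    co <- assign_treatment(generate_cohort(cfg))
    cfg2 <- cfg; cfg2$true_log_hr <- 0   # build outcomes manually below
    co <- simulate_outcomes(co)
    ep <- build_episodes(apply_eligibility(co)$cohort)
    # regenerate event status with a treatment effect only in albuminuric
    # subjects: HR 0.4 vs 1.0 (approximated by thinning treated events)
    armn <- as.numeric(ep$arm == "sglt2i")
    alb <- as.numeric(ep$albuminuria == "low_level")
    set.seed(700 + r)
    thin <- armn == 1 & alb == 1 & ep$status == 1 & runif(nrow(ep)) > 0.4
    ep$status[thin] <- 0
    fit <- fit_weighted_cox(ep, extra_terms = data.frame(alb = alb,
                                                         arm_alb = armn * alb))
    if (interaction_test(fit, "arm_alb")$p < 0.05) rej_pow <- rej_pow + 1
  }
  expect_gte(rej_pow, 4)
})

test_that("robust variance approximates the bootstrap on clustered data", {
  cfg <- synthetic_config(n_subjects = 2000, seed = 888, baseline_rate = 60)
  co <- simulate_outcomes(assign_treatment(generate_cohort(cfg)))
  ep <- build_episodes(apply_eligibility(co)$cohort)
  fit <- fit_weighted_cox(ep, covariates = c("age", "hba1c"))
  se_robust <- sqrt(fit$var_robust["arm", "arm"])
  set.seed(99)
  ids <- unique(ep$subject_id)
  bs <- replicate(120, {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(lapply(take, function(i) which(ep$subject_id == i)))
    f <- tryCatch(suppressWarnings(
      fit_weighted_cox(ep[idx, ], covariates = c("age", "hba1c"))),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else unname(f$coefficients["arm"])
  })
  expect_lt(abs(se_robust - sd(bs, na.rm = TRUE)) / sd(bs, na.rm = TRUE), 0.2)
})

test_that("permuted arm labels recover the null hazard ratio", {
  co <- cached_cohort(20000, 77)
  ep <- build_episodes(apply_eligibility(co)$cohort)
  set.seed(5)
  cover <- 0
  for (r in 1:10) {
    ep$arm_perm <- sample(ep$arm)
    f <- fit_weighted_cox(ep, treatment_col = "arm_perm")
    ci <- f$coefficients["arm"] + c(-1.96, 1.96) * sqrt(f$var_robust["arm", "arm"])
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 8)
})
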