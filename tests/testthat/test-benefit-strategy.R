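test_that("pARR arithmetic follows S0^HR - S0", {
  expect_equal(predict_parr(0.99, 0.62), 0.99^0.62 - 0.99)
  expect_equal(predict_parr(0.99, 0.62), 0.003787, tolerance = 1e-3)
  expect_equal(predict_parr(0.90, 0.62), 0.0368, tolerance = 1e-3)
  expect_equal(predict_parr(c(0.5, 0.9, 0.99), 1), c(0, 0, 0))
  expect_error(predict_parr(0, 0.62), "s0")
  expect_error(predict_parr(0.9, -1), "hr")
  # increasing in baseline risk for hr < 1; decreasing in hr for fixed S0
  s0_grid <- seq(0.80, 0.999, by = 0.001)
  expect_true(all(diff(predict_parr(s0_grid, 0.62)) < 0))
  hr_grid <- seq(0.3, 0.99, by = 0.01)
  expect_true(all(diff(predict_parr(0.95, hr_grid)) < 0))
})

test_that("counterfactual ARRs standardize the fitted Cox model", {
  co <- cached_cohort(20000, 77)
  ep <- build_episodes(apply_eligibility(co)$cohort)
  covs <- full_covariate_set(ep)
  ps <- fit_propensity(ep, covariates = covs)
  w <- overlap_weights(ps)$weights
  # rare ethnicity categories can carry zero events at this n: the fitter
  # flags the unbounded coefficient but the treatment estimate is unaffected
  fit <- suppressWarnings(fit_weighted_cox(ep, weights = w, covariates = covs))
  carr <- counterfactual_arr(fit, ep)
  s0 <- predict_survival(fit, ep, arm = 0, t = 3)
  hr <- exp(unname(fit$coefficients["arm"]))
  # consistency with the pARR identity applied to the fitted model
  expect_equal(carr, s0^hr - s0, tolerance = 1e-12)
  # a null treatment coefficient gives zero ARR everywhere
  fit0 <- fit
  fit0$coefficients["arm"] <- 0
  expect_equal(counterfactual_arr(fit0, ep[1:20, ]), rep(0, 20))
  # mean estimated ARR tracks the generator's latent truth
  lat <- co$latent[match(ep$subject_id, co$latent$id), ]
  expect_lt(abs(mean(carr) - mean(lat$true_arr)), 0.5 * mean(lat$true_arr))
})

test_that("benefit calibration slope responds linearly", {
  set.seed(1)
  parr <- runif(5000, 0.001, 0.02)
  # identity: slope 1, decile means on the diagonal (suppress the
  # perfect-fit note from the least-squares summary)
  bc <- suppressWarnings(benefit_calibration(parr, parr))
  expect_equal(bc$slope, 1, tolerance = 1e-10)
  expect_equal(bc$decile_table$carr_mean, bc$decile_table$parr_median,
               tolerance = 0.15 * mean(parr))
  # doubling: slope 2
  bc2 <- suppressWarnings(benefit_calibration(parr, 2 * parr))
  expect_equal(bc2$slope, 2, tolerance = 1e-10)
  # deciles partition the cohort
  expect_equal(sum(bc$decile_table$n), length(parr))
  expect_warning(benefit_calibration(rep(0.01, 20), rep(0.01, 20)),
                 "distinct")
})

test_that("the pARR threshold treats the requested population share", {
  v <- c(0.001, 0.002, 0.003, 0.004)
  th <- threshold_for_fraction(v, 0.25)
  expect_equal(th$delta, 0.004)
  expect_equal(th$treated_fraction, 0.25)
  expect_equal(threshold_for_fraction(v, 1)$delta, 0.001)
  # ties handled deterministically: fraction never exceeds the target
  vt <- c(1, 2, 2, 2, 3) / 100
  tht <- threshold_for_fraction(vt, 0.5)
  expect_lte(tht$treated_fraction, 0.5)
  expect_error(threshold_for_fraction(numeric(0), 0.5), "empty")
  expect_error(threshold_for_fraction(v, 0), "target_fraction")
  # matching the albuminuria-threshold share equalises treated counts
  co <- cached_cohort(20000, 77)
  ep <- build_episodes(apply_eligibility(co)$cohort)
  pr <- predict_risk3y(default_risk_score(), ep)
  parr <- predict_parr(pr$surv3y, 0.62)
  target <- mean(ep$uacr >= 3)
  th2 <- threshold_for_fraction(parr, target)
  expect_equal(sum(parr >= th2$delta), sum(ep$uacr >= 3))
})

test_that("strategy outcomes match the closed-form expectations", {
  # 1000 treated subjects at S0 = 0.99, HR 0.62
  s0 <- rep(0.99, 1000)
  st <- strategy_outcomes(s0, rep(TRUE, 1000), 0.62, "all")
  expect_equal(st$events_prevented, 1000 * (0.99^0.62 - 0.99))
  expect_equal(st$events_prevented, 3.787, tolerance = 1e-3)
  expect_equal(st$tp_per_100k / 1e5 * 1000, 1000 * (1 - 0.99^0.62))
  expect_equal(st$tp_per_100k, 100 * 1000 * (1 - 0.99^0.62))
  # treat nobody: nothing prevented, TN = sum of survivals
  st0 <- strategy_outcomes(s0, rep(FALSE, 1000), 0.62, "none")
  expect_equal(st0$events_prevented, 0)
  expect_equal(st0$tn_per_100k, 0.99 * 1e5)
  # treat-all minus treat-none equals the summed pARR (telescoping)
  set.seed(2)
  s0r <- runif(500, 0.9, 0.999)
  all_ <- strategy_outcomes(s0r, rep(TRUE, 500), 0.62)
  none <- strategy_outcomes(s0r, rep(FALSE, 500), 0.62)
  expect_equal(all_$events_prevented - none$events_prevented,
               sum(predict_parr(s0r, 0.62)))
  # invariant to subject ordering
  o <- sample(500)
  st_perm <- strategy_outcomes(s0r[o], rep(TRUE, 500)[o], 0.62)
  expect_equal(st_perm$events_prevented, all_$events_prevented)
  expect_error(strategy_outcomes(s0, rep(TRUE, 1000), hr = 0), "hr")
})

test_that("the pARR rule maximizes events prevented among equal-size sets", {
  # exhaustive check over all treated subsets of size k, n <= 12
  set.seed(3)
  for (r in 1:5) {
    n <- sample(8:12, 1)
    s0 <- runif(n, 0.85, 0.999)
    parr <- predict_parr(s0, 0.62)
    k <- sample(2:(n - 2), 1)
    thr <- sort(parr, decreasing = TRUE)[k]
    rule <- parr >= thr
    best <- strategy_outcomes(s0, rule, 0.62)$events_prevented
    subsets <- utils::combn(n, k)
    prevented <- apply(subsets, 2, function(idx) {
      treat <- rep(FALSE, n); treat[idx] <- TRUE
      strategy_outcomes(s0, treat, 0.62)$events_prevented
    })
    expect_equal(sum(rule), k)
    expect_lte(max(prevented), best + 1e-12)
  }
})

test_that("decision curves follow the net-benefit definition", {
  # hand example: ARR (0.004, 0.002), rule treats the first, delta 0.003
  dc <- decision_curve(c(0.004, 0.002), delta_grid = 0.003,
                       rules = list(first_only = c(TRUE, FALSE)))
  nb <- dc$net_benefit[dc$strategy == "first_only"]
  expect_equal(nb, 0.004 / 2 - 0.003 * 0.5)
  # treat-all at delta 0 equals the mean ARR; treat-none is always zero
  dc0 <- decision_curve(c(0.004, 0.002), delta_grid = c(0, 0.001, 0.01))
  expect_equal(dc0$net_benefit[dc0$strategy == "treat_all" & dc0$delta == 0],
               mean(c(0.004, 0.002)))
  expect_true(all(dc0$net_benefit[dc0$strategy == "treat_none"] == 0))
  # on model-consistent predictions the threshold rule dominates both
  # reference strategies at every threshold
  set.seed(4)
  arr <- runif(2000, 0, 0.02)
  grid <- seq(0, 0.025, by = 0.0025)
  dcb <- decision_curve(arr, grid)
  for (d in grid) {
    nb_thr <- dcb$net_benefit[dcb$strategy == "parr_threshold" & dcb$delta == d]
    nb_all <- dcb$net_benefit[dcb$strategy == "treat_all" & dcb$delta == d]
    expect_gte(nb_thr, max(nb_all, 0) - 1e-12)
  }
  expect_error(decision_curve(arr, -0.1), "thresholds")
})

test_that("subgroup observed ARRs separate high- and low-benefit groups", {
  # identical arms: ARR ~ 0 (duplicate every subject into both arms)
  co <- cached_cohort(20000, 77)
  ep <- build_episodes(apply_eligibility(co)$cohort)
  ep1 <- ep[ep$episode == 1, ]
  mirror <- ep1
  mirror$arm <- ifelse(ep1$arm == "sglt2i", "comparator", "sglt2i")
  mirror$subject_id <- mirror$subject_id + 1e6
  sym <- rbind(ep1, mirror)
  res0 <- extended_observed_arr(sym, rep("all", nrow(sym)), t_years = 3,
                                covariates = c("age", "hba1c"))
  expect_lt(abs(res0$table$arr), 1e-6)
  # true-benefit tertiles: the observed ARR of the top tertile exceeds the
  # bottom tertile, consistent with the generator's latent truth
  cob <- cached_cohort(50000, 101)
  epb <- build_episodes(apply_eligibility(cob)$cohort)
  epb1 <- epb[epb$episode == 1, ]
  lat <- cob$latent[match(epb1$subject_id, cob$latent$id), ]
  ter <- cut(lat$true_arr, quantile(lat$true_arr, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  res <- suppressWarnings(extended_observed_arr(epb1, as.character(ter),
    t_years = 3, covariates = c("age", "hba1c", "egfr", "log_uacr")))
  tab <- res$table[match(c("low", "high"), res$table$subgroup), ]
  truth <- tapply(lat$true_arr, ter, mean)
  expect_true(truth[["high"]] > truth[["low"]])
  expect_true(tab$arr[2] > tab$arr[1])
})
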