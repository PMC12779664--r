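#' Run the four-step benefit-prediction pipeline end to end
#'
#' Orchestrates: synthetic cohort generation (or ingestion of cohort CSVs)
#' -> eligibility and episode construction -> multiple imputation ->
#' propensity weighting with balance diagnostics -> step 1 (overlap-
#' weighted doubly robust relative effect, with albuminuria and spline
#' risk-score interaction tests) -> step 2 (risk-score calibration, Brier,
#' C statistic) -> step 3 (pARR and benefit calibration against
#' counterfactual ARRs) -> step 4 (strategy comparison and decision
#' curves). Writes CSV/JSON reports, a run log, and a checksum manifest.
#' All randomness derives from `seed` via [stage_seed()].
#'
#' @param config list (see [read_config()]) with optional entries:
#'   `n_subjects`, `seed`, `horizon_years`, `weighting`
#'   (`"overlap"`, `"iptw"` or `"none"`), `m_imputations`,
#'   `imputation_iterations`, `hr_applied`, `target_fraction` (`NULL` =
#'   match the albuminuria rule), `delta_grid`, `n_bootstrap`, `out_dir`,
#'   `input_dir` (read cohort instead of simulating), `missingness`
#'   (logical: inject/keep missingness)
#' @return invisible list of all stage results
#' @export
run_pipeline <- function(config = list()) {
  cfg <- config
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% "kb_pipeline_out"
  horizon <- cfg$horizon_years %||% 3
  weighting <- cfg$weighting %||% "overlap"
  m <- cfg$m_imputations %||% 10
  hr_applied <- cfg$hr_applied %||% 0.62
  n_boot <- cfg$n_bootstrap %||% 500
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat(sprintf("kidneybenefit %s | R %s | seed %d\n",
              as.character(utils::packageVersion("kidneybenefit")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.integer(seed)), file = logf)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    log_line("stage %-12s ok", name)
    res
  }

  # --- generate or ingest -------------------------------------------------
  cohort <- stage("ingest", {
    if (!is.null(cfg$input_dir)) {
      read_cohort(cfg$input_dir)
    } else {
      sc_args <- cfg$synthetic %||% list()
      sc_args$n_subjects <- cfg$n_subjects %||% sc_args$n_subjects %||% 20000L
      sc_args$seed <- seed
      sc_args$horizon_years <- max(horizon, 3)
      sc <- do.call(synthetic_config, sc_args)
      co <- simulate_outcomes(assign_treatment(generate_cohort(sc)))
      if (isTRUE(cfg$missingness %||% TRUE)) co <- inject_missingness(co)
      write_cohort(co, file.path(out_dir, "cohort"))
      co
    }
  })

  # --- eligibility and episodes ------------------------------------------
  elig <- stage("eligibility", apply_eligibility(cohort))
  write.csv(elig$counts, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  episodes <- stage("episodes", build_episodes(elig$cohort,
                                               horizon_years = horizon))
  write.csv(episodes[c("subject_id", "episode", "arm", "entry_day", "exit_day",
                       "followup_years", "status", "event_type", "censor_reason")],
            file.path(out_dir, "episodes.csv"), row.names = FALSE)

  # --- imputation ---------------------------------------------------------
  imp_vars <- c("imd_quintile", "height", "weight", "bmi", "sbp", "total_chol",
                "hba1c", "diabetes_duration", "smoking")
  any_missing <- anyNA(episodes[intersect(imp_vars, names(episodes))])
  stacks <- stage("impute", {
    if (any_missing) {
      chained_impute(episodes, m = m,
                     iterations = cfg$imputation_iterations %||% 10,
                     seed = stage_seed(seed, 10L))$datasets
    } else list(episodes)
  })
  m_eff <- length(stacks)

  spec <- cfg$risk_spec %||% default_risk_score()
  covs <- full_covariate_set(stacks[[1]])

  per_imp <- vector("list", m_eff)
  for (i in seq_len(m_eff)) {
    d <- stacks[[i]]
    ps <- fit_propensity(d, covariates = covs)
    w <- switch(weighting,
                overlap = overlap_weights(ps)$weights,
                iptw = iptw_weights(ps)$weights,
                none = rep(1, nrow(d)),
                stopf("configuration error: unknown weighting '%s'", weighting))
    bal <- balance_table(d, weights = w, covariates = covs)
    dr <- fit_weighted_cox(d, weights = w, covariates = covs)

    # interaction tests: albuminuria status and spline of the risk-score LP
    alb <- as.numeric(d$albuminuria == "low_level")
    armn <- as.numeric(d$arm == "sglt2i")
    it_alb <- fit_weighted_cox(d, weights = w, covariates = covs,
      extra_terms = data.frame(alb = alb, arm_alb = armn * alb))
    p_alb <- interaction_test(it_alb, "arm_alb")$p
    lp <- linear_predictor(spec, d)
    kn <- unname(quantile(lp, c(0.1, 0.5, 0.9)))
    rb <- rcs_basis(lp, kn)
    it_rcs <- fit_weighted_cox(d, weights = w, covariates = covs,
      extra_terms = data.frame(rs_lin = rb[, "lin"], rs_nl = rb[, "nl"],
                               arm_lin = armn * rb[, "lin"],
                               arm_nl = armn * rb[, "nl"]))
    p_rcs_overall <- interaction_test(it_rcs, c("arm_lin", "arm_nl"))$p
    p_rcs_nl <- interaction_test(it_rcs, "arm_nl")$p
    p_rcs_lin <- interaction_test(it_rcs, "arm_lin")$p

    # step 2: score performance on comparator-arm episodes
    cmp <- d[d$arm == "comparator", ]
    pr_cmp <- predict_risk3y(spec, cmp)
    cal <- calibration_assess(pr_cmp$lp, pr_cmp$risk3y, cmp,
                              t_years = min(horizon, 3))
    bsn <- if (i == 1) n_boot else 0
    br <- brier_score(pr_cmp$risk3y, cmp, t_years = min(horizon, 3),
                      n_bootstrap = bsn, seed = stage_seed(seed, 20L))
    cs <- c_statistic(pr_cmp$lp, cmp, n_bootstrap = bsn,
                      seed = stage_seed(seed, 21L))

    # step 3: pARR and benefit calibration
    pr_all <- predict_risk3y(spec, d)
    parr <- predict_parr(pr_all$surv3y, hr_applied)
    carr <- counterfactual_arr(dr, d, t_years = min(horizon, 3))
    bc <- benefit_calibration(parr, carr, hr_applied = hr_applied)

    per_imp[[i]] <- list(ps = ps, weights = w, balance = bal, dr = dr,
                         p_alb = p_alb, p_rcs_overall = p_rcs_overall,
                         p_rcs_nl = p_rcs_nl, p_rcs_lin = p_rcs_lin,
                         cal = cal, brier = br$brier, cstat = cs$c,
                         cstat_var = cs$se^2, parr = parr, carr = carr,
                         bc = bc, d = d)
  }
  res1 <- stage("fit", {
    loghr <- vapply(per_imp, function(x) x$dr$coefficients["arm"], 0)
    vhr <- vapply(per_imp, function(x) x$dr$var_robust["arm", "arm"], 0)
    pool_rubin(loghr, vhr)
  })
  hr_tab <- data.frame(term = "arm", log_hr = res1$estimate,
                       hr = exp(res1$estimate),
                       hr_lower = exp(res1$ci[1]), hr_upper = exp(res1$ci[2]),
                       p_interaction_albuminuria = mean(vapply(per_imp, `[[`, 0, "p_alb")),
                       p_interaction_rcs_overall = mean(vapply(per_imp, `[[`, 0, "p_rcs_overall")),
                       p_interaction_rcs_nonlinear = mean(vapply(per_imp, `[[`, 0, "p_rcs_nl")),
                       p_interaction_rcs_linear = mean(vapply(per_imp, `[[`, 0, "p_rcs_lin")))
  write.csv(hr_tab, file.path(out_dir, "relative_effect.csv"), row.names = FALSE)
  write.csv(per_imp[[1]]$balance, file.path(out_dir, "balance.csv"),
            row.names = FALSE)

  res2 <- stage("calibrate", {
    slope <- pool_rubin(vapply(per_imp, function(x) x$cal$slope, 0),
                        vapply(per_imp, function(x) x$cal$slope_se^2, 0))
    cstat <- pool_rubin(vapply(per_imp, `[[`, 0, "cstat"),
                        vapply(per_imp, `[[`, 0, "cstat_var"))
    list(slope = slope, cstat = cstat,
         citl = mean(vapply(per_imp, function(x) x$cal$citl, 0)),
         brier = mean(vapply(per_imp, `[[`, 0, "brier")))
  })
  jsonlite::write_json(list(
    calibration_slope = res2$slope$estimate,
    calibration_slope_ci = res2$slope$ci,
    calibration_in_the_large = res2$citl,
    brier = res2$brier, c_statistic = res2$cstat$estimate),
    file.path(out_dir, "score_calibration.json"), auto_unbox = TRUE, digits = NA)
  write.csv(per_imp[[1]]$cal$group_table,
            file.path(out_dir, "score_calibration_deciles.csv"), row.names = FALSE)

  res3 <- stage("benefit", {
    slope <- pool_rubin(vapply(per_imp, function(x) x$bc$slope, 0),
                        vapply(per_imp, function(x) x$bc$slope_se^2, 0))
    list(slope = slope, report = per_imp[[1]]$bc,
         median_parr = median(per_imp[[1]]$parr))
  })
  write.csv(res3$report$decile_table, file.path(out_dir, "benefit_deciles.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(benefit_slope = res3$slope$estimate,
                            benefit_slope_ci = res3$slope$ci,
                            median_parr = res3$median_parr,
                            hr_applied = hr_applied),
                       file.path(out_dir, "benefit_calibration.json"),
                       auto_unbox = TRUE, digits = NA)

  res4 <- stage("strategy", {
    d <- per_imp[[1]]$d
    parr <- per_imp[[1]]$parr
    s0 <- predict_risk3y(spec, d)$surv3y
    uacr_rule <- d$uacr >= 3
    target <- cfg$target_fraction %||% mean(uacr_rule)
    thr <- threshold_for_fraction(parr, target)
    strat <- rbind(
      strategy_outcomes(s0, parr >= thr$delta, hr_applied, "parr_threshold"),
      strategy_outcomes(s0, uacr_rule, hr_applied, "uacr_ge3"),
      strategy_outcomes(s0, rep(TRUE, nrow(d)), hr_applied, "treat_all"),
      strategy_outcomes(s0, rep(FALSE, nrow(d)), hr_applied, "treat_none"))
    grid <- cfg$delta_grid %||% seq(0, 0.02, by = 0.001)
    dc <- decision_curve(parr, grid, rules = list(uacr_ge3 = uacr_rule))
    list(threshold = thr, table = strat, curve = dc)
  })
  write.csv(res4$table, file.path(out_dir, "strategy_comparison.csv"),
            row.names = FALSE)
  write.csv(res4$curve, file.path(out_dir, "decision_curve.csv"),
            row.names = FALSE)

  manifest <- stage("manifest", {
    files <- setdiff(list.files(out_dir, recursive = TRUE), "run.log")
    sums <- tools::md5sum(file.path(out_dir, files))
    data.frame(file = files, md5 = unname(sums), stringsAsFactors = FALSE)
  })
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  invisible(list(cohort = cohort, eligibility = elig, episodes = episodes,
                 per_imputation = per_imp, relative_effect = res1,
                 hr_table = hr_tab, score = res2, benefit = res3,
                 strategy = res4, manifest = manifest, out_dir = out_dir))
}
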