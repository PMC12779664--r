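#' Assess calibration of a risk score on time-to-event data
#'
#' Fits a Cox proportional hazards model with the score's linear predictor
#' as the only variable: the coefficient is the calibration slope (1 means
#' neither over- nor under-fitting; multiplying the LP by c divides the
#' slope by c). Calibration-in-the-large is the ratio of observed
#' Kaplan-Meier event-free survival at the horizon to the mean predicted
#' survival. A decile table compares mean predicted risk with the
#' Kaplan-Meier observed risk within predicted-risk deciles. By default
#' the score is assessed on comparator-arm episodes only, since it
#' predicts untreated natural history.
#'
#' @param lp risk-score linear predictors, aligned with `episodes`
#' @param pred_risk predicted risks at `t_years` (same alignment)
#' @param episodes episode data frame with `followup_years` and `status`
#' @param t_years assessment horizon (default 3)
#' @param n_groups number of risk groups (default 10; collapsed to 5 with
#'   a warning when there are fewer than 10 events)
#' @return a `calibration_report`: `slope` (+ se, ci), `citl`,
#'   `group_table`, `n`, `n_events`
#' @export
calibration_assess <- function(lp, pred_risk, episodes, t_years = 3,
                               n_groups = 10) {
  time <- episodes$followup_years
  status <- episodes$status
  n_ev <- sum(status)
  if (var(lp) == 0) {
    warnf("constant linear predictor: calibration slope is undefined")
    return(structure(list(slope = NA_real_, slope_se = NA_real_,
                          slope_ci = c(NA_real_, NA_real_), citl = NA_real_,
                          group_table = NULL, n = length(lp), n_events = n_ev,
                          degenerate = TRUE),
                     class = "calibration_report"))
  }
  if (n_ev < 10 && n_groups > 5) {
    warnf("fewer than 10 events: collapsing risk deciles to quintiles")
    n_groups <- 5
  }
  cfit <- survival::coxph(survival::Surv(time, status) ~ lp)
  slope <- unname(coef(cfit))
  slope_se <- sqrt(diag(vcov(cfit)))[1]

  km <- survival::survfit(survival::Surv(time, status) ~ 1)
  s_obs <- km_at(km, t_years)
  citl <- s_obs / mean(1 - pred_risk)

  qs <- quantile(pred_risk, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(pred_risk, unique(qs), include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    kmg <- survival::survfit(survival::Surv(time[sel], status[sel]) ~ 1)
    sg <- km_at(kmg, t_years, se = TRUE)
    data.frame(group = g, n = sum(sel),
               mean_predicted_risk = mean(pred_risk[sel]),
               observed_risk = 1 - sg$surv,
               observed_lower = 1 - sg$upper, observed_upper = 1 - sg$lower)
  })
  structure(list(slope = slope, slope_se = slope_se,
                 slope_ci = slope + c(-1.96, 1.96) * slope_se,
                 citl = citl, group_table = do.call(rbind, rows),
                 n = length(lp), n_events = n_ev, degenerate = FALSE),
            class = "calibration_report")
}

km_at <- function(km, t, se = FALSE) {
  i <- findInterval(t, km$time)
  s <- if (i == 0) 1 else km$surv[i]
  if (!se) return(s)
  if (i == 0) return(list(surv = 1, lower = 1, upper = 1))
  list(surv = s,
       lower = if (!is.null(km$lower)) km$lower[i] else NA,
       upper = if (!is.null(km$upper)) km$upper[i] else NA)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration: slope %.3f (95%% CI %.3f, %.3f), CITL %.4f, %d events / %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$citl, x$n_events, x$n))
  invisible(x)
}

#' Censoring-weighted Brier score at a horizon
#'
#' Inverse-probability-of-censoring-weighted mean squared difference
#' between the predicted event probability at `t_years` and observed
#' status: subjects with an event before `t` contribute
#' `(1 - p)^2 / G(T-)`, subjects under follow-up at `t` contribute
#' `p^2 / G(t)`, where `G` is the Kaplan-Meier censoring survival.
#'
#' @param pred_risk predicted event probabilities at `t_years`
#' @param episodes episode data frame (`followup_years`, `status`)
#' @param t_years horizon (default 3)
#' @param n_bootstrap bootstrap resamples for the CI (0 = point estimate
#'   only; 500 in the reference configuration)
#' @param seed seed for the bootstrap
#' @return list with `brier` and, when bootstrapped, `ci`
#' @export
brier_score <- function(pred_risk, episodes, t_years = 3, n_bootstrap = 0,
                        seed = 1) {
  time <- episodes$followup_years
  status <- episodes$status
  point <- ipcw_brier(pred_risk, time, status, t_years)
  out <- list(brier = point$score, n = length(pred_risk))
  if (point$max_weight > 100)
    warnf("IPCW weights exceed 100; Brier score may be unstable")
  if (n_bootstrap > 0) {
    set.seed(seed)
    bs <- replicate(n_bootstrap, {
      idx <- sample.int(length(time), replace = TRUE)
      ipcw_brier(pred_risk[idx], time[idx], status[idx], t_years)$score
    })
    out$ci <- unname(quantile(bs, c(0.025, 0.975)))
  }
  out
}

ipcw_brier <- function(p, time, status, t) {
  cens_km <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  G <- function(u) {
    i <- findInterval(u, cens_km$time)
    ifelse(i == 0, 1, pmax(cens_km$surv[pmax(i, 1)], 1e-8))
  }
  event_by_t <- time <= t & status == 1
  at_risk_t <- time > t
  w <- numeric(length(time))
  w[event_by_t] <- 1 / G(pmax(time[event_by_t] - 1e-9, 0))
  w[at_risk_t] <- 1 / G(t)
  sq <- numeric(length(time))
  sq[event_by_t] <- (1 - p[event_by_t])^2
  sq[at_risk_t] <- p[at_risk_t]^2
  list(score = sum(w * sq) / length(time), max_weight = max(w))
}

#' Harrell's C statistic for a risk score
#'
#' Probability that, of two comparable subjects, the one with the higher
#' linear predictor fails first; ties in the predictor count 1/2.
#' Computed with [survival::concordance()].
#'
#' @param lp linear predictors (higher = higher risk)
#' @param episodes episode data frame (`followup_years`, `status`)
#' @param n_bootstrap bootstrap resamples for the CI (0 = none)
#' @param seed seed for the bootstrap
#' @return list with `c`, `se` and, when bootstrapped, `ci`
#' @export
c_statistic <- function(lp, episodes, n_bootstrap = 0, seed = 1) {
  time <- episodes$followup_years
  status <- episodes$status
  if (sum(status) == 0) stopf("input error: no comparable pairs (no events)")
  cf <- survival::concordance(survival::Surv(time, status) ~ lp, reverse = TRUE)
  out <- list(c = as.numeric(cf$concordance), se = sqrt(cf$var))
  if (n_bootstrap > 0) {
    set.seed(seed)
    bs <- replicate(n_bootstrap, {
      idx <- sample.int(length(time), replace = TRUE)
      as.numeric(survival::concordance(
        survival::Surv(time[idx], status[idx]) ~ lp[idx],
        reverse = TRUE)$concordance)
    })
    out$ci <- unname(quantile(bs, c(0.025, 0.975)))
  }
  out
}
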