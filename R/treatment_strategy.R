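#' pARR threshold treating a target fraction of the population
#'
#' Returns the smallest threshold `delta` such that the fraction of
#' subjects with `parr >= delta` does not exceed `target_fraction`
#' (ties handled deterministically), so a pARR-based strategy treats a
#' population share comparable to the albuminuria-threshold strategy.
#'
#' @param parr predicted absolute risk reductions
#' @param target_fraction fraction of the population to treat, in (0, 1]
#' @return list with `delta` and the realised `treated_fraction`
#' @export
threshold_for_fraction <- function(parr, target_fraction) {
  if (!length(parr)) stopf("input error: empty pARR vector")
  if (target_fraction <= 0 || target_fraction > 1)
    stopf("input error: 'target_fraction' must be in (0, 1]")
  n <- length(parr)
  cand <- sort(unique(parr))
  frac <- vapply(cand, function(d) mean(parr >= d), 0)
  ok <- which(frac <= target_fraction)
  if (!length(ok)) return(list(delta = max(parr) * (1 + 1e-9), treated_fraction = 0))
  delta <- cand[min(ok)]
  list(delta = delta, treated_fraction = mean(parr >= delta))
}

#' Modelled outcomes of a treatment-targeting strategy
#'
#' Expected 3-year events with and without the strategy, events prevented,
#' and expected true positives/negatives per 100,000, all model-based:
#' treated subjects' expected risk is `1 - S0^HR`, untreated `1 - S0`.
#'
#' @param s0 predicted untreated event-free survival per subject
#' @param treat logical vector: does the strategy treat this subject?
#' @param hr relative treatment effect (> 0)
#' @param label strategy label
#' @return a one-row data frame: label, n, n_treated, treated_fraction,
#'   expected events with/without the strategy, events_prevented,
#'   tp_per_100k, tn_per_100k
#' @export
strategy_outcomes <- function(s0, treat, hr = 0.62, label = "strategy") {
  if (hr <= 0) stopf("input error: 'hr' must be > 0")
  stopifnot(length(s0) == length(treat))
  n <- length(s0)
  risk_trt <- 1 - s0^hr
  risk_unt <- 1 - s0
  events_without <- sum(risk_unt)
  events_with <- sum(risk_trt[treat]) + sum(risk_unt[!treat])
  data.frame(strategy = label, n = n, n_treated = sum(treat),
             treated_fraction = mean(treat),
             expected_events_no_treatment = events_without,
             expected_events_strategy = events_with,
             events_prevented = events_without - events_with,
             tp_per_100k = sum(risk_trt[treat]) / n * 1e5,
             tn_per_100k = sum(s0[!treat]) / n * 1e5,
             stringsAsFactors = FALSE)
}

#' Decision curves for treat/no-treat policies
#'
#' Net benefit of a policy at benefit threshold `delta`:
#' `NB(delta) = sum(ARR_i over treated) / N - delta * n_treated / N`,
#' the treatment-policy form of decision-curve analysis (expected benefit
#' minus threshold-weighted treatment burden). Curves are produced for
#' the pARR-threshold rule family (treat when `parr >= delta`), any
#' supplied fixed rules (e.g. the uACR >= 3 mg/mmol rule), treat-all and
#' treat-none.
#'
#' @param arr model-based expected benefit per subject (e.g. pARR)
#' @param delta_grid thresholds (>= 0) at which to evaluate net benefit
#' @param rules named list of logical treat vectors for fixed strategies
#' @param parr per-subject pARR driving the threshold rule family;
#'   defaults to `arr`
#' @return data frame: strategy, delta, net_benefit, treated_fraction
#' @export
decision_curve <- function(arr, delta_grid, rules = list(), parr = NULL) {
  if (any(delta_grid < 0)) stopf("input error: thresholds must be >= 0")
  parr <- parr %||% arr
  n <- length(arr)
  nb <- function(treat, delta)
    sum(arr[treat]) / n - delta * sum(treat) / n
  out <- list()
  for (d in delta_grid) {
    rows <- list(
      data.frame(strategy = "parr_threshold", delta = d,
                 net_benefit = nb(parr >= d, d),
                 treated_fraction = mean(parr >= d)),
      data.frame(strategy = "treat_all", delta = d,
                 net_benefit = nb(rep(TRUE, n), d), treated_fraction = 1),
      data.frame(strategy = "treat_none", delta = d,
                 net_benefit = 0, treated_fraction = 0))
    for (nm in names(rules))
      rows[[length(rows) + 1]] <- data.frame(strategy = nm, delta = d,
                                             net_benefit = nb(rules[[nm]], d),
                                             treated_fraction = mean(rules[[nm]]))
    out[[length(out) + 1]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed absolute risk reductions by subgroup in extended follow-up
#'
#' Within each subgroup, refits the propensity model, overlap weights and
#' the doubly robust Cox model, then standardizes:
#' `ARR = mean_i [S(t | x_i, treated) - S(t | x_i, control)]`. The
#' variance is a delta-method approximation propagating the treatment
#' coefficient's robust variance (covariate and baseline-hazard
#' uncertainty not propagated), giving a Wald test between two subgroups.
#'
#' @param episodes extended-horizon episode data frame
#' @param subgroup factor/character vector aligned with `episodes`
#' @param t_years horizon (default 5)
#' @param covariates adjustment covariates; default [full_covariate_set()]
#' @return list with `table` (subgroup, n, arr, se, ci) and, when exactly
#'   two subgroups are present, `difference` (estimate, se, p)
#' @export
extended_observed_arr <- function(episodes, subgroup, t_years = 5,
                                  covariates = NULL) {
  stopifnot(nrow(episodes) == length(subgroup))
  levels_ <- sort(unique(as.character(subgroup)))
  rows <- list()
  for (g in levels_) {
    sel <- subgroup == g
    sub <- episodes[sel, , drop = FALSE]
    if (length(unique(sub$arm)) < 2 || sum(sub$status) == 0) {
      warnf("subgroup '%s' skipped: one arm empty or no events", g)
      next
    }
    covs <- covariates %||% full_covariate_set(sub)
    ps <- fit_propensity(sub, covariates = covs)
    ow <- overlap_weights(ps)
    fit <- fit_weighted_cox(sub, weights = ow$weights, covariates = covs)
    s1 <- predict_survival(fit, sub, arm = 1, t = t_years)
    s0 <- predict_survival(fit, sub, arm = 0, t = t_years)
    arr <- mean(s1 - s0)
    # delta method in the treatment coefficient
    beta <- fit$coefficients["arm"]
    darr <- mean(s1 * log(pmax(s0, 1e-12)) * exp(beta))
    v <- darr^2 * fit$var_robust["arm", "arm"]
    rows[[g]] <- data.frame(subgroup = g, n = nrow(sub),
                            n_events = sum(sub$status), arr = arr,
                            se = sqrt(v), lower = arr - 1.96 * sqrt(v),
                            upper = arr + 1.96 * sqrt(v),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- list(table = tab)
  if (!is.null(tab) && nrow(tab) == 2) {
    diff <- tab$arr[1] - tab$arr[2]
    se <- sqrt(tab$se[1]^2 + tab$se[2]^2)
    out$difference <- list(estimate = diff, se = se,
                           p = 2 * pnorm(-abs(diff / se)))
  }
  out
}
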