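#' Predicted absolute risk reduction (pARR) at a fixed horizon
#'
#' `pARR = S0^HR - S0`, where `S0` is the predicted untreated event-free
#' survival at the horizon and `HR` the relative treatment effect
#' (0.62 for SGLT2 inhibitors on kidney disease progression, from the
#' trial meta-analysis).
#'
#' @param s0 predicted untreated event-free survival in (0, 1]
#' @param hr relative treatment effect (> 0)
#' @return predicted absolute risk reduction (fraction of 1)
#' @export
predict_parr <- function(s0, hr = 0.62) {
  if (any(s0 <= 0 | s0 > 1)) stopf("input error: 's0' must lie in (0, 1]")
  if (any(hr <= 0)) stopf("input error: 'hr' must be > 0")
  s0^hr - s0
}

#' Counterfactual absolute risk reductions from a doubly robust Cox fit
#'
#' Model-based standardization: for each subject,
#' `ARR_i = S(t | x_i, treated) - S(t | x_i, control)` from the fitted
#' overlap-weighted, covariate-adjusted Cox model. Group summaries of
#' these ARRs are weighted means.
#'
#' @param fit a `kb_coxfit` containing a treatment (`arm`) term
#' @param newdata subject/episode data with the fit's covariates
#' @param t_years horizon (default 3)
#' @return numeric vector of per-subject counterfactual ARRs
#' @export
counterfactual_arr <- function(fit, newdata, t_years = 3) {
  if (!"arm" %in% fit$terms)
    stopf("input error: fit has no treatment term")
  s1 <- predict_survival(fit, newdata, arm = 1, t = t_years)
  s0 <- predict_survival(fit, newdata, arm = 0, t = t_years)
  s1 - s0
}

#' Benefit calibration: pARR versus counterfactual ARR
#'
#' Compares model-predicted absolute risk reductions with counterfactual
#' ARRs estimated from the observed data: a decile table (median and IQR
#' of pARR, mean counterfactual ARR with a normal-approximation CI per
#' pARR decile, for the calibration plot) and an individual-level
#' least-squares calibration slope of counterfactual ARR on pARR
#' (intercept included). Slope 1 with decile points on the identity line
#' indicates accurate benefit prediction.
#'
#' @param parr predicted absolute risk reductions
#' @param carr counterfactual ARRs (same alignment)
#' @param weights optional weights for the slope regression
#' @param n_groups number of pARR groups (default 10; collapsed with a
#'   warning when there are fewer than 10 distinct pARR values)
#' @param hr_applied the relative effect used to build `parr` (metadata)
#' @return a `benefit_calibration_report`: `slope` (+ se, ci),
#'   `intercept`, `decile_table`, `hr_applied`
#' @export
benefit_calibration <- function(parr, carr, weights = NULL, n_groups = 10,
                                hr_applied = 0.62) {
  stopifnot(length(parr) == length(carr))
  if (length(unique(parr)) < 2) {
    warnf("fewer than 2 distinct pARR values: calibration slope undefined")
    return(structure(list(slope = NA_real_, slope_se = NA_real_,
                          slope_ci = c(NA_real_, NA_real_),
                          intercept = NA_real_,
                          decile_table = data.frame(decile = 1L,
                            n = length(parr), parr_median = median(parr),
                            parr_q1 = unname(quantile(parr, 0.25)),
                            parr_q3 = unname(quantile(parr, 0.75)),
                            carr_mean = mean(carr),
                            carr_lower = NA_real_, carr_upper = NA_real_),
                          hr_applied = hr_applied, n = length(parr)),
                     class = "benefit_calibration_report"))
  }
  if (length(unique(parr)) < n_groups) {
    warnf("fewer than %d distinct pARR values: collapsing groups", n_groups)
    n_groups <- max(1, length(unique(parr)) - 1)
  }
  w <- weights %||% rep(1, length(parr))
  fit <- lm(carr ~ parr, weights = w)
  slope <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  qs <- unique(quantile(parr, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- cut(parr, qs, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    m <- wmean(carr[sel], w[sel])
    s <- sqrt(wvar(carr[sel], w[sel]) / sum(sel))
    data.frame(decile = g, n = sum(sel),
               parr_median = median(parr[sel]),
               parr_q1 = unname(quantile(parr[sel], 0.25)),
               parr_q3 = unname(quantile(parr[sel], 0.75)),
               carr_mean = m, carr_lower = m - 1.96 * s,
               carr_upper = m + 1.96 * s)
  }))
  structure(list(slope = slope, slope_se = unname(se),
                 slope_ci = slope + c(-1.96, 1.96) * se,
                 intercept = unname(coef(fit)[1]),
                 decile_table = tab, hr_applied = hr_applied,
                 n = length(parr)),
            class = "benefit_calibration_report")
}

#' @export
print.benefit_calibration_report <- function(x, ...) {
  cat(sprintf("Benefit calibration (HR %.2f): slope %.3f (95%% CI %.3f, %.3f), n = %d\n",
              x$hr_applied, x$slope, x$slope_ci[1], x$slope_ci[2], x$n))
  invisible(x)
}
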