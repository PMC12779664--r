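#' Fit a weighted Cox proportional hazards model
#'
#' Maximizes the weighted partial likelihood (Efron tie handling) with a
#' robust sandwich variance clustered on subject, so the two follow-up
#' periods of a crossover subject form one cluster. The doubly robust
#' estimator of the treatment effect combines overlap (or truncated IPTW)
#' weights with adjustment for the full covariate set. Continuous design
#' columns are centered at their weighted means, so the stored baseline
#' cumulative hazard refers to the weighted-mean covariate profile with
#' treatment at its reference (comparator) level.
#'
#' @param episodes episode data frame with `followup_years`, `status`,
#'   `arm`, `subject_id` and raw covariates
#' @param weights per-episode weights (>= 0); `NULL` for unweighted
#' @param covariates covariate-frame columns to adjust for (may be empty
#'   for a weight-only model)
#' @param extra_terms optional data frame of additional numeric design
#'   columns (e.g. spline bases and interactions), not centered
#' @param treatment_col treatment column; entered as 0/1 (`"sglt2i"` = 1)
#'   under the name `arm`
#' @param time_col,status_col follow-up time (years) and event indicator
#' @param cluster_col clustering column for the robust variance
#' @param ties tie-handling method, `"efron"` default
#' @param init optional initial coefficient values
#' @param iter_max optional cap on Newton iterations; `0` evaluates the
#'   baseline hazard at the supplied `init` (useful for fixed-coefficient
#'   baselines)
#' @return a `kb_coxfit`: coefficients, robust and model-based covariance,
#'   baseline cumulative hazard step function, centers, and the fitted
#'   [survival::coxph()] object
#' @export
fit_weighted_cox <- function(episodes, weights = NULL, covariates = character(),
                             extra_terms = NULL, treatment_col = "arm",
                             time_col = "followup_years", status_col = "status",
                             cluster_col = "subject_id", ties = "efron",
                             init = NULL, iter_max = NULL) {
  n <- nrow(episodes)
  if (sum(episodes[[status_col]]) < 1)
    stopf("input error: no events in the data")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stopf("input error: weights must be >= 0")
  X <- data.frame(row.names = seq_len(n))
  centers <- numeric(0)
  if (!is.null(treatment_col)) {
    X$arm <- as.numeric(episodes[[treatment_col]] == "sglt2i")
    centers["arm"] <- 0
  }
  if (length(covariates)) {
    fr <- covariate_frame(episodes, covariates)
    if (anyNA(fr))
      stopf("input error: covariates contain missing values; impute first (see chained_impute)")
    for (nm in names(fr)) {
      ctr <- wmean(fr[[nm]], w)
      X[[nm]] <- fr[[nm]] - ctr
      centers[nm] <- ctr
    }
  }
  if (!is.null(extra_terms)) {
    for (nm in names(extra_terms)) {
      X[[nm]] <- extra_terms[[nm]]
      centers[nm] <- 0
    }
  }
  if (!ncol(X)) stopf("input error: no model terms")
  df <- cbind(data.frame(.time = episodes[[time_col]],
                         .status = episodes[[status_col]],
                         .cluster = episodes[[cluster_col]],
                         .w = w), X)
  fml <- as.formula(paste("survival::Surv(.time, .status) ~",
                          paste(sprintf("`%s`", names(X)), collapse = " + ")))
  args <- list(fml, data = df, weights = quote(.w), cluster = quote(.cluster),
               ties = ties, robust = TRUE, x = FALSE, y = TRUE)
  if (!is.null(init)) args$init <- init
  if (!is.null(iter_max)) args$control <- survival::coxph.control(iter.max = iter_max)
  fit <- withCallingHandlers(
    do.call(survival::coxph, args),
    warning = function(wrn) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(wrn))) {
        warnf("monotone likelihood suspected: an estimate may be unbounded")
        invokeRestart("muffleWarning")
      }
    })
  bh <- survival::basehaz(fit, centered = FALSE)
  co <- coef(fit)
  names(co) <- names(X)
  vr <- fit$var
  dimnames(vr) <- list(names(X), names(X))
  vn <- if (!is.null(fit$naive.var)) fit$naive.var else fit$var
  dimnames(vn) <- list(names(X), names(X))
  structure(list(coefficients = co, var_robust = vr, var_naive = vn,
                 basehaz = bh, centers = centers, terms = names(X),
                 ties = ties, n = n, nevent = sum(episodes[[status_col]]),
                 coxph = fit),
            class = "kb_coxfit")
}

#' @export
print.kb_coxfit <- function(x, ...) {
  se <- sqrt(diag(x$var_robust))
  tab <- data.frame(term = x$terms, coef = x$coefficients,
                    hr = exp(x$coefficients), robust_se = se,
                    lower = exp(x$coefficients - 1.96 * se),
                    upper = exp(x$coefficients + 1.96 * se),
                    p = 2 * pnorm(-abs(x$coefficients / se)))
  cat(sprintf("Weighted Cox fit: %d rows, %d events\n", x$n, x$nevent))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarise a Cox fit as a coefficient table
#' @param fit a `kb_coxfit`
#' @return data frame with term, coefficient, HR, robust SE, CI, p
#' @export
cox_summary <- function(fit) {
  se <- sqrt(diag(fit$var_robust))
  data.frame(term = fit$terms, coef = fit$coefficients,
             hr = exp(fit$coefficients), robust_se = se,
             hr_lower = exp(fit$coefficients - 1.96 * se),
             hr_upper = exp(fit$coefficients + 1.96 * se),
             p = 2 * pnorm(-abs(fit$coefficients / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Baseline survival from a weighted Cox fit
#'
#' `S0(t) = exp(-Lambda0(t))` with `Lambda0` the weighted Breslow-type
#' cumulative baseline hazard (Efron correction for ties) at the fit's
#' reference profile (weighted covariate means, comparator arm).
#'
#' @param fit a `kb_coxfit`
#' @param t time(s) in years (>= 0)
#' @return numeric vector of survival probabilities
#' @export
baseline_survival <- function(fit, t) {
  if (any(t < 0)) stopf("input error: t must be >= 0")
  bh <- fit$basehaz
  last <- max(bh$time)
  if (any(t > last))
    warnf("t beyond last observed time (%.3f); returning last value", last)
  idx <- findInterval(pmin(t, last), bh$time)
  lam <- ifelse(idx == 0, 0, bh$hazard[pmax(idx, 1)])
  exp(-lam)
}

#' Predict survival for a subject under a given arm
#'
#' `S(t | x, arm) = S0(t)^exp(LP)` where the linear predictor uses the
#' fit's stored centers, so predictions are exactly consistent with the
#' stored baseline hazard.
#'
#' @param fit a `kb_coxfit`
#' @param newdata data frame of raw covariates (or covariate-frame
#'   columns); one row per subject
#' @param arm 0/1 (or `"comparator"`/`"sglt2i"`) treatment assignment
#' @param t horizon in years (scalar)
#' @param extra_terms optional additional design columns matching the fit
#' @return vector of survival probabilities
#' @export
predict_survival <- function(fit, newdata, arm, t, extra_terms = NULL) {
  s0 <- baseline_survival(fit, t)
  lp <- cox_lp(fit, newdata, arm, extra_terms)
  s0^exp(lp)
}

cox_lp <- function(fit, newdata, arm, extra_terms = NULL) {
  terms <- fit$terms
  covs <- setdiff(terms, c("arm", names(extra_terms %||% list())))
  fr <- if (length(covs)) {
    if (all(covs %in% names(newdata))) newdata[covs] else covariate_frame(newdata, covs)
  } else NULL
  if (is.character(arm)) arm <- as.numeric(arm == "sglt2i")
  n <- if (!is.null(fr)) nrow(fr) else
    max(length(arm), if (!is.null(extra_terms)) nrow(extra_terms) else 1)
  lp <- numeric(n)
  if ("arm" %in% terms) lp <- lp + fit$coefficients["arm"] * (arm - fit$centers["arm"])
  for (nm in covs)
    lp <- lp + fit$coefficients[nm] * (fr[[nm]] - fit$centers[nm])
  if (!is.null(extra_terms))
    for (nm in names(extra_terms))
      lp <- lp + fit$coefficients[nm] * extra_terms[[nm]]
  unname(lp)
}

#' Restricted cubic spline basis with three knots
#'
#' Returns the linear term and the single non-linear basis of a
#' three-knot restricted cubic spline, linear beyond the boundary knots
#' and scaled by `(k3 - k1)^2` (Harrell's normalization).
#'
#' @param x numeric vector
#' @param knots three strictly increasing knot locations
#' @return matrix with columns `lin` and `nl`
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3 || any(diff(knots) <= 0))
    stopf("input error: knots must be 3 strictly increasing values")
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  nl <- (p3(x - k1) - p3(x - k2) * (k3 - k1) / (k3 - k2) +
           p3(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(lin = x, nl = nl)
}

#' Wald test of an interaction coefficient block
#'
#' Chi-square Wald test on a block of coefficients using the robust
#' covariance; used to test treatment-by-modifier interactions (overall
#' block, and the non-linear spline term alone).
#'
#' @param fit a `kb_coxfit` (or any list with `coefficients` and
#'   `var_robust`)
#' @param terms names of the coefficients in the block
#' @return list with `statistic`, `df`, `p`
#' @export
interaction_test <- function(fit, terms) {
  co <- fit$coefficients
  if (!all(terms %in% names(co)))
    stopf("input error: interaction term(s) not in fit: %s",
          paste(setdiff(terms, names(co)), collapse = ", "))
  b <- co[terms]
  V <- fit$var_robust[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stopf("singular covariance block for interaction test"))
  stat <- as.numeric(t(b) %*% Vi %*% b)
  df <- length(terms)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
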