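#' Fit a logistic propensity score model
#'
#' Maximum-likelihood logistic regression of treatment arm on the full
#' covariate set (continuous covariates untransformed, uACR on the log
#' scale, categorical covariates reference-coded, calendar year entered as
#' categorical to capture prescribing trends). Fitted to high precision so
#' overlap weights inherit their exact mean-balance property.
#'
#' @param data episode- or subject-level data frame with an `arm` column
#'   (`"sglt2i"` treated) and raw covariate columns
#' @param covariates covariate-frame column names; default
#'   [full_covariate_set()]
#' @param arm_col name of the treatment column
#' @return a `propensity_fit`: coefficients, per-row score `e(x)` in
#'   (0, 1), convergence flag, log-likelihood, and the design matrix used
#' @export
fit_propensity <- function(data, covariates = NULL, arm_col = "arm") {
  z <- as.numeric(data[[arm_col]] == "sglt2i")
  if (length(unique(z)) < 2) stopf("input error: both arms must be present")
  covariates <- covariates %||% full_covariate_set(data)
  X <- covariate_frame(data, covariates)
  if (anyNA(X))
    stopf("input error: covariates contain missing values; impute first (see chained_impute)")
  fit <- glm(z ~ ., data = X, family = binomial(),
             control = list(epsilon = 1e-12, maxit = 100))
  co <- coef(fit)
  if (any(!is.finite(co)))
    stopf("propensity model is rank-deficient (covariate '%s'); drop collinear or constant columns",
          names(co)[which(!is.finite(co))[1]])
  if (any(abs(co[-1]) > 15)) {
    worst <- names(co[-1])[which.max(abs(co[-1]))]
    stopf("perfect separation suspected in propensity model (covariate '%s')", worst)
  }
  e <- fitted(fit)
  e <- pmin(pmax(e, 1e-12), 1 - 1e-12)
  structure(list(coefficients = co, scores = e, converged = fit$converged,
                 loglik = as.numeric(stats::logLik(fit)),
                 covariates = covariates, design = X, treated = z),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit: %d covariates, score range [%.3f, %.3f], %s\n",
              length(x$coefficients) - 1, min(x$scores), max(x$scores),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Overlap weights
#'
#' Treated units receive `1 - e(x)`, comparator units `e(x)`, targeting
#' the population of clinical equipoise. With a maximum-likelihood
#' logistic score these weights balance every covariate mean in the score
#' model exactly across arms.
#'
#' @param scores propensity scores in (0, 1), or a `propensity_fit`
#' @param treated logical/0-1 vector (ignored when a fit is supplied)
#' @return list with `weights`, `scheme`
#' @export
overlap_weights <- function(scores, treated = NULL) {
  if (inherits(scores, "propensity_fit")) {
    treated <- scores$treated; scores <- scores$scores
  }
  if (any(scores <= 0 | scores >= 1))
    stopf("input error: propensity scores must lie strictly in (0, 1)")
  treated <- as.numeric(treated)
  list(weights = ifelse(treated == 1, 1 - scores, scores), scheme = "overlap")
}

#' Truncated inverse-probability-of-treatment weights
#'
#' Treated units receive `1 / e(x)`, comparator units `1 / (1 - e(x))`;
#' weights outside the stated percentiles of the combined-arm weight
#' distribution are set to the percentile value (2nd and 98th by default).
#'
#' @inheritParams overlap_weights
#' @param lower_pct,upper_pct truncation percentiles (0-100)
#' @return list with `weights`, `scheme`, `bounds` (the percentile values)
#' @export
iptw_weights <- function(scores, treated = NULL, lower_pct = 2, upper_pct = 98) {
  if (inherits(scores, "propensity_fit")) {
    treated <- scores$treated; scores <- scores$scores
  }
  if (any(scores <= 0 | scores >= 1))
    stopf("input error: propensity scores must lie strictly in (0, 1)")
  treated <- as.numeric(treated)
  w <- ifelse(treated == 1, 1 / scores, 1 / (1 - scores))
  bounds <- quantile(w, c(lower_pct, upper_pct) / 100, names = FALSE)
  list(weights = pmin(pmax(w, bounds[1]), bounds[2]), scheme = "iptw_truncated",
       bounds = bounds)
}

#' Standardized mean differences before and after weighting
#'
#' For continuous covariates the SMD is `(m1 - m2) / sqrt((s1^2 + s2^2)/2)`;
#' binary covariates use `p(1-p)` variances. Weighted versions use weighted
#' means and variances. A zero pooled variance yields SMD 0 with a warning.
#'
#' @param data data frame with raw covariates and `arm`
#' @param weights per-row weights (`NULL` for unweighted only)
#' @param covariates covariate-frame columns; default [full_covariate_set()]
#' @param arm_col treatment column name
#' @return data frame: covariate, means by arm, `smd_unweighted`,
#'   `smd_weighted`
#' @export
balance_table <- function(data, weights = NULL, covariates = NULL,
                          arm_col = "arm") {
  covariates <- covariates %||% full_covariate_set(data)
  X <- covariate_frame(data, covariates)
  z <- data[[arm_col]] == "sglt2i"
  w1 <- rep(1, nrow(X))
  smd_one <- function(x, w) {
    m1 <- wmean(x[z], w[z]); m2 <- wmean(x[!z], w[!z])
    binary <- all(x %in% c(0, 1))
    v1 <- if (binary) m1 * (1 - m1) else wvar(x[z], w[z])
    v2 <- if (binary) m2 * (1 - m2) else wvar(x[!z], w[!z])
    pooled <- (v1 + v2) / 2
    if (pooled <= 0) {
      warnf("zero pooled variance for a covariate; SMD reported as 0")
      return(c(m1, m2, 0))
    }
    c(m1, m2, (m1 - m2) / sqrt(pooled))
  }
  un <- t(vapply(X, smd_one, numeric(3), w = w1))
  out <- data.frame(covariate = names(X),
                    mean_treated = un[, 1], mean_comparator = un[, 2],
                    smd_unweighted = un[, 3], stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    ww <- t(vapply(X, smd_one, numeric(3), w = weights))
    out$wmean_treated <- ww[, 1]
    out$wmean_comparator <- ww[, 2]
    out$smd_weighted <- ww[, 3]
  }
  rownames(out) <- NULL
  out
}
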