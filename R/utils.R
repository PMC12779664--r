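#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm binomial coef vcov lm predict fitted quantile rnorm
#'   runif rbinom rexp rlnorm sd var qnorm qt pnorm pchisq setNames
#'   complete.cases as.formula model.matrix aggregate median weighted.mean
#' @importFrom utils write.csv read.csv head
NULL

DAYS_PER_YEAR <- 365.25

expit <- function(x) 1 / (1 + exp(-x))

#' Derive a stage-specific seed from a master seed
#'
#' A single pipeline seed is expanded into per-stage seeds so each stage is
#' independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stage integer stage index (0-99)
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  # multiplicative hash so nearby (seed, stage) pairs map to well-separated
  # generator states
  as.integer((as.numeric(seed) * 48271 + stage * 30269 + 11213) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("configuration error: '%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && !any(is.na(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stopf("configuration error: '%s' must be %s", name,
                 if (strict) "> 0" else ">= 0")
  invisible(x)
}

# Weighted mean / variance (reliability weights) used for balance diagnostics
# and covariate centering.
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Numeric covariate frame (the "full covariate set")
#'
#' Expands a subject- or episode-level data frame into the numeric design
#' columns used by the propensity model, the outcome model and the risk
#' score: continuous variables untransformed (uACR on the log scale),
#' categorical variables reference-coded (ethnicity ref White, smoking ref
#' non-smoker, calendar year ref first year, glucose-lowering count ref 1).
#'
#' @param data data frame with subject covariate columns
#' @param covariates character vector of frame columns to keep; default all
#' @return data frame of numeric columns, one row per input row
#' @export
covariate_frame <- function(data, covariates = NULL) {
  out <- data.frame(row.names = seq_len(nrow(data)))
  has <- function(v) v %in% names(data)
  if (has("age")) out$age <- as.numeric(data$age)
  if (has("sex")) out$male <- as.numeric(data$sex == "male")
  if (has("ethnicity")) {
    for (lv in c("south_asian", "black", "mixed", "other")) {
      out[[paste0("eth_", lv)]] <- as.numeric(data$ethnicity == lv)
    }
  }
  if (has("imd_quintile")) out$imd_quintile <- as.numeric(data$imd_quintile)
  if (has("bmi")) out$bmi <- as.numeric(data$bmi)
  if (has("sbp")) out$sbp <- as.numeric(data$sbp)
  if (has("total_chol")) out$total_chol <- as.numeric(data$total_chol)
  if (has("hba1c")) out$hba1c <- as.numeric(data$hba1c)
  if (has("egfr")) out$egfr <- as.numeric(data$egfr)
  if (has("uacr")) out$log_uacr <- log(as.numeric(data$uacr))
  if (has("diabetes_duration")) out$diabetes_duration <- as.numeric(data$diabetes_duration)
  if (has("smoking")) {
    out$smoking_ex <- as.numeric(data$smoking == "ex")
    out$smoking_current <- as.numeric(data$smoking == "current")
  }
  if (has("hypertension")) out$hypertension <- as.numeric(data$hypertension)
  if (has("atrial_fibrillation")) out$af <- as.numeric(data$atrial_fibrillation)
  if (has("prior_hospitalisation")) out$prior_hosp <- as.numeric(data$prior_hospitalisation)
  if (has("calendar_year")) {
    yrs <- sort(unique(data$calendar_year))
    for (y in yrs[-1]) out[[paste0("year_", y)]] <- as.numeric(data$calendar_year == y)
  }
  if (has("n_glucose_lowering")) {
    out$ngl_2 <- as.numeric(data$n_glucose_lowering == "2")
    out$ngl_3 <- as.numeric(data$n_glucose_lowering == "3+")
  }
  if (has("statin")) out$statin <- as.numeric(data$statin)
  if (has("insulin")) out$insulin <- as.numeric(data$insulin)
  if (has("acei_arb")) out$acei_arb <- as.numeric(data$acei_arb)
  if (has("hypertension") && has("acei_arb")) {
    out$antihtn <- as.numeric(data$hypertension | data$acei_arb)
  }
  if (has("hf_chd")) out$hf_chd <- as.numeric(data$hf_chd)
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, names(out))
    # calendar-year indicators for levels absent from this subset
    yr <- grepl("^year_\\d+$", missing)
    if (any(yr) && "calendar_year" %in% names(data)) {
      for (nm in missing[yr])
        out[[nm]] <- as.numeric(data$calendar_year == sub("year_", "", nm))
      missing <- missing[!yr]
    }
    if (length(missing))
      stopf("configuration error: unknown covariate(s): %s",
            paste(missing, collapse = ", "))
    out <- out[, covariates, drop = FALSE]
  }
  out
}

#' Default covariate set used for adjustment and propensity modelling
#'
#' All covariate-frame columns except the derived antihypertensive
#' indicator (collinear with its components) and any column that is
#' constant in `data` (e.g. heart failure/CHD after the eligibility
#' filter removes all carriers).
#'
#' @param data data frame (used to detect which columns are available)
#' @return character vector of covariate-frame column names
#' @export
full_covariate_set <- function(data) {
  fr <- covariate_frame(data)
  keep <- vapply(fr, function(x) length(unique(x)) > 1, TRUE)
  setdiff(names(fr)[keep], "antihtn")
}
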