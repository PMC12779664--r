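#' Chained-equation multiple imputation
#'
#' Multivariate imputation by chained equations over the variables with
#' missing values: numeric variables by predictive mean matching (PMM,
#' `k` nearest donors by predicted mean from a linear regression),
#' unordered categoricals by multinomial regression
#' ([nnet::multinom()]), and BMI passively recomputed as
#' `weight / height^2` after its components are imputed. Variables are
#' visited in order of increasing missingness; each of the `m` chains is
#' initialised by random draws from the observed values and swept
#' `iterations` times.
#'
#' @param data data frame; missingness only in the variables to impute
#' @param m number of imputations (>= 1)
#' @param iterations chained-equation sweeps per chain (default 10)
#' @param seed integer seed
#' @param variables variables to impute; defaults to the clinical
#'   covariates that carry missingness in primary-care records
#'   (IMD, height/weight/BMI, systolic BP, total cholesterol, HbA1c,
#'   diabetes duration, smoking), restricted to columns actually present
#'   and incomplete. Structural columns that are missing by design
#'   (event fields, drug dates) are never imputed.
#' @param predictors character vector of complete columns used as
#'   predictors; defaults to all complete numeric/logical/character
#'   columns except identifiers
#' @param k PMM donor count (default 5)
#' @return an `imputed_stack`: list with `datasets` (m complete copies),
#'   `m`, `methods`, `iterations`, `seed`
#' @export
chained_impute <- function(data, m = 10, iterations = 10, seed = 1,
                           variables = NULL, predictors = NULL, k = 5) {
  stopifnot(is.data.frame(data), m >= 1)
  set.seed(seed)
  default_vars <- c("imd_quintile", "height", "weight", "bmi", "sbp",
                    "total_chol", "hba1c", "diabetes_duration", "smoking")
  miss_frac <- vapply(data, function(x) mean(is.na(x)), 0)
  if (is.null(variables)) {
    variables <- intersect(default_vars, names(data))
    if (!length(variables)) variables <- names(miss_frac)[miss_frac > 0]
  }
  if (any(miss_frac[variables] == 1))
    stopf("input error: variable(s) 100%% missing: %s",
          paste(variables[miss_frac[variables] == 1], collapse = ", "))
  targets <- variables[miss_frac[variables] > 0]
  # passive BMI: impute height/weight, recompute bmi afterwards
  passive_bmi <- all(c("height", "weight", "bmi") %in% names(data)) &&
    "bmi" %in% targets
  if (passive_bmi) targets <- setdiff(targets, "bmi")
  targets <- targets[order(miss_frac[targets])]
  if (!length(targets) && !passive_bmi) {
    stacks <- replicate(m, data, simplify = FALSE)
    return(structure(list(datasets = stacks, m = m, methods = character(),
                          iterations = iterations, seed = seed),
                     class = "imputed_stack"))
  }
  if (is.null(predictors)) {
    complete_cols <- names(data)[vapply(data, function(x) !anyNA(x), TRUE)]
    usable <- vapply(data[complete_cols], function(x)
      is.numeric(x) || is.logical(x) ||
        (is.character(x) && length(unique(x)) <= 12) || is.factor(x), TRUE)
    predictors <- setdiff(complete_cols[usable],
                          c("id", "subject_id", "episode", targets, "bmi"))
    # drop constant columns
    predictors <- predictors[vapply(data[predictors],
                                    function(x) length(unique(x)) > 1, TRUE)]
  }
  if (!length(predictors))
    stopf("input error: no complete predictor columns available")
  methods <- vapply(targets, function(v)
    if (is.numeric(data[[v]])) "pmm" else "multinomial", "")
  if (passive_bmi) methods <- c(methods, bmi = "passive")

  pred_mat <- function(df) {
    mm <- model.matrix(~ ., data = df[predictors])
    mm
  }
  X_pred <- pred_mat(data)

  impute_one <- function() {
    d <- data
    idx <- lapply(targets, function(v) which(is.na(d[[v]])))
    names(idx) <- targets
    for (v in targets) {
      obs <- d[[v]][!is.na(d[[v]])]
      d[[v]][idx[[v]]] <- sample(obs, length(idx[[v]]), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in targets) {
        mi <- idx[[v]]
        if (!length(mi)) next
        obs_rows <- setdiff(seq_len(nrow(d)), mi)
        if (methods[[v]] == "pmm") {
          fit <- stats::lm.fit(X_pred[obs_rows, , drop = FALSE],
                               d[[v]][obs_rows])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          yhat_obs <- drop(X_pred[obs_rows, , drop = FALSE] %*% beta)
          yhat_mis <- drop(X_pred[mi, , drop = FALSE] %*% beta)
          d[[v]][mi] <- pmm_draw(yhat_obs, d[[v]][obs_rows], yhat_mis, k)
        } else {
          df_fit <- cbind(data.frame(.y = factor(d[[v]][obs_rows])),
                          d[obs_rows, predictors, drop = FALSE])
          fit <- nnet::multinom(.y ~ ., data = df_fit, trace = FALSE,
                                maxit = 200)
          pr <- predict(fit, newdata = d[mi, predictors, drop = FALSE],
                        type = "probs")
          lv <- levels(df_fit$.y)
          if (length(lv) == 2) pr <- cbind(1 - pr, pr)
          pr <- matrix(pr, ncol = length(lv))
          u <- runif(length(mi))
          cum <- t(apply(pr, 1, cumsum))
          pick <- rowSums(u > cum) + 1L
          d[[v]][mi] <- lv[pmin(pick, length(lv))]
        }
      }
    }
    if (passive_bmi) d$bmi <- d$weight / d$height^2
    d
  }
  datasets <- replicate(m, impute_one(), simplify = FALSE)
  structure(list(datasets = datasets, m = m, methods = methods,
                 iterations = iterations, seed = seed),
            class = "imputed_stack")
}

# PMM: for each missing prediction, sample one of the k observed values
# with the closest predicted means.
pmm_draw <- function(yhat_obs, y_obs, yhat_mis, k) {
  o <- order(yhat_obs)
  ys <- yhat_obs[o]; vs <- y_obs[o]
  n <- length(ys)
  kk <- min(k, n)
  pos <- findInterval(yhat_mis, ys)
  out <- numeric(length(yhat_mis))
  for (j in seq_along(yhat_mis)) {
    lo <- max(1, pos[j] - kk); hi <- min(n, pos[j] + kk)
    cand <- lo:hi
    dd <- abs(ys[cand] - yhat_mis[j])
    donors <- cand[order(dd)][seq_len(kk)]
    out[j] <- vs[donors[sample.int(kk, 1)]]
  }
  out
}

#' Write an imputed stack as CSVs plus a JSON manifest
#' @param stack an `imputed_stack`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(stack$m)
  for (i in seq_len(stack$m)) {
    files[i] <- sprintf("imputed_%02d.csv", i)
    write.csv(stack$datasets[[i]], file.path(dir, files[i]), row.names = FALSE)
  }
  jsonlite::write_json(list(m = stack$m, files = files,
                            methods = as.list(stack$methods),
                            iterations = stack$iterations, seed = stack$seed),
                       file.path(dir, "imputation_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance `T = W + (1 + 1/m) B` combines the mean within-imputation
#' variance `W` and the between-imputation variance `B` (sample variance
#' of the estimates). Degrees of freedom follow Barnard-Rubin when a
#' complete-data df is supplied, else the classical
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates m point estimates
#' @param variances m squared standard errors (>= 0)
#' @param conf confidence level for the pooled interval
#' @param df_com complete-data degrees of freedom (default `Inf`)
#' @return list with `estimate`, `within`, `between`, `variance`, `se`,
#'   `df`, `ci` (length-2), `m`
#' @export
pool_rubin <- function(estimates, variances, conf = 0.95, df_com = Inf) {
  if (length(estimates) != length(variances))
    stopf("input error: estimates and variances differ in length")
  if (any(variances < 0)) stopf("input error: variances must be >= 0")
  m <- length(estimates)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1) var(estimates) else 0
  Tt <- W + (1 + 1 / m) * B
  if (m == 1 || B == 0) {
    df <- Inf
  } else {
    riv <- (1 + 1 / m) * B / W
    lambda <- if (is.finite(riv)) riv / (1 + riv) else 1
    df_old <- (m - 1) / lambda^2
    if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else df <- df_old
  }
  se <- sqrt(Tt)
  tcrit <- if (is.finite(df)) qt(1 - (1 - conf) / 2, df) else qnorm(1 - (1 - conf) / 2)
  list(estimate = qbar, within = W, between = B, variance = Tt, se = se,
       df = df, ci = c(qbar - tcrit * se, qbar + tcrit * se), m = m)
}
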