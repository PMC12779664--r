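# Independent brute-force oracles used to cross-check the model fitters.

# Negative weighted log partial likelihood for a single-covariate Cox model
# (assumes untied event times), written directly from the definition.
oracle_cox_nloglik <- function(beta, time, status, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (beta * x[i] - log(sum(w[risk] * exp(beta * x[risk]))))
  }
  -ll
}

oracle_cox_beta <- function(time, status, x, w = rep(1, length(time))) {
  stats::optimize(oracle_cox_nloglik, c(-10, 10), time = time, status = status,
                  x = x, w = w, tol = 1e-10)$minimum
}

# Harrell's C by exhaustive pair enumeration: a pair is comparable when the
# shorter time is an event and the times differ; ties in the predictor
# count one half.
oracle_cindex <- function(lp, time, status) {
  conc <- 0; comp <- 0
  n <- length(lp)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (time[i] == time[j]) {
      # tied failure times are incomparable; an event tied with a censoring
      # is comparable, the event counted as failing first
      if (status[i] + status[j] != 1) next
      first <- if (status[i] == 1) i else j
    } else {
      first <- if (time[i] < time[j]) i else j
      if (!status[first]) next
    }
    other <- if (first == i) j else i
    comp <- comp + 1
    if (lp[first] > lp[other]) conc <- conc + 1
    else if (lp[first] == lp[other]) conc <- conc + 0.5
  }
  conc / comp
}

# Small deterministic episode frame for hand-checked fits.
mini_episodes <- function(time, status, arm, id = seq_along(time)) {
  data.frame(subject_id = id, followup_years = time, status = status,
             arm = ifelse(arm == 1, "sglt2i", "comparator"),
             stringsAsFactors = FALSE)
}

# Default-config cohort, built once per size and memoised across tests.
.kb_cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed, missing = FALSE) {
  key <- paste0("n", n, "s", seed, "m", missing)
  if (is.null(.kb_cohort_cache[[key]])) {
    cfg <- synthetic_config(n_subjects = n, seed = seed)
    co <- simulate_outcomes(assign_treatment(generate_cohort(cfg)))
    if (missing) co <- inject_missingness(co)
    .kb_cohort_cache[[key]] <- co
  }
  .kb_cohort_cache[[key]]
}
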