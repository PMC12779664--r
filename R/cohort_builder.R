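#' Resolve the baseline laboratory value for one subject
#'
#' The value taken at the date closest to baseline within the previous
#' `lookback` days is used; ties go to the later reading.
#' @noRd
baseline_value <- function(days, values, at = 0, lookback = 730) {
  keep <- days <= at & days >= at - lookback
  if (!any(keep)) return(NA_real_)
  d <- days[keep]; v <- values[keep]
  dist <- abs(at - d)
  cand <- which(dist == min(dist))
  v[cand[which.max(d[cand])]]
}

# Vectorised per-subject baseline resolution over a long readings table.
# `rd` must be sorted by (id, day); returns one value per element of `ids`
# (NA when no reading in [at - lookback, at]). `at` is scalar or per-id.
resolve_baseline_vec <- function(rd, ids, at = 0, lookback = 730) {
  if (length(at) == 1) at <- rep(at, length(ids))
  at_row <- at[match(rd$id, ids)]
  sel <- !is.na(at_row) & rd$day <= at_row & rd$day >= at_row - lookback
  ids_sel <- rd$id[sel]
  last <- !duplicated(ids_sel, fromLast = TRUE)  # latest day <= at wins
  out <- rep(NA_real_, length(ids))
  out[match(ids_sel[last], ids)] <- rd$value[sel][last]
  out
}

# Vectorised composite-event scan: first qualifying day per subject.
# Returns data.frame(day, type) aligned with `ids`; Inf day = no event.
scan_events_vec <- function(rd, ids, entry, base, decline_threshold,
                            rrt_day, death_day, kidney_related_death,
                            sustained_days = 90) {
  n <- length(ids)
  ev_day <- rep(Inf, n); ev_type <- rep(NA_character_, n)
  note <- function(day, type, pos) {
    better <- !is.na(day) & is.finite(day) & day < ev_day[pos]
    ev_day[pos[better]] <<- day[better]
    ev_type[pos[better]] <<- type
  }
  m <- match(rd$id, ids)
  ent_row <- entry[m]; base_row <- base[m]
  post <- !is.na(m) & !is.na(ent_row) & rd$day > ent_row & !is.na(base_row)
  # >= threshold decline in eGFR from the episode baseline
  hit <- post & rd$value <= (1 - decline_threshold) * base_row
  if (any(hit)) {
    first <- !duplicated(rd$id[hit])
    note(rd$day[hit][first],
         sprintf("decline%d", round(100 * decline_threshold)),
         match(rd$id[hit][first], ids))
  }
  # sustained eGFR < 15: consecutive readings < 15 spanning >= sustained_days
  low <- rd$value < 15
  if (any(low)) {
    nr <- nrow(rd)
    prev_same <- c(FALSE, rd$id[-1] == rd$id[-nr])
    pair <- low & c(FALSE, low[-nr]) & prev_same &
      c(FALSE, rd$day[-1] - rd$day[-nr] >= sustained_days) & post &
      c(FALSE, post[-nr])
    if (any(pair)) {
      first <- !duplicated(rd$id[pair])
      note(rd$day[pair][first], "eskd", match(rd$id[pair][first], ids))
    }
  }
  if (!all(is.na(rrt_day))) {
    pos <- which(!is.na(rrt_day) & rrt_day > entry)
    note(rrt_day[pos], "eskd", pos)
  }
  kd <- which(!is.na(death_day) & kidney_related_death & death_day > entry)
  note(death_day[kd], "kidney_death", kd)
  data.frame(day = ev_day, type = ev_type, stringsAsFactors = FALSE)
}

#' Apply target-trial eligibility criteria
#'
#' Subjects are excluded by the first matching criterion, in this fixed
#' order: prior heart failure/atherosclerotic CVD; missing baseline eGFR or
#' uACR (no reading in the previous 2 years); eGFR < 60 ml/min per 1.73 m2
#' or uACR >= 30 mg/mmol; prior end-stage kidney disease; concurrent GLP-1
#' receptor agonist; BMI < 20 kg/m2; age < 20 or > 80 years; fewer than 91
#' days of registration before the index date. Baseline eGFR and uACR are
#' resolved from the reading closest to the index date in the prior 2
#' years.
#'
#' @param cohort a `kb_cohort`
#' @param index_day index (baseline) day per subject; default 0 for all
#' @return list with `cohort` (eligible subjects, with resolved `egfr`,
#'   `uacr` and `albuminuria` columns), `exclusions` (id, reason) and
#'   `counts` (per-criterion exclusion counts)
#' @export
apply_eligibility <- function(cohort, index_day = 0) {
  stopifnot(inherits(cohort, "kb_cohort"))
  s <- cohort$subjects
  n <- nrow(s)
  if (length(index_day) == 1) index_day <- rep(index_day, n)

  rd <- cohort$readings
  rd <- rd[order(rd$id, rd$day), ]
  egfr_rd <- rd[rd$measure == "egfr", ]
  uacr_rd <- rd[rd$measure == "uacr", ]
  s$egfr <- resolve_baseline_vec(egfr_rd, s$id, index_day)
  s$uacr <- resolve_baseline_vec(uacr_rd, s$id, index_day)

  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    hit <- is.na(reason) & cond & !is.na(cond)
    reason[hit] <<- why
  }
  mark(if (!is.null(s$hf_chd)) s$hf_chd else FALSE, "prior_hf_ascvd")
  mark(is.na(s$egfr) | is.na(s$uacr), "missing_egfr_uacr")
  mark(s$egfr < 60 | s$uacr >= 30, "egfr_lt60_or_uacr_ge30")
  mark(if (!is.null(s$esrd_prior)) s$esrd_prior else FALSE, "eskd")
  glp1_conc <- if (!is.null(s$glp1_start_day)) !is.na(s$glp1_start_day) &
    s$glp1_start_day <= index_day else FALSE
  mark(glp1_conc, "concurrent_glp1")
  mark(!is.na(s$bmi) & s$bmi < 20, "bmi_lt20")
  mark(s$age < 20 | s$age > 80, "age_lt20_or_gt80")
  mark(if (!is.null(s$registration_days)) s$registration_days < 91 else FALSE,
       "registration_lt91d")

  excl <- data.frame(id = s$id[!is.na(reason)], reason = reason[!is.na(reason)])
  counts <- table(factor(excl$reason,
    levels = c("prior_hf_ascvd", "missing_egfr_uacr", "egfr_lt60_or_uacr_ge30",
               "eskd", "concurrent_glp1", "bmi_lt20", "age_lt20_or_gt80",
               "registration_lt91d")))
  keep <- is.na(reason)
  s2 <- s[keep, , drop = FALSE]
  # two consecutive pre-baseline readings in [3, 30) => low-level albuminuria
  at_row <- index_day[match(uacr_rd$id, s$id)]
  pre <- uacr_rd[!is.na(at_row) & uacr_rd$day <= at_row, , drop = FALSE]
  inband <- pre$value >= 3 & pre$value < 30
  npre <- nrow(pre)
  pair_ids <- if (npre >= 2) unique(pre$id[-1][inband[-1] & inband[-npre] &
                                               pre$id[-1] == pre$id[-npre]])
              else integer()
  s2$albuminuria <- ifelse(s2$id %in% pair_ids, "low_level", "normal")
  out <- cohort
  out$subjects <- s2
  out$latent <- cohort$latent[keep, , drop = FALSE]
  list(cohort = out, exclusions = excl, counts = as.data.frame(counts,
       responseName = "n", stringsAsFactors = FALSE))
}

#' Classify albuminuria status from baseline uACR readings
#'
#' Low-level albuminuria (uACR 3-30 mg/mmol) requires two consecutive
#' readings in `[3, 30)`; anything else is classed as normal.
#'
#' @param uacr_values uACR readings (mg/mmol) ordered by day, at or before
#'   baseline
#' @return `"low_level"` or `"normal"`
#' @export
classify_albuminuria <- function(uacr_values) {
  v <- uacr_values[!is.na(uacr_values)]
  if (length(v) < 2) return("normal")
  inband <- v >= 3 & v < 30
  if (any(inband[-1] & inband[-length(inband)])) "low_level" else "normal"
}

#' Detect kidney disease progression from a subject's record
#'
#' The primary composite comprises (i) a >= 50% decline in eGFR from
#' baseline (first qualifying reading), (ii) end-stage kidney disease —
#' renal replacement therapy, or a sustained eGFR < 15 defined as two
#' consecutive readings < 15 spanning >= 90 days (event at the second) —
#' and (iii) death from a kidney-related cause. The composite event is the
#' earliest component. The secondary composite uses a 40% decline
#' threshold. Thresholds are inclusive (>= 50%, >= 40%).
#'
#' @param egfr_days,egfr_values post-baseline eGFR readings, ordered by day
#' @param baseline_egfr baseline eGFR (> 0)
#' @param rrt_day day of renal replacement therapy start, or `NA`
#' @param death_day day of death, or `NA`
#' @param kidney_related_death logical: was the death kidney-related?
#' @param decline_threshold fractional decline defining the event
#'   (0.5 primary, 0.4 secondary)
#' @param sustained_days minimum span of the two sub-15 readings (90)
#' @return `NULL` if no event, else `list(day, type)` with type one of
#'   `"decline50"` (or `"decline40"`), `"eskd"`, `"kidney_death"`
#' @export
detect_kidney_progression <- function(egfr_days, egfr_values, baseline_egfr,
                                      rrt_day = NA, death_day = NA,
                                      kidney_related_death = FALSE,
                                      decline_threshold = 0.5,
                                      sustained_days = 90) {
  if (is.na(baseline_egfr) || baseline_egfr <= 0)
    stopf("input error: baseline eGFR must be > 0")
  o <- order(egfr_days)
  d <- egfr_days[o]; v <- egfr_values[o]
  cands <- list()
  hit <- which(v <= (1 - decline_threshold) * baseline_egfr)
  if (length(hit))
    cands[[length(cands) + 1]] <- list(day = d[hit[1]],
      type = sprintf("decline%d", round(100 * decline_threshold)))
  # sustained eGFR < 15: two consecutive readings < 15 spanning >= 90 days
  low <- v < 15
  if (length(v) >= 2) {
    pair <- which(low[-1] & low[-length(low)] &
                    (d[-1] - d[-length(d)]) >= sustained_days)
    if (length(pair))
      cands[[length(cands) + 1]] <- list(day = d[pair[1] + 1], type = "eskd")
  }
  if (!is.na(rrt_day))
    cands[[length(cands) + 1]] <- list(day = rrt_day, type = "eskd")
  if (!is.na(death_day) && isTRUE(kidney_related_death))
    cands[[length(cands) + 1]] <- list(day = death_day, type = "kidney_death")
  if (!length(cands)) return(NULL)
  days <- vapply(cands, `[[`, 0, "day")
  cands[[which.min(days)]]
}

#' Resolve the end of follow-up for one treatment episode
#'
#' Follow-up runs from episode entry until the earliest of: outcome event,
#' death, practice deregistration, GLP-1 receptor agonist initiation,
#' crossover censoring (comparator arm), administrative study end, or the
#' horizon (3 years by default, 5 in extended analyses; 365.25 days/year).
#'
#' @param entry_day episode entry day
#' @param event `NULL` or `list(day, type)` from
#'   [detect_kidney_progression()]
#' @param death_day,deregistration_day,glp1_day,crossover_day,study_end_day
#'   candidate censoring days (`NA`/`Inf` if not applicable)
#' @param horizon_years follow-up cap in years
#' @return list with `exit_day`, `followup_years`, `status` (1 event,
#'   0 censored), `event_type`, `censor_reason`
#' @export
resolve_followup <- function(entry_day, event = NULL, death_day = NA,
                             deregistration_day = NA, glp1_day = NA,
                             crossover_day = NA, study_end_day = Inf,
                             horizon_years = 3) {
  horizon_day <- entry_day + horizon_years * DAYS_PER_YEAR
  cand_day <- c(event = if (!is.null(event)) event$day else Inf,
                death = if (is.na(death_day)) Inf else death_day,
                deregistration = if (is.na(deregistration_day)) Inf else deregistration_day,
                glp1_start = if (is.na(glp1_day)) Inf else glp1_day,
                crossover = if (is.na(crossover_day)) Inf else crossover_day,
                admin = study_end_day,
                horizon = horizon_day)
  if (all(!is.finite(cand_day)))
    stopf("input error: no candidate exit for episode (administrative end must exist)")
  first <- names(cand_day)[which.min(cand_day)]
  exit_day <- unname(min(cand_day))
  if (exit_day <= entry_day)
    stopf("input error: episode exit (day %s) not after entry (day %s)",
          exit_day, entry_day)
  list(exit_day = exit_day,
       followup_years = (exit_day - entry_day) / DAYS_PER_YEAR,
       status = as.integer(first == "event"),
       event_type = if (first == "event") event$type else NA_character_,
       censor_reason = if (first == "event") NA_character_ else first)
}

#' Build analyzable treatment episodes under target-trial rules
#'
#' SGLT2 inhibitor initiators contribute one episode from their index date.
#' Comparator initiators contribute an episode from their index date,
#' censored at SGLT2 inhibitor initiation (crossover) if it occurs; from
#' that same date they contribute a second, non-overlapping episode in the
#' SGLT2 inhibitor arm. Starting a DPP4 inhibitor or sulfonylurea during
#' follow-up never censors in the pooled-comparator analysis; in
#' `mode = "pairwise"` any other study-drug start censors. Events are
#' detected from the post-entry eGFR record against the episode's baseline
#' eGFR; the second episode's baseline is re-resolved at the crossover
#' date.
#'
#' @param cohort an eligible `kb_cohort` (after [apply_eligibility()])
#' @param horizon_years follow-up cap (3 default, 5 extended)
#' @param decline_threshold 0.5 for the primary composite, 0.4 secondary
#' @param mode `"pooled"` (DPP4i/SU as one arm) or `"pairwise"`
#' @param study_end_day administrative end of the study period
#' @return data frame of episodes: subject_id, episode, arm, entry_day,
#'   exit_day, followup_years, status, event_type, censor_reason, plus
#'   subject baseline covariates for modelling
#' @export
build_episodes <- function(cohort, horizon_years = 3, decline_threshold = 0.5,
                           mode = c("pooled", "pairwise"),
                           study_end_day = Inf) {
  stopifnot(inherits(cohort, "kb_cohort"))
  mode <- match.arg(mode)
  s <- cohort$subjects
  if (is.null(s$arm)) stopf("input error: arms not assigned")
  rd <- cohort$readings
  rd <- rd[order(rd$id, rd$day), ]
  egfr_rd <- rd[rd$measure == "egfr", ]

  bad <- s$arm == "comparator" & !is.na(s$crossover_day) & s$crossover_day <= 0
  if (any(bad))
    stopf("record rejected: subject %s has SGLT2i start on/before comparator start",
          s$id[which(bad)[1]])

  resolve_vec <- function(rows, arm, entry, cross_censor) {
    ids <- s$id[rows]
    base <- resolve_baseline_vec(egfr_rd, ids, entry)
    ev <- scan_events_vec(egfr_rd, ids, entry, base, decline_threshold,
                          s$rrt_day[rows], s$death_day[rows],
                          s$kidney_related_death[rows])
    inf_na <- function(x) ifelse(is.na(x), Inf, x)
    m <- cbind(event = ev$day,
               death = inf_na(s$death_day[rows]),
               deregistration = inf_na(s$deregistration_day[rows]),
               glp1_start = inf_na(s$glp1_start_day[rows]),
               crossover = inf_na(cross_censor),
               admin = rep(study_end_day, length(rows)),
               horizon = entry + horizon_years * DAYS_PER_YEAR)
    pick <- max.col(-m, ties.method = "first")
    exit <- m[cbind(seq_along(rows), pick)]
    reason <- colnames(m)[pick]
    # a kidney-related death is the event even when it coincides with "death"
    status <- as.integer(reason == "event")
    data.frame(subject_id = s$id[rows], arm = arm, entry_day = entry,
               exit_day = exit, followup_years = (exit - entry) / DAYS_PER_YEAR,
               status = status,
               event_type = ifelse(status == 1, ev$type, NA_character_),
               censor_reason = ifelse(status == 1, NA_character_, reason),
               stringsAsFactors = FALSE)
  }

  trt_rows <- which(s$arm == "sglt2i")
  cmp_rows <- which(s$arm == "comparator")
  ep1t <- if (length(trt_rows))
    resolve_vec(trt_rows, "sglt2i", rep(0, length(trt_rows)), rep(Inf, length(trt_rows)))
  ep1c <- if (length(cmp_rows))
    resolve_vec(cmp_rows, "comparator", rep(0, length(cmp_rows)),
                ifelse(is.na(s$crossover_day[cmp_rows]), Inf, s$crossover_day[cmp_rows]))
  # second episodes: comparators censored at crossover re-enter as SGLT2i
  ep2 <- NULL
  if (length(cmp_rows)) {
    xo <- which(!is.na(ep1c$censor_reason) & ep1c$censor_reason == "crossover")
    if (length(xo)) {
      rows2 <- cmp_rows[xo]
      ep2 <- resolve_vec(rows2, "sglt2i", s$crossover_day[rows2],
                         rep(Inf, length(rows2)))
    }
  }
  ep <- do.call(rbind, Filter(Negate(is.null), list(ep1t, ep1c, ep2)))
  ep <- ep[ep$exit_day > ep$entry_day, , drop = FALSE]
  ep <- ep[order(ep$subject_id, ep$entry_day), ]
  ep$episode <- stats::ave(ep$subject_id, ep$subject_id, FUN = seq_along)
  cov_cols <- setdiff(names(s), "arm")
  ep <- merge(ep, s[cov_cols], by.x = "subject_id", by.y = "id", sort = FALSE)
  if (mode == "pairwise")
    ep$arm_drug <- ifelse(ep$arm == "sglt2i", "sglt2i",
                          s$comparator_drug[match(ep$subject_id, s$id)])
  rownames(ep) <- NULL
  ep[order(ep$subject_id, ep$entry_day), ]
}
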