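---
title: "Methods: predicting individual kidney-protection benefit of SGLT2 inhibitors"
author: "kidneybenefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting individual kidney-protection benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimand and the four-step procedure

The package targets the individual-level 3-year absolute risk reduction
(pARR) in kidney disease progression — a composite of a ≥ 50% decline in
eGFR, end-stage kidney disease (renal replacement therapy or sustained
eGFR < 15 ml/min per 1.73 m²), or kidney-related death — conferred by
starting an SGLT2 inhibitor rather than a DPP4 inhibitor or sulfonylurea,
in adults with type 2 diabetes, preserved eGFR (≥ 60) and uACR < 30 mg/mmol,
without heart failure or atherosclerotic cardiovascular disease.

The prediction model factorizes into two externally derived components:

$$pARR = S_0(t\,|\,x)^{\mathrm{HR}} - S_0(t\,|\,x),$$

where $S_0(t|x) = S_0(t)^{\exp(\mathrm{LP}(x))}$ is an individual's predicted
untreated progression-free survival from a proportional-hazards risk score,
and HR is the relative treatment effect from randomized evidence (0.62 by
default). The factorization assumes (i) proportional hazards for the score,
(ii) a relative effect that is constant across the predicted-risk spectrum,
and (iii) that the score describes untreated natural history. Assumption (ii)
is not taken on faith: step 1 tests it.

1. **Step 1 — relative effect.** A target-trial emulation on new users:
   first-ever initiation defines time zero, follow-up runs to the earliest of
   event, death, deregistration, GLP-1 receptor agonist start, crossover
   censoring, administrative end, or 3 years (5 in extended analyses).
   Comparator initiators who later start an SGLT2 inhibitor are censored at
   that date and re-enter the SGLT2i arm from the same date, giving at most
   two non-overlapping follow-up periods per subject; DPP4i/SU starts never
   censor in the pooled analysis. The hazard ratio comes from an
   overlap-weighted Cox model additionally adjusted for the full covariate
   set (doubly robust); effect modification is tested by albuminuria status
   and by a three-knot restricted cubic spline of the risk score interacting
   with treatment, using robust Wald tests.
2. **Step 2 — risk-score performance.** On comparator-arm episodes:
   calibration slope (coefficient of the linear predictor in a fresh Cox
   fit), calibration-in-the-large (ratio of Kaplan–Meier to mean predicted
   3-year survival), censoring-weighted Brier score, Harrell's C; bootstrap
   confidence intervals where requested.
3. **Step 3 — benefit calibration.** Counterfactual ARRs are standardized
   from the doubly robust fit, $ARR_i = S(t|x_i,1) - S(t|x_i,0)$, and
   compared with pARR across pARR deciles and through an individual-level
   least-squares calibration slope.
4. **Step 4 — clinical utility.** Decision curves with net benefit
   $NB(\delta) = \tfrac{1}{N}\sum_{\text{treated}} ARR_i - \delta\,
   \tfrac{n_{\text{treated}}}{N}$ (the treatment-policy form: expected events
   prevented minus a threshold-weighted treatment burden), and a
   threshold-matched comparison in which the pARR cut-off is chosen so that
   the same population share is treated as under the uACR ≥ 3 mg/mmol rule.

# The synthetic cohort generator

UK primary-care EHR databases (CPRD and its linkages) grant access only by
application, so the package ships a
seeded generator whose defaults *are* the study conditions: age truncated
normal 58 ± 11 on [20, 80]; 59% male; published ethnicity, deprivation,
smoking, comorbidity and co-prescription frequencies; BMI 33 ± 7 built from
height and weight so that BMI missingness can operate on the components;
eGFR truncated normal 96 ± 14; uACR log-normal with median 1.1 mg/mmol and
log-SD 1.06 (solved from the published median and IQR 0.6–2.5); diabetes
duration log-normal (median 7, log-SD 0.76); calendar year 2013–2020 with
the published year mix.

**Treatment assignment** is Bernoulli on a logistic index whose coefficients
reproduce the published imbalance directions: insulin use, triple-or-more
glucose-lowering therapy, higher HbA1c and BMI, longer diabetes duration,
higher eGFR, younger age and later calendar year all push toward SGLT2i.
The true propensity is stored only in the latent sidecar.

**Outcomes** follow a Weibull hazard $\Lambda(t) = (\lambda_i t)^{k}$
(exponential, $k=1$, by default — the source evidence reports rates, not
shapes) with $\lambda_i = \lambda_0 \exp(\mathrm{LP}_i + \text{arm} \cdot
\log 0.62)$, where LP is the surrogate risk score's linear predictor
evaluated on the generating covariates. $\lambda_0$ is normalized per cohort
so the mean hazard equals 3.8 events per 1000 person-years, the comparator
rate. Both counterfactual event times are produced from a single shared
uniform draw per subject, so each subject's true ARR is exactly defined and
benefit calibration has a ground truth. Crossover runs on an independent
exponential clock (0.08/year; the mechanism is described in the source
setting, its rate is not, so it is configurable); the post-crossover residual
event time is redrawn under the treated hazard, which is exact for the
exponential default (memoryless) and approximate for other shapes.
Competing censoring (deregistration 0.05/year, non-kidney death 0.01/year,
GLP-1 start 0.03/year) uses independent exponential clocks. Five percent of
composite events are realised as kidney-related deaths (unreported;
configurable); the rest as eGFR declines.

**eGFR series.** Readings are scheduled every 120 days with measurement SD
3 ml/min per 1.73 m², drift −1.5%/year, and are clamped above 55% of
baseline so noise alone never crosses the −50% threshold. An event subject's
trajectory stays stable until 90 days before the event, drops acutely, and
ends with a supporting reading at 45% of baseline on the event day. The
supporting value is anchored at 45% of the *lowest baseline any follow-up
period would resolve* — in particular the re-resolved baseline at a
crossover date — so that detection from the record reproduces the latent
event time in both follow-up periods. Reading frequency and noise have no
published anchor and are exposed as parameters without any claim of source
fidelity.

**What the generator does not emulate:** coding idiosyncrasies and
code-list ambiguity, visit-driven (outcome-dependent) measurement, adherence
and refill gaps (follow-up is deliberately insensitive to refills),
competing-risk-of-death structure beyond an independent censoring clock, and
the real CKD-PC coefficients. Passing tests therefore demonstrate internal
statistical validity of the pipeline, not fidelity of any real-world
estimate.

# The surrogate risk score

The published score's coefficients are not redistributable, so the default
`risk_score_spec` is an openly synthetic surrogate over the same feature
set: linear terms for age (0.020/year), eGFR (−0.015), systolic BP (0.010),
HbA1c (0.012), BMI (0.010); log-uACR (0.45); and indicators for male sex,
smoking, antihypertensive use, regimen intensity, insulin, atrial
fibrillation and heart failure/coronary disease — magnitudes chosen once to
give a plausible risk spread (median 3-year risk ≈ 0.9%, C ≈ 0.66). Its
baseline survival $S_0(3) = 0.9938972$ was calibrated once against a
500,000-draw reference population so that the implied mean comparator hazard
is 3.8 per 1000 person-years; the same spec drives the generator's outcome
model, making the whole pipeline checkable by self-consistency. User-supplied
coefficients (for example, the real ones, if obtained) load via
`read_risk_score()` and flow through every step unchanged.

# Numerical and design choices

* **Ties and baselines.** Efron tie handling (EHR day granularity produces
  ties); the baseline cumulative hazard is stored at the weighted-mean
  covariate profile with treatment at its comparator reference, so
  `predict_survival()` is exactly consistent with the stored baseline.
* **Weights.** Overlap weights $1-e(x)$ / $e(x)$; truncated IPTW clamps at
  the 2nd/98th percentiles of the *combined-arm* weight distribution (arm
  stratification is not specified in the source description). The propensity
  model is fitted to tolerance 1e−12 so the exact-balance identity of
  overlap weights holds to numerical precision; rank deficiency and
  separation are errors, not warnings.
* **Spline.** Three knots at the 10th/50th/90th percentiles of the modifier
  (the conventional placement), non-linear basis normalized by
  $(k_3-k_1)^2$.
* **Sustained eGFR < 15** means two consecutive readings < 15 spanning at
  least 90 days, dated at the second — a standard chronicity window; the
  source wording says only "sustained".
* **Eligibility order** (prior HF/ASCVD → missing labs → eGFR/uACR range →
  ESKD → concurrent GLP-1 → BMI → age → registration) fixes the exclusion
  log counts; baseline labs take the closest reading in the prior 2 years,
  ties to the later reading. Decline thresholds are inclusive. A year is
  365.25 days.
* **Imputation.** PMM with k = 5 donors, 10 chained sweeps, visit order by
  increasing missingness; IMD and smoking by multinomial regression; BMI
  passively as weight/height²; hazard ratios pooled on the log scale;
  Barnard–Rubin degrees of freedom when a complete-data df is supplied.
  The propensity model is refit in each imputed dataset and estimates are
  pooled by Rubin's rules (whether the source refit per imputation is
  unstated; refitting is the conservative choice).
* **Score calibration is assessed on comparator-arm episodes only**, because
  the score predicts untreated natural history; assessing on both arms would
  mix the treatment effect into the calibration slope. Calibration-in-the-
  large is reported as the ratio of observed to mean predicted 3-year
  survival (the exact scale of the published figure is ambiguous; this ratio
  is dimensionless and equals 1 under perfect average calibration).
* **Benefit-calibration slope at the individual level.** Ten decile means
  cannot support a tight slope estimate; the slope is the least-squares
  coefficient over subjects, deciles are used for the calibration plot only.
* **Strategy arithmetic.** "True positives" and "events prevented" are
  model-based expectations ($\sum_{\text{treated}} (1-S_0^{HR})$ and
  $\sum_{\text{treated}} (S_0^{HR}-S_0)$), matching the modelled 3-year
  comparison; observed-count analyses are available through the 5-year
  extended mode. The published phrase about "adjusting the risk score" for
  one of the two groups is ambiguous about direction; here treated subjects'
  risks are HR-adjusted and untreated risks are not, which is the only
  reading consistent with the pARR formula.
* **Subgroup ARR variance** in the extended 5-year analysis propagates only
  the treatment coefficient's robust variance (delta method); baseline
  hazard and covariate-coefficient uncertainty are ignored, which is
  adequate for the Wald contrast of two subgroups but not for absolute CI
  coverage.
* **Seeds.** One master seed expands to per-stage seeds through a
  multiplicative hash (`stage_seed()`); adjacent-integer seeding of
  consecutive stages is avoided deliberately, because nearby Mersenne–
  Twister initializations produced measurably correlated streams (event
  counts inflated by several percent against the closed-form expectation).

# Self-consistency checks and problem sizes

The test suite validates each operation against hand calculations and
brute-force oracles (a grid-search partial-likelihood maximizer, exhaustive
concordant-pair enumeration, exhaustive treated-subset enumeration for
strategy optimality), and the pipeline end to end by parameter recovery:
overlap weighting drives every weighted SMD below 0.01 on confounded
cohorts of 5,000; the doubly robust 95% CI covers HR 0.62 at the nominal
rate over 25 replicate cohorts of 40,000 while the unadjusted estimate is
biased toward the null (treated subjects carry higher outcome risk);
score calibration slope and calibration-in-the-large average 1.0 over
replicates of 20,000; and the benefit-calibration slope averages inside
(0.85, 1.15) over 20 replicate cohorts of 60,000. `scripts/acceptance.R`
re-runs the same checks at larger sizes (one full pipeline at 100,000
subjects with 2 imputations; 30 hazard-ratio replicates of 40,000; 12
benefit replicates of 60,000), sizes chosen to keep a complete run within
roughly fifteen minutes on a single core while leaving each check's Monte
Carlo error well inside its acceptance band.

Two subtleties matter when interpreting these checks. First, a single
cohort's benefit-calibration slope inherits the sampling error of the
fitted treatment coefficient (roughly ±0.2 at n = 60,000), so the
self-consistency estimand is the replicate mean, not any single run.
Second, the within-person lab noise attenuates both the score's effective
coefficients and the counterfactual model when they are evaluated on
measured rather than generating covariates (slope ≈ 0.93 instead of 1.0
under the default noise); the self-consistency checks therefore evaluate
the score on the generating covariates, while the pipeline's reported
calibration on measured covariates retains this realistic attenuation.

# Known limitations

* The surrogate score is not the published score; real-data users must load
  the real coefficients before interpreting absolute risks.
* No competing-risks decomposition: non-kidney death censors rather than
  competes, which overstates absolute risk slightly in the oldest patients.
* The pairwise-comparator mode censors at any other study-drug start but the
  generator does not simulate DPP4i/SU add-on switching, so that mode is
  exercised structurally rather than calibrated.
* Net benefit uses the treatment-policy formulation; cost-effectiveness
  weighting of thresholds is out of scope.
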