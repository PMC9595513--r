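---
title: "Methods: SMR-weighted survival evaluation of a patient-navigation program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMR-weighted survival evaluation of a patient-navigation program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navsurv)
```

## The problem and the estimand

A hospital introduces a patient-navigation program for newly suspected
cancer patients and wants to know whether overall survival improved. The
comparison is observational: an annual cohort treated after implementation
(intervention) against the annual cohort before it (historic control).
Day 0 for every time measurement is the first cancer-suspect code in the
hospital's medical system; follow-up ends at death or the last visit
(right censoring). Patients with an unexpectedly short care delay
(tumor-board meeting within 3 days or treatment start within 7 days),
death before day 30, or loss to follow-up before day 30 are excluded at
eligibility screening, because such patients either arrived with an
already-worked-up cancer or could never have benefited from navigation.

The estimand is the average treatment effect on the treated (ATT): the
survival benefit for the kind of patient the program actually served.
SMR weighting targets it directly — intervention patients keep weight 1,
controls are reweighted by `e(x)/(1 - e(x))` so their covariate
distribution matches the treated cohort's.

## Model chain and assumptions

1. **Propensity model.** Logistic regression of cohort membership on all
   baseline covariates (demographics, residence, clinical onset type,
   histology, onset-to-code delay quartile class, prior investigations)
   except prior scintigraphy, which is performed in too few patients to
   support a coefficient. Assumptions: no unmeasured confounding given
   these covariates, and positivity (`e(x) < 1` for controls).
2. **Weighted Cox models.** The weighted partial likelihood multiplies
   individual score contributions by the SMR weights. Because the weights
   are estimated quantities, not frequencies, all intervals use the robust
   sandwich variance by default. Three fixed specifications are exposed:
   univariate (cohort only), all-baseline, and all-post-baseline; terms
   are never pruned by significance. The post-baseline model deliberately
   conditions on mediators (stage and ECOG at treatment initiation,
   investigations, treatment modalities): its cohort coefficient is a
   mediation probe, not a total effect, and attenuation toward 1 is the
   expected signature of an effect transmitted through earlier, more
   complete diagnostics.
3. **g-computation.** With balance established by weighting, the
   counterfactual model is the univariate weighted Cox fit. Survival is
   predicted per intervention patient at fixed horizons under both values
   of the cohort indicator via `S(t|x) = exp(-H0(t))^{exp(x beta)}` with
   the Breslow baseline cumulative hazard; the effect is the mean
   individual difference. A cohort-stratified bootstrap (resampling
   patients with replacement, preserving the 123/173 design) re-runs the
   *entire* pipeline per replicate — propensity fit, weights, Cox,
   prediction — so the percentile CI propagates weight-estimation
   uncertainty. "Positive benefit" means effect strictly > 0.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| horizons | days | 365, 730, 1095 | "1, 2, 3 years" at day resolution |
| n_bootstrap | replicates | 1000 | study convention; < 1000 logs reduced-replicate mode |
| ties | — | Efron | day-resolution data tie heavily; Efron is the accepted default; Breslow available (and used where exact weight-frequency equivalence matters) |
| robust | — | TRUE | weights are estimated; model-based variance available for comparison |
| balance scale | — | PS | B/R are described as statistics *of propensity scores*; logit-PS exposed as an option |
| extreme_quantile | — | 0.95 | warn (never trim) when the largest control weight exceeds 10× this quantile |
| eligibility bounds | days | ≤3, ≤7, <30 | "within" read inclusively; a day-30 death is retained |

## The synthetic world

The generator emulates the study population, not just "some data": two
cohorts of 173/123; age ≈ N(63.8–64.9, ~9); the printed baseline
marginals including the real imbalances (prior chest CT 68.8% control vs
56.3% intervention, prior bronchoscopy 1.7% vs 8.6%); a zero-prevalence
covariate (prior cytology 0%/0%) kept on purpose so the zero-variance drop
path is always exercised; post-baseline process/treatment/stage/ECOG rates
per cohort (PET-CT 37.6%/47.2%, surgery 23.6%/29.3%, chemotherapy
49.0%/44.7%, stage I+II 11.8%/14.7%, stage IV 41.1%/35.0%). Survival
follows a Weibull proportional-hazards model (shape 1.2, scale 1250 days
at the reference pattern — calibrated once so that simulated deaths per
cohort, ≈80/≈40, and mean follow-up match the study's printed values)
with conditional cohort log-HR log(0.63) and hazard effects for
symptomatic onset (HR 2.0), prior chest CT (HR 0.55) and age (HR
1.03/year). Censoring combines a 1095-day administrative horizon with
exponential dropout (5e-4/day). Event times use the exact Weibull
inverse-transform `T = scale · (−log U · e^{−lp})^{1/shape}`. Rates the
study never prints (radiotherapy, pre-treatment brain imaging and
bronchoscopy, board-recommendation and stage-documentation rates, the
ECOG mix, the delay lognormals) were chosen once as field-plausible values
and are not revisited.

Two assignment modes exist because the estimator needs both: the
historic-control design fixes cohorts and draws covariates per cohort,
while estimator testing draws covariates from pooled marginals and assigns
cohort from a logistic model, giving controllable confounding with a known
conditional effect to recover.

What the generator does *not* emulate — so a green test does not establish
it: staggered accrual (censoring is a fixed horizon, not entry-date
driven), survival-dependent post-baseline variables (they are drawn given
cohort only, so mediation analyses are exercised for plumbing, not
recovered causally), enrollment-stage exclusions upstream of the modelled
variables, and within-patient correlation between investigations.

## Numerical conventions

* **Weighted variance** is `Σw(x − x̄_w)²/Σw` (no small-sample
  correction): frequency-consistent, invariant to uniform weight
  rescaling, hence seed-stable B/R diagnostics.
* **Weighted quantiles** use the inverse-CDF lower-value rule (smallest
  value whose cumulative normalized weight reaches the target); at n ≈ 300
  the convention moves medians by whole days, so it is fixed and tested.
* **Weighted design-based tests** rescale weights to Kish effective sample
  sizes (χ², t with Satterthwaite df, Kruskal-Wallis on weighted average
  ranks); unit weights reproduce the classical tests exactly.
* **Separation policy.** The propensity fit fails loudly only where the
  ATT pipeline actually breaks: a *control* patient with fitted PS → 1
  (exploding weight) or complete separation. A small covariate cell pure
  in one cohort (PS → 0 controls / PS → 1 intervention-only patterns)
  yields zero or unit weights and is tolerated — with ~2–4% category
  levels at n ≈ 300, bootstrap replicates hit such cells routinely and
  the study's own analysis evidently fitted through them. Failed
  replicates are redrawn and counted; > 5% is a hard error.
* **Step conventions.** KM curves and the Breslow cumulative hazard are
  right-continuous; predictions beyond the last event time return the last
  step with an extrapolation warning.
* **Ties.** Efron by default; the weight-frequency equivalence (integer
  weights ≡ replicated records, point estimates exact) holds under
  Breslow, which is what the equivalence tests use — Efron's weighted tie
  correction is intentionally not frequency-consistent.
* **Seeds.** One master seed; stage seeds derive from it via a fixed
  stream (`seed_streams`), all below 2³¹, so stage-level reruns reproduce
  slices of a full run and two runs are byte-identical.

## Non-collapsibility and what the recovery tests check

The hazard ratio is non-collapsible: with covariates that affect the
hazard, the marginal (population-averaged) HR that an ATT-weighted Cox
model estimates is slightly attenuated relative to the conditional HR that
generated the data, even with perfect balance. The confounded test world
therefore keeps covariate hazard effects moderate (binary confounder HR
1.4, age HR 1.015/year — chosen a priori), and the recovery test compares
the pipeline's average estimate against the *marginal ATT truth* computed
by an independent potential-outcomes oracle (treatment randomized over the
treated population's covariates at large n), while also asserting that
this marginal truth stays within 0.05 of log(0.63) and that nominal 95%
CI coverage of the conditional value holds. The naive unweighted contrast
is checked to be biased in the direction built into the assignment model.

Under the null (true HR = 1), the bootstrap proportion-positive for any
*single* dataset is approximately uniform on (0, 1) — it is a one-sided
bootstrap p-value — so calibration ("≈ 0.5") is asserted on the average
over 150 simulated studies, and CI coverage of zero over the same runs.
Bootstrap-vs-point convergence is checked at 300 vs 1200 replicates (a
scaled-down version of the 1000-vs-4000 property, for runtime).

## Design choices that were genuinely open

* **Config files are JSON**, not YAML (no YAML parser in the supported
  dependency set; the interface contract allowed either).
* **Percentile bootstrap CI** (not normal or BCa): the plainest reading of
  a bootstrap "95% CI"; BCa was considered and left out as the study
  reports nothing suggesting it.
* **Stratified resampling by default** preserves the two-sample design
  and the ATT target; unstratified resampling is available.
* **The propensity model is re-estimated inside every bootstrap
  replicate**, mirroring "re-run exactly as for the original sample" and
  propagating weight uncertainty; the alternative (freeze weights) was
  rejected as anti-conservative.
* **Both the point effect and the bootstrap-mean effect are reported**:
  they coincide closely, and published tables may quote either.
* **"Unknown" is a category level, not missingness**, everywhere the
  study tabulates it (onset, delay class, stage, ECOG): hazard ratios are
  estimated for unknown levels rather than imputing or dropping.

## Known limitations

* No proportional-hazards diagnostics, time-varying covariates, or
  competing risks; no PS matching/stratification sensitivity analyses —
  all out of scope by design.
* The deposited study table is not redistributable with the package, so
  the reproduction criterion runs only when the user supplies the file
  (`NAVSURV_DEPOSITED_DATA`); everything else is validated on the
  synthetic world.
* Exact third-decimal replication of published B/R values can depend on
  the original's unstated PS-vs-logit scale and variance conventions;
  both scales are exposed.
* Weighted "effective sample size" reasoning (Kish) is an approximation;
  design-based p-values on heavily weighted data are indicative, not
  exact.
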