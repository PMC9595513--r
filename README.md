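# navsurv

Survival-impact evaluation of patient-navigation (integrated cancer care)
programs against a historic control cohort, for biostatisticians and health
services researchers working with observational hospital data.

The setting: a hospital introduces a navigation program that manages newly
suspected cancer patients from their first cancer-suspect code through
complete diagnostics to treatment. Its effect on overall survival is
assessed by comparing an annual patient cohort after implementation
("intervention") with the annual cohort before it ("control"). Because the
cohorts are not randomized, the package implements the full
confounding-adjusted pipeline:

1. **Propensity-score SMR (ATT) weighting.** A logistic model estimates
   each patient's propensity `e(x) = P(intervention | x)` from baseline
   covariates; weights are `w = 1` for intervention patients and
   `w = e(x) / (1 - e(x))` for controls (standardized-mortality-ratio
   weighting), so the weighted controls match the treated cohort's
   covariate distribution — the average treatment effect on the treated.
2. **Balance diagnostics.** Rubin's B (100 × standardized mean difference
   of the PS between cohorts; B < 25 is adequate) and Rubin's R (PS
   variance ratio; 0.5 ≤ R ≤ 2 is adequate), before and after weighting,
   plus a per-covariate weighted balance table.
3. **Weighted survival analysis.** Weighted Kaplan-Meier curves
   `S(t) = ∏_{t_i ≤ t} (1 − d_w(t_i)/n_w(t_i))`, weighted log-rank tests,
   and weighted Cox proportional-hazards models
   `h(t|x) = h0(t) exp(xβ)` with robust (sandwich) variance — univariate
   (cohort only), all-baseline, and all-post-baseline specifications —
   with a Breslow baseline cumulative hazard for prediction.
4. **Counterfactual g-computation.** From the univariate weighted Cox
   model, each intervention patient's survival at 1/2/3 years is predicted
   twice — as observed and with the cohort indicator flipped to control —
   and the effect is the mean individual difference. Uncertainty comes
   from a cohort-stratified nonparametric bootstrap (default 1000
   replicates) that re-runs the whole pipeline per replicate, reported as
   a percentile 95% CI and the proportion of replicates with a positive
   effect.
5. **Synthetic two-cohort generator.** A configurable world (cohort sizes
   173/123, realistic baseline marginals with a built-in chest-CT /
   bronchoscopy imbalance, Weibull proportional hazards with a cohort
   effect, administrative + dropout censoring, eligibility filters, and an
   optional confounded logistic assignment mode) so the entire chain is
   developed and tested without patient data.

## Worked example

```r
library(navsurv)

rec  <- generate_cohort(synthetic_config(), seed = 2024)  # 173 + 123 patients
prop <- fit_propensity(rec)                # drops zero-variance covariates
w    <- compute_smr_weights(prop$ps, rec$cohort)

rubins_b(prop$ps, rec$cohort); rubins_b(prop$ps, rec$cohort, w)
#> 66.88  ->  5.97        # imbalanced before weighting, balanced after

fit_weighted_cox(rec, w, terms = "cohort")
#> Weighted Cox PH fit (efron ties, robust variance): n = 296, events = 125
#>                term   HR        ci95     p
#>  cohortintervention 0.66 [0.44-1.01] 0.054

bootstrap_effect(rec, n_bootstrap = 200, seed = 99)
#> Counterfactual g-computation of overall survival
#>   point effect        : 1-year +7.8 pp  2-year +12.2 pp  3-year +14.3 pp
#>   bootstrap (200 replicates, 0 failed redrawn):
#>     1-year effect +8.3 pp [0.3, 16.4], P(effect > 0) = 98.0%
#>     ...
```

Reading: the synthetic world was generated with a conditional hazard ratio
of 0.63 for the intervention; after SMR weighting the estimated HR is 0.66
(robust 95% CI 0.44–1.01), and g-computation translates it into absolute
survival gains of about +8 to +14 percentage points at 1–3 years, positive
in 98% of bootstrap replicates.

The whole chain — including the balance table, KM curves/plot, the three
Cox specifications, counterfactual bootstrap, and the delay/process
descriptive tables, all written as CSVs with a reproducible run log — runs
from one call:

```r
res <- run_full_analysis(analysis_config(seed = 1, n_bootstrap = 1000,
                                         out_dir = "out"))
# or from a study CSV: analysis_config(input = "cohort.csv", ...)
```

A CLI wrapper (`inst/scripts/navsurv`) exposes the subcommands
`simulate | analyze | bootstrap | report` with flags `--input --config
--seed --n-bootstrap --horizons --out`.

## Documentation

The methods vignette (`vignettes/navsurv-methods.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, numerical conventions
(tie handling, weighted-variance estimator, quantile rule, separation
policy), and known limitations.
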