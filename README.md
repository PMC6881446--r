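# icudyn

Dynamic 30-day mortality prediction from ICU vital-sign time series in
traumatic brain injury (TBI).

Static TBI prognostic scores (IMPACT-style admission models) are frozen at
admission and cannot react to what actually happens in the ICU. `icudyn`
implements the opposite idea: a *dynamic* prognostic algorithm that re-scores
a patient's 30-day mortality risk every 8 hours from 24 h to 120 h after
admission, using rolling-window features of intracranial pressure (ICP), mean
arterial pressure (MAP), cerebral perfusion pressure (CPP = MAP − ICP) and,
optionally, the motor and eye components of the Glasgow Coma Scale (GCS).

The risk model is a logistic regression on pooled (patient × prediction-time)
rows with constant coefficients,

```
logit P(death ≤ 30 d) = β₀ + Σⱼ βⱼ xⱼ(t),
```

where each feature `xⱼ(t)` is recomputed at every prediction time `t` from
derived rolling-window series (4-h windows for ICP/MAP/CPP, 24-h for GCS
components) and min–max normalized to [0, 1]. Feature aspects follow the
field's naming: `begin` (mean over the first 24 h of monitoring), `end`
(trailing 8 h), `coef` (OLS trend up to `t`), last-window extremes and
threshold-exceedance fractions (`icp_ht20`, `icp_lt10`, `map_ht120`). The
candidate sets comprise 54 dynamic features (+ age category) for the
ICP-MAP-CPP variant and 74 (+ age) for the ICP-MAP-CPP-GCS variant; recursive
feature elimination with patient-grouped cross-validation picks the working
subset. Evaluation is a time-dependent AUC curve under repeated stratified
patient-grouped 5-fold cross-validation, plus misclassification accounting at
a 50 % last-prediction threshold and a static IMPACT-style admission model as
the comparison baseline.

Real patient-level ICU data of this kind is not freely shareable, so the
package ships a synthetic cohort generator (`simulate_cohort()`) that
reproduces the statistical structure such a cohort exhibits — ~19 % 30-day
mortality, higher and rising ICP with lower CPP but matched MAP in
non-survivors, sparse wake-up-test GCS observations, monitoring gaps and
out-of-bounds artifacts — making the entire pipeline testable end to end.

## Worked example

```r
library(icudyn)

cohort   <- simulate_cohort(sim_config(n_patients = 120, seed = 42))
censored <- preprocess_cohort(cohort$vitals, cohort$baseline)
censored
#> <icudyn_censored> 120 included patients (20 deaths), 0 excluded, 377196 grid rows

features <- build_feature_matrix(censored, "ICP-MAP-CPP")
model    <- fit_dynamic_model(features, seed = 1)
model
#> <icudyn_model> ICP-MAP-CPP: 8 dynamic features + agecat, lambda = 0.001
#>   trained on 1118 rows from 120 patients (seed 1)

tracks <- predict_rolling(model, features)
misclassification_report(tracks, censored$patients)
#> <icudyn_misclass> threshold 50%: TP 20, FP 2, TN 98, FN 0, unclassifiable 0

cv <- cross_validated_auc_curve(features, n_repeats = 5, seed = 1)
cv[cv$t_hours %in% c(24, 72, 120), 1:6]
#>   t_hours   auc ci_low ci_high n_patients n_deaths
#> 1      24 0.744  0.668   0.784        120       20
#> 2      72 0.921  0.895   0.951        101       20
#> 3     120 0.973  0.967   0.997         17        2
```

The preprocessing step aggregates raw samples to 5-minute medians, removes
physiologically impossible values (ICP outside [0, 100] mmHg, MAP outside
[20, 150] mmHg), derives CPP, excludes patients with ≤ 24 h of ICP monitoring
or death within 36 h, and censors the final 12 h before death for patients
dying within five days (a treatment-withdrawal guard). The cross-validated
AUC curve shows the characteristic dynamic-prognosis shape: modest
discrimination on day 1 that strengthens as the monitored physiology
diverges between survivors and non-survivors. The misclassification report
classifies each patient by the *last* prediction: a survivor whose last risk
exceeds 50 % is a false positive.

`plot_auc_curve()`, `plot_risk_distribution()`, `plot_calibration()` and
`plot_risk_track()` render the standard views (AUC-over-time, risk violins
by outcome, calibration of the static model, and per-patient contribution
heatmaps); `tidy()`/`glance()` give broom-style summaries of fitted models.

A thin command-line wrapper is installed as `exec/icudyn`
(`icudyn simulate | validate | run-all`), and `run_pipeline()` drives the full
simulate → preprocess → featurize → train → predict → evaluate chain with a
provenance manifest; identical configs and seeds yield bit-identical outputs.

## Scope

The package deliberately excludes imputation of missing vitals (gaps stay
gaps, and a patient drops out of a specific window-based estimate when the
window is empty), frequency-domain or pressure-reactivity features,
nonlinear learners, per-prediction error bars, and the GiViTI calibration
belt (a binned calibration curve stands in for it).
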