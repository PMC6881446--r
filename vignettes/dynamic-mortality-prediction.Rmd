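---
title: "Dynamic mortality prediction from ICU vital signs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic mortality prediction from ICU vital signs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`icudyn` implements a dynamic prognostic algorithm for ICU-treated traumatic
brain injury: a logistic model of 30-day mortality whose coefficients are
fixed once at training time but whose inputs — rolling-window summaries of
intracranial pressure (ICP), mean arterial pressure (MAP), cerebral perfusion
pressure (CPP) and optionally the Glasgow Coma Scale (GCS) motor and eye
components — are recomputed every 8 hours from 24 h to 120 h after admission.
This vignette records the model, its assumptions, and the concrete design
decisions behind the implementation.

## The data model

Raw monitor samples arrive as long-format rows (patient, minute, channel,
value) at 1–5-minute resolution. Preprocessing maps them onto a 5-minute
median grid:

* each sample is assigned to its nearest 5-minute slot, ties at the
  2.5-minute boundary rounding **up** (the convention had to be fixed
  somewhere; half-up keeps the mapping monotone and is the common choice for
  event timestamps);
* each occupied slot carries the **median** of its contributing samples,
  which absorbs duplicated transmissions and single spikes;
* empty slots stay empty. The pipeline never imputes: a missing window
  simply withdraws the patient from that specific window-based estimate.

Artifact filtering removes values that are physiologically impossible rather
than merely extreme: ICP outside [0, 100] mmHg and MAP outside [20, 150]
mmHg. The bounds are **strict** — a value of exactly 100 or 0 survives —
because the rule is phrased as "greater than / less than" and boundary
values are rare but representable. Filtering is applied to the raw samples
*before* median aggregation and once more on the grid with the same bounds:
aggregating medians over raw artifacts would bias grid values, so filtering
pre-median is the conservative order (the alternative order is observably
equivalent on clean data and strictly worse when artifacts cluster).

CPP is derived on the grid as MAP − ICP and exists only at times where both
parents exist (gap propagation).

## Cohort rules

A patient enters the analysis cohort when their censored ICP record spans
more than 24 h. Patients dying within 36 h of admission are excluded, and
for deaths within five days the final 12 h of data are discarded — both rules
guard against learning the signature of treatment withdrawal rather than of
evolving physiology. The monitoring *span* is measured as last minus first
ICP grid time on the **censored** data (gaps ignored): it is the usable
record backing the first prediction that matters, not the nominal monitoring
period. The 30-day clock starts at hospital admission; `death_hour` is
therefore a required baseline field, and a death recorded before admission
is a data-integrity error, not a warning.

## Dynamic features

Every feature is an (signal, statistic, aspect) triple:

* **Derived series.** For each signal, consecutive rolling windows of 4 h
  (ICP/MAP/CPP) or 24 h (GCS components) are tiled from the patient's
  monitoring start, with step equal to the window length. Each window
  contributes one derived point — the window's mean, signed mean of
  consecutive differences (`diff`), population variance (`var`), 90th/10th
  percentile (`q90`/`q10`), extreme (`min`/`max`) or threshold-exceedance
  fraction (`ht20`/`lt10` for ICP, `ht120` for MAP). Windows are half-open
  `(end − length, end]`; the single point exactly at monitoring start is
  folded into the first window.
* **Aspects.** At prediction time `t`: `begin` aggregates the derived points
  of the first 24 h of monitoring, `end` those of the trailing 8 h before
  `t`, `last` takes the most recent derived point in that trailing span, and
  `coef` is the ordinary-least-squares slope (units per hour) of the derived
  series from monitoring start up to `t`.

The candidate enumeration is 54 dynamic features for the ICP-MAP-CPP variant
and 74 for the GCS variant, with the age category appended separately. The
scheme — {mean, diff, var, q90, q10} × {begin, end, coef} plus last-window
extremes and the three threshold fractions per continuous signal; {mean,
var} × {begin, end, coef} plus min/max × {begin, end} per GCS component —
is the unique economical crossing consistent with both printed totals and
with every published final-model feature name (`icp_end`, `map_q10_coef`,
`cpp_diff_begin`, `er_min_end`, …). `published_features()` ships the final
selections (14 and 13 dynamic features) for reference.

Numerical conventions that had to be pinned down: percentiles interpolate
linearly between order statistics (R type 7); `var` divides by *n* (the
population convention — windows are small and the window *is* the population
of interest); `diff` uses signed consecutive differences, so a window that
rises then falls back cancels to zero by design; a single-value window has
variance 0 but an undefined `diff` (missing, not zero). The trend `coef`
needs at least two derived points and is missing otherwise.

Two consequences of anchoring windows at the monitoring start deserve
emphasis. First, a prediction row exists only when `t` is at least 24 h
after the monitoring start, which simultaneously guarantees that the
`begin` window lies entirely in the past of every emitted row (causality is
structural, and the tests assert it by poisoning post-`t` data). Second,
because the GCS derived series steps in 24-h strides, its `end`/`last`
aspects only exist at prediction times that are multiples of 24 h from the
monitoring start; the GCS-variant evaluation is therefore effectively
supported at 24/48/72/96/120 h. The trailing-8-h `end` span is kept for GCS
features for consistency with the published feature descriptions.

Age enters as an ordinal category on five 15-year adult bands
([16, 30), [30, 45), [45, 60), [60, 75), 75+) mapped to {0, 0.25, 0.5,
0.75, 1} — a quartile-like banding around a typical cohort median age in the
late 40s. Ages below 16 are rejected (adult cohort).

All dynamic features are min–max normalized to [0, 1] with bounds fitted on
training rows only; degenerate features (max = min) map to 0.5, and
application-time values are clipped into [0, 1]. The age category is already
encoded in [0, 1] and bypasses the normalizer.

## Model, selection, and the leakage discipline

Training pools all (patient, prediction-time) rows across the schedule: the
model is one set of coefficients applied at every timepoint, so it should be
fit on the whole five-day experience, not on any single timepoint. Rows with
missing candidate values are dropped (no imputation). The fit is maximum
likelihood with a weak L2 penalty (`lambda = 1e-3` on the summed
log-likelihood scale, intercept unpenalized), implemented as iteratively
reweighted least squares with a step-convergence tolerance of `1e-9`. The
penalty exists to keep the recursive-elimination path well-defined under the
heavy collinearity of 54 overlapping window summaries and to keep separable
subsets finite; at `lambda = 0` the fit agrees with `stats::glm` to
numerical precision (asserted in the tests). Non-convergence is reported
with the iteration count, never silently.

Recursive feature elimination drops the candidate with the smallest absolute
coefficient one at a time — ties broken lexicographically by name, so runs
are reproducible — and scores every feature count by held-out AUC in an
inner cross-validation whose folds are stratified by outcome and **grouped
by patient**: a patient's rows never straddle the train/test divide, because
within-patient correlation would otherwise leak outcome information. Score
ties resolve toward fewer features. A single candidate is returned as-is;
zero candidates or a single outcome class is an error.

Evaluation repeats the discipline at the outer level: stratified
patient-grouped 5-fold cross-validation, 20 repetitions by default, with the
normalizer, the elimination and the fit all re-run inside every training
fold. Held-out risks are pooled per repetition; the AUC (rank-based,
midranks for ties) is computed per prediction time; the point estimate is
the mean over repetitions and the 95 % interval the 2.5/97.5 percentiles of
the repetition-level AUCs — a spread-of-repetitions interval, chosen because
the repetition distribution is what the repeated-CV design actually
measures. Repetition seeds derive deterministically from the master seed
(`seed + repetition`). A fold draw that leaves any fold without both classes
is redrawn with a logged warning. Patients lacking a usable feature row at a
given time are excluded from that time's AUC only.

Classification uses the **last** prediction with a strict threshold: a
survivor whose last risk exceeds 50 % is a false positive, with the audit
breakdown (monitoring-duration band, just-above vs clearly-above risk band)
that a clinical review of false positives would want. The static comparison
model refits a logistic regression on the IMPACT-style admission covariates
of the cohort at hand (age, motor score, pupils, hypoxia, hypotension,
Marshall CT class, traumatic SAH, epidural mass, glucose, hemoglobin);
patients missing the two laboratory values fall back to the core covariate
set instead of being imputed or dropped. Its calibration is summarized by an
equal-frequency binned curve of observed versus mean predicted risk.

## The synthetic cohort generator

No patient-level data of this kind is freely shareable, so the generator is
a first-class module: every downstream stage is developed and tested against
cohorts whose relevant structure is known by construction.

Each patient's continuous vitals are AR(1)-perturbed piecewise-linear mean
trajectories sampled at 5-minute intervals: survivors hold a constant
individual ICP level (mean 12 mmHg, between-patient SD 5), non-survivors
start higher (16 mmHg) and drift upward by 3 mmHg/day scaled by
`effect_ramp`, while MAP (85 ± 10 mmHg within, SD 6 between) is distributed
identically in both groups — so CPP separates through ICP alone. Within-noise
is AR(1) with autocorrelation 0.9 and stationary SD 4 mmHg, giving the
minute-scale persistence real monitor traces show. GCS components are
observed only at 12-hourly wake-up tests, lower in non-survivors and
declining in the final 24 h before death. Monitoring durations are normal
(96 ± 24 h) clamped to [30, 144] h — centred on the 3–5-day monitoring
typical of such cohorts, with enough upper tail that the day-5 timepoint
remains evaluable at a few hundred patients. Deaths occur at a 19 % rate,
uniform between 36 h and 30 days, with a configurable 5 % point mass below
36 h purely to exercise the exclusion rule. Gaps (5 % of samples) and
artifacts (2 %, drawn strictly outside the validity bounds and flagged in a
side file, never in the main CSV) corrupt the record the way transfers and
flushes do. Admission covariates are drawn from group-conditional
categorical/lognormal marginals (non-survivors older, worse pupils, larger
mass lesions, higher glucose, lower hemoglobin; matched pre-hospital
hypoxia/hypotension).

What the generator does *not* emulate — and hence what green tests do not
establish about real data: treatment feedback (ICP-lowering interventions
that decouple measured ICP from prognosis, e.g. after decompressive
craniectomy), center heterogeneity, waveform-resolution dynamics,
non-stationary artifact bursts, and informative missingness. The generator's
group contrast is also deliberately strong relative to a real cohort —
useful for verifying that the machinery recovers planted structure, not a
claim about achievable clinical discrimination. In particular the simulated
GCS contrast separates groups more sharply than admission GCS does in
practice.

## Problem sizes and determinism

The test suite checks window statistics and whole feature rows against
brute-force oracles on random grids, recovers planted elimination signal in
≥ 90 % of seeds, verifies chance-level AUC under label permutation (20
shuffle seeds, evaluated with the fixed candidate set so the permutation
isolates the evaluation machinery), and reproduces the rising AUC-over-time
shape on a 300-patient cohort under 5-fold × 5-repetition cross-validation
with elimination refit per fold. `scripts/acceptance.R` re-runs that
computation for both variants from a fresh seed-controlled cohort. These
sizes were chosen as the smallest at which the group structure is stable
across seeds; everything is deterministic given the master seed, and
identical configurations produce bit-identical manifests, model artifacts
(serialized with full 17-digit precision so save → load → predict is
bit-identical) and prediction files.

## Known limitations

Beyond the generator's idealizations: the model family is linear in the
normalized features with constant coefficients over time (by design — the
interpretability of per-feature contributions is the point, at the cost of
inter-feature interactions); predictions carry no per-patient uncertainty;
the GCS variant's evaluation grid is coarse (24-h support, above); and the
published-model feature lists are shipped for reference but the package
always refits coefficients on the cohort at hand rather than applying
published weights.
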