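---
title: "Methods: forecasting intracranial hypertension from early neuromonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting intracranial hypertension from early neuromonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ihpredict)
```

## The prediction problem

After moderate-to-severe traumatic brain injury, intracranial pressure (ICP)
is monitored invasively and intracranial hypertension (IH) is treated once it
occurs. `ihpredict` frames IH as a forecasting target instead: using only the
first 6 h of monitoring ("the feature window"), predict whether the patient
will later develop an IH event — ICP above 22 mmHg sustained for more than
5 min — or a severe event (SIH, sustained more than 1 h). Patients whose ICP
is already persistently above threshold in the feature window are excluded,
because for them the event to be predicted has already happened; so are
recordings shorter than 18 h (too little follow-up to observe the outcome)
and recordings dominated by artifact.

Both outcomes are binary classification tasks on an 11-dimensional feature
vector per patient: three baseline covariates (age, sex, admission Glasgow
Coma Scale), four linear signal summaries (6-h means of ICP, CPP, PRx, RAP)
and four nonlinear complexity summaries (sample entropy and Lempel–Ziv
complexity of ICP and CPP).

## Signal model and preprocessing

Raw channels are uniformly sampled pressures: ICP, mean arterial pressure
(MAP) and ICP pulse amplitude (AMP, the cardiac-cycle peak-to-trough
excursion). Preprocessing averages each channel over non-overlapping 12-s
epochs — long enough to suppress pulse and respiratory waves, short enough to
retain the slow vasogenic waves that carry autoregulatory information — and
then applies a span-4 moving average to remove sharp epoch-scale noise.

Two conventions here were genuinely open and are fixed as follows:

* **Smoothing orientation.** A span-4 *centered* window is ill-defined for an
  even span; we use a trailing (causal) window whose leading edge shortens to
  `min(span, i)` samples. The causal choice also guarantees that no sample
  after the 6-h boundary can influence a feature computed inside it.
* **CPP derivation.** CPP = MAP − ICP is recomputed from the smoothed ICP and
  MAP so the identity holds exactly in every epoch series the package emits.
* **Missing data.** An epoch with more than 50% missing samples is invalid.
  Invalid epochs are never interpolated: correlation windows containing one
  are invalid, and the complexity features drop them (concatenating across
  the gap). Whole-patient artifact burdens above 30% of epochs lead to
  exclusion instead.
* **Labeling uses the unsmoothed epoch series.** The trailing filter delays a
  threshold crossing by up to three epochs; detecting episodes on the raw
  epoch means keeps onset times sharp. Smoothing is a feature-extraction
  device, not part of the outcome definition.

## Index and complexity features

PRx is the moving Pearson correlation between epoch-averaged ICP and MAP, and
RAP the moving correlation between AMP and ICP. The correlation window is 30
epochs (6 min), the common neuromonitoring convention of roughly thirty
samples per correlation estimate; it is exposed as a parameter. Windows are
advanced one epoch at a time, a window with any invalid epoch or zero
variance in either channel yields an invalid value, and the patient-level
features `prx_m` / `rap_m` are means over all valid values in the feature
window.

Sample entropy uses the standard conventions: embedding dimension `m = 2`,
tolerance `r = 0.2` times the standard deviation of the analyzed window
itself, Chebyshev (max-norm) template distance, self-matches excluded, and
both template lengths drawn from starts `1 .. N - m`. SampEn is therefore
invariant to affine rescaling of the series. A constant series returns 0 by
convention; an (m+1)-match count of zero returns `Inf`.

Lempel–Ziv complexity uses LZ76 exhaustive parsing: a phrase ends at the
first symbol that cannot be copied from anywhere earlier in the string (the
copy source may overlap the phrase), and a trailing reproducible phrase
counts as one. The series is binarized at its sample median before parsing —
the median keeps symbol frequencies balanced, which makes the normalized
complexity `c(n) log2(n) / n` comparable across patients; the mean threshold
is available as an alternative. Normalized complexity is reported by default
because it is scale-free in the series length; the raw phrase count is one
flag away.

Both estimators are verified in the test suite against independent oracles: a
brute-force O(N²) template-counting implementation for SampEn, and a
pointer-based Kaspar–Schuster parser plus the literature example string
`"0001101001000101"` (complexity 6) for LZ76.

## Outcome labeling

Episodes are maximal runs of consecutive epochs with ICP *strictly* above
22 mmHg; a run qualifies as IH when its duration *strictly* exceeds 5 min and
as SIH above 60 min. Both inequalities are strict, mirroring the ">"
definitions, so a 5.0-min run or a run exactly at threshold is a negative.
No gap tolerance is applied: one sub-threshold epoch ends a run. An episode
counts toward the outcome if any part of it lies after the feature window,
and time-to-event is measured from the end of the feature window.

The "persistent early hypertension" exclusion is not numerically defined in
clinical practice; the package operationalizes it as first-6-h mean ICP above
22 mmHg *and* more than 80% of first-6-h epochs above threshold, both
parameters exposed. The 30% artifact-burden threshold is likewise a package
definition.

## The synthetic cohort generator

Recordings of this kind are not publicly shareable, so the generator is a
first-class, tested module whose defaults define the study conditions for
every end-to-end check. Each patient's 1-Hz channels are built from:

* a long-timescale smooth drift (AR(1), correlation time hours) carrying most
  of the slow variance — this is what makes the epoch series regular at the
  12–36-s template scale;
* sinusoidal B-waves (60–120 s periods) at a small fraction of the slow
  variance;
* a fast AR(1) component whose per-group scale is the "irregularity" knob;
* for event-positive patients, a logistic-edged plateau at ~29 mmHg planted
  after hour 6, with the edges centered so the 22 mmHg crossing happens at
  the planted onset time (detection then recovers onsets to within one
  epoch).

MAP shares the ICP slow component at a per-group coupling weight ρ, which
controls PRx; the MAP-specific fast noise scale controls CPP complexity; an
ICP-specific slow-wave amplitude controls ICP complexity; and AMP tracks the
shared drift, which keeps RAP comparable across groups. Outcome prevalences
default to 62.3% IH and, conditionally, 30/43 ≈ 69.8% SIH among IH patients
(so 43.5% marginally). Baseline covariates shift with severity: positives are
older and have lower admission GCS; sex is balanced at 66.7% male in all
groups.

Defaults were calibrated once so that a simulated cohort reproduces the
*directions* of the published group contrasts — positives with higher ICP,
PRx, CPP entropy and CPP complexity, lower GCS and ICP complexity, RAP and
CPP means not separating — with standardized effect sizes around 1–2. The
generator makes no attempt to match the absolute magnitudes of the complexity
features of real recordings (its ICP sample entropies are several-fold higher
than typical bedside values, because a three-component stationary model is
far less predictable at template scale than true ICP), nor real artifact
structure, treatment responses, or biophysically faithful hemodynamics
(no Ursino-style model). Consequently, passing end-to-end tests demonstrates
that the pipeline recovers planted structure of realistic geometry — not that
it would achieve the same operating characteristics on clinical data; the
synthetic effects are cleaner than reality and yield optimistic AUCs. The
18-h default recording also caps observable times-to-event at ~12 h after
the feature window, shorter than typical clinical monitoring.

## Modeling workflow

The modeling stage deliberately isolates everything fitted from the held-out
data. For each task:

1. **Stratified 70/30 split**, preserving outcome proportions per class.
2. **RFE-CV** on the training partition: starting from all 11 features, a
   500-tree random forest is fitted, the feature with the lowest unscaled
   permutation importance (Mean Decrease Accuracy on out-of-bag samples) is
   dropped, and the mean 5-fold inner-CV AUC is recorded at every set size.
   The returned set is the size maximizing mean CV AUC, ties going to the
   smaller set.
3. **VIF screening** of the selected set: each feature regressed on the rest
   by least squares, `VIF = 1 / (1 - R²)`, flagged above 5, `Inf` on exact
   collinearity.
4. **Grid search** over `mtry ∈ {1, 2, 3, ⌊√p⌋ + 1}` and minimum node size
   `{1, 5, 10}` (forest size fixed at 500 trees) by mean inner-CV AUC; ties
   resolve to the smaller values.
5. **Cutoff** by Youden's index on the training out-of-bag vote fractions,
   ties broken toward the lowest cutoff. Using OOB votes rather than any test
   data keeps the "optimal unbiased cutoff" leakage-free.
6. **Evaluation**: confusion-matrix metrics at the cutoff (prediction is
   `score > cutoff`, strict) and trapezoidal AUC (identical to the
   Mann–Whitney pair statistic with ties counted ½) on the test partition.
7. **Fivefold cross-validation** on the whole included cohort, re-running the
   *entire* pipeline — imputation, RFE-CV, grid search, cutoff — inside every
   training fold. Whole-cohort CV (rather than CV inside the training
   partition) is the default because the two analyses answer different
   questions: the 70/30 run estimates a deployable model's error, the CV run
   the stability of the workflow.

Missing features are imputed by training-set medians, computed on the
training partition only and stored in the fitted model for reuse at
prediction time. Random-forest fitting, out-of-bag votes, and the two
importance measures come from the `randomForest` package; every stochastic
step takes an explicit seed derived from the master seed, so studies are
bit-reproducible.

## Problem sizes and numerical tolerances

The packaged checks run at sizes chosen to make sampling noise negligible
relative to the planted effects while staying desk-scale: oracle comparisons
on series up to N = 500 (SampEn exact to 1e−10; windowed correlations to
1e−12), planted-feature recovery at n = 300 patients over 20 seeded
replicates, and the end-to-end study on a 200-patient cohort (about four
minutes of compute), where the fivefold-CV AUC floor is 0.75 for SIH and
0.65 for IH and permuted-label nulls must fall within 0.5 ± 0.1. The
acceptance script reports the same study's computed quantities at whatever
seed it is given.

## Known limitations

* The generator's complexity-feature magnitudes are calibrated to contrast
  directions, not clinical magnitudes (see above).
* PRx/RAP correlation windows, the binarization rule, LZ normalization, the
  persistent-early-IH rule and the artifact threshold are package choices for
  quantities the clinical literature leaves unspecified; all are exposed as
  parameters.
* Irregularly sampled input is not resampled — recordings must be uniform.
* No episode merging across short gaps: clinically one might bridge brief
  dips below threshold; the strict definition used here does not.
* The fivefold CV on 69–200 patients has wide fold-to-fold variance; the
  reported SDs should be read alongside the means.
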