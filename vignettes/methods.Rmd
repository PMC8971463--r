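---
title: "Methods: synthetic cohorts, windowed features and subject-independent evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, windowed features and subject-independent evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The analysis in one paragraph

A cohort of children wears a wrist device sampling a 3-axis accelerometer
and 3-axis gyroscope at 50 Hz while performing a 40-item battery of
playful and everyday activities; bouts are annotated as intervals on each
stream. The recognition pipeline segments each stream into overlapping
fixed-length windows (six sizes, 15–149 samples, step 5), computes
time- and frequency-domain features per window, trains one binary
gradient-boosted classifier per activity (positive = that activity,
negative = the other 39) under subject-independent threefold
cross-validation with 20 iterations per window size per fold, summarises
each activity by weighted AUC and accuracy, and finally asks whether the
window size matters by fitting a quadratic AUC-response per activity with
an effect-size relevance rule at 0.05 AUC units over the 15–149 range.

## 2. The synthetic cohort generator

The original recordings are not deposited, so the generator is a
first-class, tested module, not a fixture. It emulates the *statistical
structure* the analysis depends on, and nothing more:

* **Activity signatures.** Each template is a sum of sinusoids per
  channel group (accelerometer, gyroscope) plus Gaussian sensor noise.
  Playful templates carry a fundamental plus one harmonic and long bouts;
  everyday templates carry a single lower-amplitude component and short
  bouts. Frequencies span 0.6–6 Hz (gross-motor cadence), far below the
  25 Hz Nyquist limit, and are validated against it.
* **Subject variability.** Each subject draws a per-channel lognormal
  gain (sd 0.25), a lognormal tempo factor multiplying all frequencies
  (sd 0.10) and a uniform phase. These defaults make subjects clearly
  distinct without destroying activity identity; the leakage
  demonstration raises them (0.4 / 0.18) to model "strong subject random
  effects".
* **Bout scheduling.** Per subject and activity, 2–5 repeats are drawn
  (the battery's instruction), each repeat contributing
  `bouts_per_repeat` coded bouts — fine-grained codings such as pencil
  strokes give `drawing`-like templates 8–25 bouts per repeat. A few
  everyday templates have `p_present = 0.35`, modelling incomplete
  per-child data. Together these reproduce the battery's bout-count
  imbalance (roughly 50 to 2000 positives across the default registry at
  34 subjects, against 31–2656 in the motivating study). Bouts are
  separated by background gaps drawn uniformly from 0.5–2 s.
* **Confusable pairs.** Two templates may share `base_frequencies` and
  differ only in `tempo_factor` (default registry: `pray` vs `clapping`
  at ×1.0 vs ×1.1). Under between-subject tempo sd of 10–12%, a 10%
  within-pair tempo difference is inside the between-subject spread, so
  the pair is separable within a child but confusable across children —
  the mechanism behind "very similar actions, one sensor".
* **Reproducibility.** One root seed; per-subject substreams derived by
  hashing `(seed, "cohort", subject_id)`, so the same configuration and
  seed reproduce the cohort byte-identically and adding subjects never
  perturbs earlier ones.

What the generator does **not** model: biomechanics, gravity orientation,
quaternion attitude, magnetometer drift, sensor saturation, or
non-stationary execution within a bout. A green recovery test therefore
establishes that the pipeline can rank frequency-distinct activities and
expose tempo-confusable ones under subject shift — not that it would
reach any particular AUC on real children.

## 3. Segmentation and the labelling rule

Windows start at 0, 5, 10, …; the count is `floor((T − w)/5) + 1`. The
source description is self-contradictory ("5 sampling unit shifts" vs "an
overlap of 5 sample points"); we take **step = 5** (overlap `w − 5`)
because overlap-driven leakage across CV arms — central to the
subject-dependent/independent contrast — only arises with substantial
overlap, and a 5-point overlap at `w = 149` would be negligible. The
alternative is a `step` argument away.

A window spanning a bout transition is labelled by the activity covering
its **final sample**; this is the only reading of "labelled as the
activity at the end of the bout" under which every window maps to exactly
one activity. Windows whose final sample falls in a background gap get a
reserved sentinel and are dropped before modelling (the task has no null
class); transition windows are kept, flagged `spans_transition`, in both
training and testing — whether the original analysis dropped them is
unstated, so we keep the total function and the flag.

## 4. Features

Per window, 7 signals (6 channels + acceleration Euclidean norm) × 10
statistics = 70 features:

* time domain: mean, median, sample variance, skewness, kurtosis
  (standardized central moments; defined as 0 for constant windows so
  vectors stay finite), range;
* frequency domain, on the one-sided periodogram of the mean-removed
  window (no taper — windows are 0.3–3 s): peak frequency and peak power
  (DC excluded), band power on one default band 0.5–5 Hz, and spectral
  entropy in bits of the normalized periodogram.

The periodogram is scaled so its total equals the centered signal's
population variance (Parseval, tested to 1e-8 relative). For this reason
a separate "full-band power" feature is omitted: it would duplicate the
variance feature exactly. The band list is configuration — the feature
set of the study's own earlier work is unpublished, so this generic
registry (the standard HAR inventory) substitutes for it, and a different
band set can be dropped in without touching the pipeline.

## 5. The classifier

The evaluation contract is "gradient-boosted decision trees, default
hyperparameters, imbalance flag on". No gradient-boosting package exists
in the target environment, so the package ships its own C++ learner built
the way LightGBM's core is: features pre-binned into ≤255 quantile bins,
per-node gradient/hessian histograms, exact greedy split on binned
thresholds, logistic loss, leaf value `−G/(H + λ)`. Defaults: 100 rounds,
learning rate 0.1, depth ≤ 6, ≥ 20 samples per leaf, λ = 0, and
`unbalance = TRUE` up-weights positives by the negative/positive ratio
(the `is_unbalance` semantics). Training is deterministic unless
row/column subsampling is enabled. The backend sits behind
`gbt_backend()`; a logistic (`glm`) backend shares the interface so the
experiment logic stays backend-agnostic, and the two are cross-checked in
the tests.

The source's CV arithmetic ("25 + 25% train, 25% validation, remaining
25% test") cannot describe threefold CV; we implement clean subject-level
3-fold CV (2 folds train, 1 tests) and, when early stopping is enabled,
hold out 25% of the *training subjects* as an inner validation split —
subject-level, so stopping never sees test subjects. "Iterations" are
repetitions with different model seeds and inner splits on fixed outer
folds; with fully deterministic settings and no early stopping they
coincide, which is itself documented behaviour, not a bug.

Weighted AUC averages run AUCs with test-fold positive counts as weights
(the weighting is unspecified in the source; positive count is the
precision of each run's AUC estimate). Accuracy is window-level at
probability 0.5 and is reported only because the literature does; the
dissociation test shows a majority-class predictor reaching accuracy 0.95
with AUC 0.5 on a 95%-negative fold. AUC below 0.5 is reported as-is and
logged, never folded to `max(AUC, 1 − AUC)`.

## 6. Window-size response

Per activity, ordinary least squares of **run-level** AUC (fold ×
iteration points, never per-size means — the jitter in the study's
figures is a plotting device and never enters fitting; an aggregation
switch exists) on `w` and `w²`, in raw sample units, uncentered. Adjusted
R² uses `1 − (1 − R²)(n − 1)/(n − 3)`. The effect size is the achievable
AUC change: max − min of the fitted parabola over [15, 149], evaluated in
closed form at the endpoints and interior vertex (tested against a dense
grid to 1e-9); `relevant ⇔ effect ≥ 0.05`. A local maximum is reported
only for concave fits with the vertex inside the range. Under a flat
truth with run noise sd 0.02 and 60 points per size, the false-relevance
rate of this rule is estimated in the test suite and is small (< 10%).

## 7. The leakage demonstration

The demonstration world uses three *identical* activity templates with
strong subject effects. Then the subject-independent arm has, by
construction, no transferable signal (AUC ≈ 0.5), and any excess of the
subject-dependent arm (window-level random folds) is pure leakage through
step-5 overlapping windows, whose shared fraction `(w − 5)/w` grows from
67% at w = 15 to 97% at w = 149. The gap, averaged over ≥5 cohort seeds,
is positive at every size and non-decreasing in window size. Designing
the arms this way isolates the mechanism; with distinct templates the
same ordering holds but the gap's monotonicity is masked by fold-level
sampling noise in the independent arm.

## 8. Numerical and degenerate-input conventions

* Skewness/kurtosis of constant windows: 0. Spectral features of signals
  that are zero after mean removal: all 0.
* Periodogram bins: `j·fs/n`, `j = 1..⌊n/2⌋`; DC excluded; Nyquist bin
  (even `n`) not doubled.
* AUC: midrank (Mann–Whitney) formulation; `NA` when a class is absent;
  tested against a brute-force pair-counting oracle.
* Folds: subjects shuffled under a derived seed, dealt round-robin, so
  fold sizes differ by at most one (34 subjects → 12/11/11).
* Runs with no positives in training or test are skipped with a
  structured log record, not silently dropped.
* All randomness descends from one root seed via named substreams
  (`cohort/<subject>`, `folds`, `run/<activity>/<w>/<fold>/<iter>`), so
  every table is reproducible from the manifest's config digest + seed.

## 9. Known limitations

* Sinusoid-plus-noise signals are an idealisation; absolute AUCs on this
  world exceed what real child data would give, which is why the
  acceptance suite tests structure (rankings, counts, monotonicity,
  oracle agreement), not headline numbers.
* The in-package booster implements the histogram algorithm but not
  LightGBM's leaf-wise growth, feature bundling or categorical handling;
  with default depth-wise trees it is a faithful, slower cousin.
* The 0.5–5 Hz band is a default, not a claim about the unpublished
  original feature set.
* No multiple-testing correction across the 40 relevance tests, matching
  the analysis being reimplemented.
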