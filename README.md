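# wristhar

Child activity recognition from a wrist-worn inertial measurement unit
(IMU), as a reproducible, fully tested R pipeline.

## The problem

Automatically recognising what a child is doing — hopscotch, drawing,
putting on a sock — from a single wrist-worn 50 Hz
accelerometer + gyroscope is a human activity recognition (HAR) task with
three hard edges:

1. **Severe class imbalance.** A 40-item activity battery produces bout
   counts spanning tens to thousands per activity, so raw accuracy is a
   misleading score and AUC is the primary indicator.
2. **Subject-independent generalisation.** Children differ strongly in
   execution style and tempo. Cross-validation must partition *subjects*,
   not windows: with overlapping sliding windows, window-level
   (subject-dependent) CV places near-duplicate windows on both sides of
   the split and inflates performance — an effect that grows with the
   window size.
3. **Window-size choice.** Sliding-window segmentation needs a window
   length; whether an optimum exists is answered by regressing run-level
   AUC on window size with a quadratic response and an effect-size
   relevance rule.

Because the original recordings are not publicly deposited, the package
ships a first-class synthetic cohort generator that reproduces the
statistical structure the analysis assumes (34 subjects, 40 activities,
2–5 repeats, imbalanced bout counts, subject-level execution variability,
confusable activity pairs differing only in tempo).

## The method

Per subject, the 6-channel stream is segmented with an overlapping sliding
window (sizes w ∈ {15, 32, 60, 81, 100, 149} samples = 0.3–3 s at 50 Hz,
step 5). A window spanning a bout transition is labelled by the activity at
its final sample, so every window maps to exactly one activity. Each
window yields a 70-dimensional feature vector: for each of the 6 channels
plus the acceleration magnitude ‖a‖, the time-domain statistics
(mean, median, s², skewness, kurtosis, range) and periodogram statistics
(peak frequency, peak power, band power on 0.5–5 Hz, spectral entropy).

Recognition is one-vs-rest per activity: a gradient-boosted decision-tree
binary classifier (in-package C++ learner, LightGBM-style histogram
splits, logistic loss, default hyperparameters, imbalance reweighting)
under subject-independent threefold CV — 2 folds train, 1 fold tests, an
inner subject-level validation split for early stopping — with 20
iterations per window size per fold (60 runs per activity per window
size). Per activity we report mean accuracy at threshold 0.5, weighted AUC
(weights = test-fold positive counts), positive bout count and its percent
of all bouts, sorted by AUC.

The window-size effect per activity is the OLS fit
`AUC ~ b0 + b1·w + b2·w²` on run-level points; the *effect size* is
max − min of the fitted curve over w ∈ [15, 149], *relevant* when ≥ 0.05,
with adjusted R² reported alongside and a local maximum only for concave
fits with an interior vertex.

## Worked example

```r
library(wristhar)

acts  <- batb_registry()[c("hopscotch", "drawing", "pray", "clapping")]
types <- vapply(acts, `[[`, "", "activity_type")
cfg   <- cohort_config(n_subjects = 6, activities = acts)
ch    <- generate_cohort(cfg, seed = 42)
ww    <- segment_cohort(ch, window_sizes = c(32L, 60L, 100L), step = 5L)
fbs   <- lapply(ww, function(w) featurize_windows(ch, w))
res   <- run_experiment(fbs, ch$labels, activity_types = types,
                        k = 3, iterations = 2, seed = 1,
                        backend = gbt_backend("gbt", gbt_params(nrounds = 60)))
print(res$summary, digits = 4)
```

```
   activity activity_type accuracy    auc num_pos pos_pct
2   drawing       playful   0.9188 0.9705     337  68.219
3 hopscotch       playful   0.9385 0.9688      98  19.838
4      pray      everyday   0.9278 0.9250      30   6.073
1  clapping      everyday   0.9515 0.9247      29   5.870
```

Read: the playful multi-frequency sequences (`drawing`, `hopscotch`) are
recognised at AUC ≈ 0.97 on unseen subjects, while `pray`/`clapping` — a
configured confusable pair sharing frequencies and differing only in
tempo — rank below them (≈ 0.925), the playful-high/similar-everyday-low
pattern the method is designed to expose. `num_pos` counts labelled bouts
(note `drawing` is coded bout-by-bout, hence its dominance), `pos_pct` its
share of all bouts.

```r
print(fit_window_response(res$runs)[, c("activity", "adj_r2", "effect_size",
                                        "relevant")], digits = 3)
```

```
   activity adj_r2 effect_size relevant
1  clapping  0.471       0.161     TRUE
2   drawing  0.550       0.188     TRUE
3 hopscotch  0.286       0.163     TRUE
4      pray  0.345       0.339     TRUE
```

With three window sizes, 6 subjects and 2 iterations this is an
illustration, not an inference — tiny run counts make the quadratic fits
jumpy. The full grid uses all six sizes and 60 runs per activity per
size.

## Command line

```sh
inst/cli/wristhar all      --config config.yaml --seed 7 --out out/
inst/cli/wristhar simulate --config config.yaml --seed 7 --out out/
inst/cli/wristhar analyze  --runs out/runs.csv --range 15:149 --threshold 0.05
```

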