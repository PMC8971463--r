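# Shared fixture builders. All cohorts are generated in code at test time;
# sizes are kept small so the default run stays well inside its budget.

# minimal registry of n well-separated activities
tiny_registry <- function(n = 2, repeats = c(2L, 5L), bouts = c(1L, 1L),
                          noise_sd = 0.1) {
  freqs <- seq(1, 6, length.out = max(n, 2))[seq_len(n)]
  acts <- lapply(seq_len(n), function(i) activity_template(
    name = paste0("act", i), activity_type = "everyday",
    base_frequencies = list(acc = freqs[i], gyr = 0.6 * freqs[i]),
    amplitudes = list(acc = 0.8, gyr = 0.5),
    bout_duration = c(2, 0.4), repeats_per_subject = repeats,
    bouts_per_repeat = bouts, noise_sd = noise_sd))
  names(acts) <- paste0("act", seq_len(n))
  acts
}

tiny_cohort <- function(n_subjects = 3, n_activities = 2, seed = 42, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                activities = tiny_registry(n_activities, ...)),
                  seed)
}

# recovery world: 4 activities with well-separated frequency signatures
# plus a confusable pair sharing frequencies and differing only in tempo
recovery_registry <- function() {
  sep_f <- c(0.8, 1.8, 3.0, 4.5)
  acts <- list()
  for (i in 1:4) acts[[paste0("sep", i)]] <- activity_template(
    paste0("sep", i), "playful",
    base_frequencies = list(acc = c(sep_f[i], 2 * sep_f[i]), gyr = sep_f[i]),
    amplitudes = list(acc = c(1.2, 0.5), gyr = 0.9),
    bout_duration = c(2.5, 0.6), repeats_per_subject = c(3L, 5L),
    bouts_per_repeat = c(2L, 4L), noise_sd = 0.15)
  f_pair <- list(acc = 6.5, gyr = 3.2)
  tempos <- c(pair_a = 1, pair_b = 1.1)
  for (nm in names(tempos)) {
    acts[[nm]] <- activity_template(nm, "everyday", f_pair,
      amplitudes = list(acc = 0.9, gyr = 0.6), bout_duration = c(2.5, 0.6),
      repeats_per_subject = c(3L, 5L), bouts_per_repeat = c(2L, 4L),
      noise_sd = 0.15, tempo_factor = tempos[[nm]])
  }
  acts
}

recovery_features <- function(seed = 11, window_size = 60L) {
  cfg <- cohort_config(n_subjects = 12, activities = recovery_registry(),
                       subject_sd = list(gain = 0.3, tempo = 0.12))
  ch <- generate_cohort(cfg, seed)
  ww <- segment_cohort(ch, window_size, 5L)
  list(cohort = ch,
       features = featurize_windows(ch, ww[[as.character(window_size)]]))
}

# leakage world: three *identical* templates with strong subject effects,
# so subject-independent AUC is chance and any excess of subject-dependent
# CV is pure window-overlap leakage
leakage_registry <- function() {
  acts <- list()
  for (i in 1:3) acts[[paste0("act", i)]] <- activity_template(
    paste0("act", i), "everyday",
    base_frequencies = list(acc = 2.4, gyr = 1.4),
    amplitudes = list(acc = 0.8, gyr = 0.5),
    bout_duration = c(2.5, 0.6), repeats_per_subject = c(3L, 5L),
    bouts_per_repeat = c(2L, 4L), noise_sd = 0.25)
  acts
}

leakage_contrast_once <- function(seed, window_sizes = WINDOW_SIZES,
                                  nrounds = 60) {
  cfg <- cohort_config(n_subjects = 8, activities = leakage_registry(),
                       subject_sd = list(gain = 0.4, tempo = 0.18))
  ch <- generate_cohort(cfg, seed)
  ww <- segment_cohort(ch, window_sizes, 5L)
  fbs <- lapply(ww, function(w) featurize_windows(ch, w))
  subject_leakage_contrast(fbs, "act2", k = 3, iterations = 1, seed = seed,
                           backend = gbt_backend("gbt",
                                                 gbt_params(nrounds = nrounds)))
}

quiet <- function(expr) {
  out <- NULL
  capture.output(out <- expr)
  out
}
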