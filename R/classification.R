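#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) formulation with midrank tie handling:
#' the probability that a random positive scores above a random negative.
#' Invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical) true labels.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Subject-level cross-validation folds
#'
#' Random partition of subjects into `k` folds of as-equal-as-possible
#' size. Because folds partition subjects (not windows), no individual
#' contributes data to both the training and the test side of any run:
#' subject-independent cross-validation.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param k number of folds (default 3).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return object of class `cv_split`: named integer vector mapping
#'   subject id to fold index in `0:(k-1)`.
#' @export
make_subject_folds <- function(subject_ids, k = 3L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (k < 2) stop("k must be >= 2")
  if (length(subject_ids) < k)
    stop(sprintf("need at least %d subjects for %d folds", k, k))
  perm <- with_seed(seed, sample(subject_ids))
  fold <- (seq_along(perm) - 1L) %% k
  structure(stats::setNames(as.integer(fold), perm), class = "cv_split", k = k)
}

#' Weighted AUC across runs
#'
#' Mean of run-level AUCs weighted by each run's test-fold positive count
#' (runs whose test fold saw more positives estimate AUC more precisely).
#'
#' @param runs data.frame with columns `auc` and `n_test_positives`.
#' @return weighted mean AUC.
#' @export
weighted_auc <- function(runs) {
  stopifnot(nrow(runs) >= 1)
  w <- runs$n_test_positives
  if (sum(w) == 0) stop("all run weights are zero")
  sum(runs$auc * w) / sum(w)
}

# split training subjects into core-train and inner validation (by subject,
# so early stopping never sees test subjects and stays leakage-free)
inner_validation_split <- function(train_subjects, fraction, seed) {
  if (fraction <= 0 || length(train_subjects) < 4)
    return(list(train = train_subjects, valid = character(0)))
  nv <- max(1L, round(fraction * length(train_subjects)))
  if (nv >= length(train_subjects)) nv <- length(train_subjects) - 1L
  vsubj <- with_seed(seed, sample(train_subjects, nv))
  list(train = setdiff(train_subjects, vsubj), valid = vsubj)
}

#' Train and evaluate one one-vs-rest run
#'
#' Fits a binary classifier (positive = `target` activity, negative = all
#' other activities) on the windows of the training-fold subjects and
#' evaluates on the held-out fold: ROC-AUC plus accuracy at the 0.5
#' probability threshold (reported for literature comparability only; on
#' imbalanced data accuracy is misleading).
#'
#' @param fs a `feature_set` (see [featurize_windows()]).
#' @param target activity identifier.
#' @param split a `cv_split` from [make_subject_folds()].
#' @param fold test fold index.
#' @param iteration iteration index (seeds the model and the inner
#'   validation split).
#' @param backend classifier backend ([gbt_backend()]).
#' @param seed root seed.
#' @param validation_fraction fraction of training subjects held out for
#'   early stopping (0 disables the inner split).
#' @return one-row data.frame (`RunResult`): activity, window_size, fold,
#'   iteration, auc, accuracy, n_test_windows, n_test_positives; or `NULL`
#'   if the run is skipped (no positives in training or test), with a
#'   structured log record.
#' @export
train_eval_binary <- function(fs, target, split, fold, iteration = 1L,
                              backend = gbt_backend(), seed = 1L,
                              validation_fraction = 0.25) {
  subj <- fs$windows$subject_id
  y <- as.numeric(fs$windows$label == target)
  test_subjects <- names(split)[split == fold]
  train_subjects <- names(split)[split != fold]
  stopifnot(length(intersect(train_subjects, test_subjects)) == 0)
  run_seed <- derive_seed(seed, "run", target, fs$window_size, fold, iteration)
  inner <- inner_validation_split(train_subjects, validation_fraction, run_seed)
  tr <- subj %in% inner$train
  va <- subj %in% inner$valid
  te <- subj %in% test_subjects
  if (sum(y[tr]) == 0 || sum(y[te]) == 0) {
    log_msg("WARN", "evaluate",
            "skipped run: activity=%s window=%d fold=%d iter=%d (%s positives)",
            target, fs$window_size, fold, iteration,
            if (sum(y[tr]) == 0) "no training" else "no test")
    return(NULL)
  }
  valid <- if (any(va) && sum(y[va]) > 0 && sum(1 - y[va]) > 0)
    list(X = fs$X[va, , drop = FALSE], y = y[va]) else NULL
  model <- backend$fit(fs$X[tr, , drop = FALSE], y[tr], valid = valid,
                       seed = run_seed)
  p <- backend$predict(model, fs$X[te, , drop = FALSE])
  auc <- auc_score(p, y[te])
  if (!is.na(auc) && auc < 0.5)
    log_msg("INFO", "evaluate", "AUC below 0.5: activity=%s window=%d fold=%d iter=%d auc=%.3f",
            target, fs$window_size, fold, iteration, auc)
  data.frame(activity = target, window_size = fs$window_size, fold = fold,
             iteration = iteration, auc = auc,
             accuracy = mean((p >= 0.5) == (y[te] == 1)),
             n_test_windows = sum(te), n_test_positives = sum(y[te]),
             stringsAsFactors = FALSE)
}

#' Run the full one-vs-rest experiment grid
#'
#' For each window size and each activity: `k` folds x `iterations`
#' repetitions (with default `k = 3`, `iterations = 20`: 60 runs per
#' activity per window size). Outer subject folds are fixed per window
#' size; iterations differ in model seed and inner validation split.
#'
#' @param features_by_size named list of `feature_set`s, one per window
#'   size (names = window size), e.g. built via [segment_cohort()] +
#'   [featurize_windows()].
#' @param labels cohort label intervals (for bout counts).
#' @param activities activity identifiers to evaluate (default: all
#'   labelled activities).
#' @param activity_types optional named character vector mapping activity
#'   to `"playful"`/`"everyday"` for the summary table.
#' @param k folds (default 3).
#' @param iterations repetitions per window size per fold (default 20).
#' @param seed root seed.
#' @param backend classifier backend.
#' @param validation_fraction see [train_eval_binary()].
#' @param refold_per_size draw new outer folds per window size
#'   (default FALSE: one fold assignment for all sizes).
#' @return list with `runs` (all `RunResult` rows) and `summary`
#'   (per-activity table, see [summarize_activity_results()]).
#' @export
run_experiment <- function(features_by_size, labels, activities = NULL,
                           activity_types = NULL, k = 3L, iterations = 20L,
                           seed = 1L, backend = gbt_backend(),
                           validation_fraction = 0.25,
                           refold_per_size = FALSE) {
  stopifnot(length(features_by_size) >= 1)
  if (is.null(activities)) {
    activities <- sort(unique(unlist(lapply(features_by_size,
                                            function(f) f$windows$label))))
    activities <- setdiff(activities, BACKGROUND)
  }
  all_subjects <- sort(unique(unlist(lapply(features_by_size,
                                            function(f) f$windows$subject_id))))
  base_split <- make_subject_folds(all_subjects, k, derive_seed(seed, "folds"))
  runs <- list()
  for (wname in names(features_by_size)) {
    fs <- features_by_size[[wname]]
    split <- if (refold_per_size)
      make_subject_folds(all_subjects, k, derive_seed(seed, "folds", wname))
    else base_split
    for (act in activities) {
      for (fold in 0:(k - 1)) {
        for (it in seq_len(iterations)) {
          rr <- train_eval_binary(fs, act, split, fold, it, backend,
                                  seed, validation_fraction)
          if (!is.null(rr)) runs[[length(runs) + 1]] <- rr
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  list(runs = runs,
       summary = summarize_activity_results(runs, labels, activity_types))
}

#' Per-activity summary table
#'
#' Aggregates run-level results into one row per activity: mean accuracy,
#' weighted AUC (weights = test-fold positive counts), the number of
#' positive bouts of the activity in the dataset (`num_pos`) and its share
#' of all bouts (`pos_pct`, percent). Sorted by AUC descending, highest
#' recognition on top.
#'
#' @param runs run-level results from [run_experiment()].
#' @param labels cohort label intervals (bout counts).
#' @param activity_types optional named map activity -> type.
#' @return data.frame: activity, activity_type, accuracy, auc, num_pos,
#'   pos_pct.
#' @export
summarize_activity_results <- function(runs, labels, activity_types = NULL) {
  total_bouts <- nrow(labels)
  acts <- unique(runs$activity)
  rows <- lapply(acts, function(a) {
    ra <- runs[runs$activity == a, , drop = FALSE]
    np <- sum(labels$activity == a)
    data.frame(activity = a,
               activity_type = if (!is.null(activity_types))
                 unname(activity_types[a]) else NA_character_,
               accuracy = mean(ra$accuracy),
               auc = weighted_auc(ra),
               num_pos = np,
               pos_pct = if (total_bouts > 0) 100 * np / total_bouts else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc), , drop = FALSE]
}

# window-level (subject-dependent) fold assignment: windows of one subject
# may land on both sides of a split, and overlapping neighbours usually do
make_window_folds <- function(n_windows, k = 3L, seed = 1L) {
  with_seed(seed, sample.int(k, n_windows, replace = TRUE) - 1L)
}

#' Subject-dependent vs subject-independent CV contrast
#'
#' Runs the same one-vs-rest pipeline for one activity across window
#' sizes under two fold designs: subject-level folds (subject-independent
#' CV) and window-level random folds (subject-dependent CV). With
#' overlapping windows, window-level folds place near-duplicate windows
#' on both sides of the split, inflating AUC; the inflation grows with
#' the window size because the shared fraction `(w - step)/w` grows.
#'
#' @param features_by_size named list of `feature_set`s per window size.
#' @param activity target activity.
#' @param k folds.
#' @param iterations repetitions per fold.
#' @param seed root seed.
#' @param backend classifier backend.
#' @return data.frame: window_size, auc_dependent, auc_independent, gap.
#' @export
subject_leakage_contrast <- function(features_by_size, activity, k = 3L,
                                     iterations = 1L, seed = 1L,
                                     backend = gbt_backend()) {
  all_subjects <- sort(unique(unlist(lapply(features_by_size,
                                            function(f) f$windows$subject_id))))
  if (length(all_subjects) < 2) stop("need at least 2 subjects")
  split <- make_subject_folds(all_subjects, k, derive_seed(seed, "folds"))
  rows <- lapply(names(features_by_size), function(wname) {
    fs <- features_by_size[[wname]]
    y <- as.numeric(fs$windows$label == activity)
    # subject-independent arm
    indep <- list()
    for (fold in 0:(k - 1)) for (it in seq_len(iterations)) {
      rr <- train_eval_binary(fs, activity, split, fold, it, backend, seed,
                              validation_fraction = 0)
      if (!is.null(rr)) indep[[length(indep) + 1]] <- rr
    }
    indep <- do.call(rbind, indep)
    # subject-dependent arm: window-level folds, same classifier settings
    wfold <- make_window_folds(nrow(fs$X), k,
                               derive_seed(seed, "wfolds", wname))
    dep <- list()
    for (fold in 0:(k - 1)) for (it in seq_len(iterations)) {
      te <- wfold == fold; tr <- !te
      if (sum(y[tr]) == 0 || sum(y[te]) == 0) next
      model <- backend$fit(fs$X[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, "dep", wname, fold, it))
      p <- backend$predict(model, fs$X[te, , drop = FALSE])
      dep[[length(dep) + 1]] <- data.frame(auc = auc_score(p, y[te]),
                                           n_test_positives = sum(y[te]))
    }
    dep <- do.call(rbind, dep)
    data.frame(window_size = fs$window_size,
               auc_dependent = weighted_auc(dep),
               auc_independent = weighted_auc(indep))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$window_size), , drop = FALSE]
  out$gap <- out$auc_dependent - out$auc_independent
  rownames(out) <- NULL
  out
}
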