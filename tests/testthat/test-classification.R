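test_that("subject folds are balanced, exhaustive and reproducible", {
  ids34 <- sprintf("S%02d", 1:34)
  f <- make_subject_folds(ids34, 3, seed = 2)
  expect_setequal(names(f), ids34)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE), c(12, 11, 11))
  expect_identical(f, make_subject_folds(ids34, 3, seed = 2))
  expect_false(identical(f, make_subject_folds(ids34, 3, seed = 3)))
  f3 <- make_subject_folds(c("a", "b", "c"), 3, 1)
  expect_equal(as.vector(table(f3)), c(1, 1, 1))
  expect_error(make_subject_folds(c("a", "b"), 3, 1), "at least 3 subjects")
})

test_that("weighted AUC reduces correctly", {
  runs <- data.frame(auc = c(0.8, 0.6), n_test_positives = c(10, 30))
  expect_equal(weighted_auc(runs), 0.65)
  expect_equal(weighted_auc(data.frame(auc = 0.71, n_test_positives = 4)), 0.71)
  eq <- data.frame(auc = c(0.9, 0.7, 0.5), n_test_positives = c(5, 5, 5))
  expect_equal(weighted_auc(eq), mean(eq$auc))
  expect_error(weighted_auc(data.frame(auc = 0.7, n_test_positives = 0)),
               "weights")
})

test_that("one run trains on train-fold subjects only and reports counts", {
  rf <- recovery_features(seed = 61, window_size = 32L)
  fs <- rf$features
  split <- make_subject_folds(unique(fs$windows$subject_id), 3, 5)
  rr <- train_eval_binary(fs, "sep1", split, fold = 0, iteration = 1,
                          backend = gbt_backend("gbt", gbt_params(nrounds = 30)),
                          seed = 9)
  expect_s3_class(rr, "data.frame")
  test_subjects <- names(split)[split == 0]
  expect_equal(rr$n_test_windows,
               sum(fs$windows$subject_id %in% test_subjects))
  expect_equal(rr$n_test_positives,
               sum(fs$windows$subject_id %in% test_subjects &
                     fs$windows$label == "sep1"))
  expect_true(rr$auc >= 0 && rr$auc <= 1)
  # a target absent from the whole cohort is skipped with a log record
  expect_output(
    rr0 <- train_eval_binary(fs, "no_such_activity", split, 0, 1,
                             backend = gbt_backend("gbt",
                                                   gbt_params(nrounds = 5)),
                             seed = 9),
    "skipped run")
  expect_null(rr0)
})

test_that("experiment bookkeeping: runs = activities x folds x iterations", {
  ch <- tiny_cohort(6, 2, seed = 19, bouts = c(2L, 3L))
  ww <- segment_cohort(ch, 32L, 5L)
  fbs <- list("32" = featurize_windows(ch, ww[["32"]]))
  res <- run_experiment(fbs, ch$labels, k = 3, iterations = 2, seed = 3,
                        backend = gbt_backend("gbt", gbt_params(nrounds = 5)))
  expect_equal(nrow(res$runs), 2 * 3 * 2)   # 2 activities x 3 folds x 2 iters
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$summary$num_pos,
               as.vector(table(ch$labels$activity)[res$summary$activity]))
  expect_equal(sum(res$summary$pos_pct), 100)
  # sorted by AUC descending
  expect_true(all(diff(res$summary$auc) <= 0))
  # determinism end to end
  res2 <- run_experiment(fbs, ch$labels, k = 3, iterations = 2, seed = 3,
                         backend = gbt_backend("gbt", gbt_params(nrounds = 5)))
  expect_identical(res$runs, res2$runs)
})

test_that("no subject ever appears on both sides of a split", {
  ids <- sprintf("S%02d", 1:10)
  for (seed in 1:10) {
    f <- make_subject_folds(ids, 3, seed)
    for (k in 0:2)
      expect_length(intersect(names(f)[f == k], names(f)[f != k]), 0)
  }
})

test_that("accuracy and AUC dissociate under class imbalance", {
  # majority-class predictor on a 95%-negative test set
  y <- c(rep(0, 950), rep(1, 50))
  scores <- rep(0, 1000)          # constant score = predict negative always
  acc <- mean((scores >= 0.5) == (y == 1))
  expect_equal(acc, 0.95)
  expect_equal(auc_score(scores, y), 0.5)
  # label-independent random scores give AUC ~ 0.5 (permutation oracle)
  set.seed(10)
  aucs <- replicate(50, auc_score(rnorm(2000), rbinom(2000, 1, 0.1)))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})
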