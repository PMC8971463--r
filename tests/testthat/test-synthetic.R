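test_that("cohort scheduler produces the configured bout counts", {
  # empty cohort
  empty <- generate_cohort(cohort_config(n_subjects = 0,
                                         activities = tiny_registry(1)), 1)
  expect_length(empty$streams, 0)
  expect_equal(nrow(empty$labels), 0)

  # 3 subjects x 2 activities x exactly 5 repeats -> 30 intervals
  ch <- tiny_cohort(n_subjects = 3, n_activities = 2, seed = 7,
                    repeats = c(5L, 5L), bouts = c(1L, 1L))
  expect_length(ch$streams, 3)
  expect_equal(nrow(ch$labels), 3 * 2 * 5)
  expect_equal(as.vector(table(ch$labels$subject_id)), rep(10, 3))
})

test_that("default battery configuration matches the study contract", {
  reg <- batb_registry()
  expect_length(reg, 40)
  types <- vapply(reg, `[[`, "", "activity_type")
  expect_gte(sum(types == "playful"), 10)
  # every template keeps its frequencies below Nyquist at 50 Hz
  for (tpl in reg) {
    expect_lt(max(unlist(tpl$base_frequencies)) * tpl$tempo_factor, 25)
    expect_true(all(tpl$repeats_per_subject == c(2L, 5L)))
  }
  cfg <- cohort_config()
  expect_equal(cfg$n_subjects, 34)
  expect_equal(cfg$sampling_rate, 50)
  # a confusable pair is configured: shared frequencies, different tempo
  expect_identical(reg$pray$base_frequencies, reg$clapping$base_frequencies)
  expect_true(reg$pray$tempo_factor != reg$clapping$tempo_factor)
})

test_that("default cohort yields one 50 Hz stream per subject", {
  # scaled down to 6 subjects: stream count and rate are per-subject
  # properties, independent of cohort size
  ch <- generate_cohort(cohort_config(n_subjects = 6), 3)
  expect_length(ch$streams, 6)
  expect_true(all(vapply(ch$streams, `[[`, 0, "sampling_rate") == 50))
  # every labelled activity comes from the registry; rare templates
  # (p_present < 1) may legitimately be absent in a 6-subject cohort
  seen <- unique(ch$labels$activity)
  expect_true(all(seen %in% names(batb_registry())))
  expect_gte(length(seen), 33)
})

test_that("cohort generation is reproducible and subject-stable", {
  a <- tiny_cohort(3, 2, seed = 99)
  b <- tiny_cohort(3, 2, seed = 99)
  expect_identical(a, b)
  d <- tiny_cohort(3, 2, seed = 100)
  expect_false(identical(a$streams[[1]]$samples, d$streams[[1]]$samples))
  # adding subjects does not perturb earlier ones (hierarchical substreams)
  big <- generate_cohort(cohort_config(n_subjects = 5,
                                       activities = tiny_registry(2)), 99)
  expect_identical(a$streams[["S01"]], big$streams[["S01"]])
  expect_identical(a$streams[["S03"]], big$streams[["S03"]])
})

test_that("labels stay inside their streams and never overlap", {
  ch <- tiny_cohort(4, 3, seed = 5, bouts = c(1L, 3L))
  for (sid in names(ch$streams)) {
    li <- ch$labels[ch$labels$subject_id == sid, ]
    expect_true(all(li$start_index >= 0))
    expect_true(all(li$end_index > li$start_index))
    expect_true(all(li$end_index <= nrow(ch$streams[[sid]]$samples)))
    li <- li[order(li$start_index), ]
    if (nrow(li) > 1)
      expect_true(all(li$start_index[-1] >= li$end_index[-nrow(li)]))
  }
  expect_false(any(duplicated(ch$labels$bout_id)))
})

test_that("bout-count imbalance spans an order of magnitude when configured", {
  acts <- c(tiny_registry(1, bouts = c(1L, 1L)),
            stats::setNames(tiny_registry(1, bouts = c(12L, 20L)), "act_freq"))
  acts$act_freq$name <- "act_freq"
  ch <- generate_cohort(cohort_config(n_subjects = 6, activities = acts), 21)
  tab <- table(ch$labels$activity)
  expect_gte(max(tab) / min(tab), 10)
})

test_that("activity_signal honours amplitudes, noise and Nyquist", {
  tpl <- activity_template("t", "everyday",
                           base_frequencies = list(acc = 2, gyr = 2),
                           amplitudes = list(acc = 0, gyr = 0),
                           noise_sd = 0)
  prof <- subject_profile("s", gain = 1, tempo = 1, phase_offset = 0)
  expect_equal(activity_signal(tpl, prof, 100, 50), matrix(0, 100, 6))

  # single 2 Hz component: discrete-Fourier peak at the 2 Hz bin
  tpl2 <- activity_template("t2", "everyday",
                            base_frequencies = list(acc = 2, gyr = 2),
                            amplitudes = list(acc = 1, gyr = 1),
                            noise_sd = 0)
  sig <- activity_signal(tpl2, prof, 500, 50)
  pg <- abs(fft(sig[, 1] - mean(sig[, 1])))^2
  peak_bin <- which.max(pg[2:250])        # exclude DC, one-sided
  expect_equal(peak_bin * 50 / 500, 2)    # bin frequency = 2 Hz exactly

  # noise sd recovered by Monte Carlo
  tpl3 <- activity_template("t3", "everyday",
                            base_frequencies = list(acc = 2, gyr = 2),
                            amplitudes = list(acc = 0, gyr = 0),
                            noise_sd = 0.1)
  set.seed(1)
  sig3 <- activity_signal(tpl3, prof, 10000, 50)
  expect_equal(sd(sig3[, 1]), 0.1, tolerance = 0.1)
  expect_lt(abs(sd(as.vector(sig3)) - 0.1), 0.01)

  # effective frequency at or above Nyquist is rejected, naming the frequency
  fast <- subject_profile("f", tempo = 20)
  expect_error(activity_signal(tpl2, fast, 10, 50), "Nyquist")
})

test_that("configuration and scheduling errors are raised", {
  expect_error(cohort_config(activities = list()), "empty activity registry")
  acts <- tiny_registry(1, repeats = c(5L, 5L))
  expect_error(
    generate_cohort(cohort_config(n_subjects = 1, activities = acts,
                                  max_samples = 200), 1),
    "scheduling error.*S01.*act1")
  expect_error(activity_template("x", "everyday",
                                 base_frequencies = list(acc = 1, gyr = 1),
                                 amplitudes = list(acc = -1, gyr = 1)),
               "amplitudes")
  expect_error(activity_template("x", "everyday",
                                 base_frequencies = list(acc = 1, gyr = 1),
                                 amplitudes = list(acc = 1, gyr = 1),
                                 bout_duration = c(0, 1)),
               "bout_duration")
  expect_error(subject_profile("s", gain = -1), "gain")
})
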