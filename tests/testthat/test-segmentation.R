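# brute-force oracle: enumerate every admissible start position
count_windows_oracle <- function(T, w, step) {
  starts <- 0
  n <- 0
  while (starts + w <= T) { n <- n + 1; starts <- starts + step }
  n
}

test_that("window counts match brute-force enumeration", {
  expect_equal(nrow(segment_stream(100L, 15L, 5L)), 18)
  expect_equal(segment_stream(100L, 15L, 5L)$start_index, seq(0L, 85L, 5L))
  # boundary cases
  expect_equal(nrow(segment_stream(60L, 60L, 5L)), 1)
  w149 <- segment_stream(149L, 149L, 5L)
  expect_equal(nrow(w149), 1)
  expect_equal(w149$start_index, 0L)
  # randomized property vs the oracle
  set.seed(404)
  for (i in 1:60) {
    T <- sample(20:4000, 1); w <- sample(5:T, 1); step <- sample(1:40, 1)
    got <- nrow(segment_stream(T, w, step))
    expect_equal(got, count_windows_oracle(T, w, step))
    expect_identical(got, as.integer((T - w) %/% step + 1))
  }
})

test_that("oversized windows yield an empty result with a warning", {
  expect_warning(res <- segment_stream(100L, 149L, 5L), "exceeds stream length")
  expect_equal(nrow(res), 0)
})

test_that("increasing the step weakly decreases the window count", {
  set.seed(7)
  for (i in 1:20) {
    T <- sample(100:2000, 1); w <- sample(5:80, 1)
    counts <- vapply(1:20, function(s) nrow(segment_stream(T, w, s)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("window labels follow the end-of-window rule", {
  # stream of 30 samples: bout A on [0,10), bout B on [10,15), gap after 20
  labs <- data.frame(subject_id = "s", activity = c("A", "B"),
                     start_index = c(0L, 10L), end_index = c(10L, 15L),
                     bout_id = c("b1", "b2"), stringsAsFactors = FALSE)
  win <- data.frame(subject_id = "s",
                    start_index = c(0L, 0L, 5L, 14L),
                    window_size = c(10L, 15L, 10L, 10L))
  lw <- label_windows(win, labs, 30L)
  # fully inside A
  expect_equal(lw$label[1], "A")
  expect_false(lw$spans_transition[1])
  # spans the A->B transition: labelled as the activity at its end
  expect_equal(lw$label[2], "B")
  expect_true(lw$spans_transition[2])
  # spans A then B, ends inside B
  expect_equal(lw$label[3], "B")
  expect_true(lw$spans_transition[3])
  # final sample in background gap -> sentinel
  expect_equal(lw$label[4], BACKGROUND)
})

test_that("every labelled window's final sample carries that label", {
  ch <- tiny_cohort(3, 2, seed = 12)
  ww <- segment_cohort(ch, c(15L, 60L), 5L)
  for (w in ww) {
    for (sid in unique(w$subject_id)) {
      sw <- w[w$subject_id == sid, ]
      lab <- wristhar:::sample_labels(nrow(ch$streams[[sid]]$samples),
                                      ch$labels[ch$labels$subject_id == sid, ])
      expect_identical(sw$label, lab[sw$start_index + sw$window_size])
      expect_false(any(sw$label == BACKGROUND))   # background dropped
    }
  }
  # keep_background retains sentinel windows
  wb <- segment_cohort(ch, 60L, 5L, keep_background = TRUE)[["60"]]
  expect_true(any(wb$label == BACKGROUND))
})

test_that("window seconds conversion matches the 50 Hz grid", {
  expect_equal(window_seconds(100, 50), 2.0)
  expect_equal(window_seconds(60, 50), 1.2)
  expect_equal(window_seconds(50, 50), 1.0)
  expect_error(window_seconds(100, 0), "sampling_rate")
})
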