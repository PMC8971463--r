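#' Window sizes used throughout the analysis
#'
#' Six sliding-window lengths in samples (0.3-3 s at 50 Hz).
#' @export
WINDOW_SIZES <- c(15L, 32L, 60L, 81L, 100L, 149L)

#' Window length in seconds
#'
#' @param window_size window length in samples.
#' @param sampling_rate Hz (> 0).
#' @return seconds, `window_size / sampling_rate`.
#' @export
window_seconds <- function(window_size, sampling_rate = 50) {
  if (any(sampling_rate <= 0)) stop("sampling_rate must be > 0")
  window_size / sampling_rate
}

#' Overlapping sliding-window segmentation
#'
#' Cuts a stream into fixed-length windows starting at
#' `0, step, 2*step, ...`; the number of windows is
#' `floor((T - w) / step) + 1`. Windows are unlabelled; see
#' [label_windows()].
#'
#' @param stream an [imu_stream()], or its length in samples.
#' @param window_size window length in samples.
#' @param step shift between successive windows in samples (default 5, so
#'   adjacent windows overlap by `window_size - 5`).
#' @return data.frame `subject_id, start_index, window_size` ordered by
#'   `start_index`; zero rows (with a warning) if the stream is shorter
#'   than the window.
#' @export
segment_stream <- function(stream, window_size, step = 5L) {
  if (step < 1) stop("step must be >= 1")
  if (window_size < 1) stop("window_size must be > 0")
  if (inherits(stream, "imu_stream")) {
    n <- nrow(stream$samples); sid <- stream$subject_id
  } else {
    n <- as.integer(stream); sid <- NA_character_
  }
  if (window_size > n) {
    warning(sprintf("window_size %d exceeds stream length %d; no windows",
                    window_size, n))
    return(data.frame(subject_id = character(), start_index = integer(),
                      window_size = integer(), stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, n - window_size, by = step)
  data.frame(subject_id = sid, start_index = as.integer(starts),
             window_size = as.integer(window_size), stringsAsFactors = FALSE)
}

# per-sample label vector for one subject (background where unannotated)
sample_labels <- function(n, labels) {
  lab <- rep(BACKGROUND, n)
  if (nrow(labels)) {
    for (i in seq_len(nrow(labels)))
      lab[(labels$start_index[i] + 1):labels$end_index[i]] <- labels$activity[i]
  }
  lab
}

#' Resolve window labels against bout annotations
#'
#' A window whose samples all carry one annotation gets that label. A
#' window spanning a transition is labelled as the activity covering its
#' final sample (the activity at the end of the bout boundary), so every
#' window maps to exactly one activity. Windows whose final sample is
#' background get the background sentinel; `spans_transition` flags
#' windows whose samples are not label-homogeneous.
#'
#' @param windows data.frame from [segment_stream()] (one subject).
#' @param labels label-interval data.frame for the same subject.
#' @param stream_length stream length in samples.
#' @return `windows` with `label` and `spans_transition` columns added.
#' @export
label_windows <- function(windows, labels, stream_length) {
  if (nrow(windows) == 0) {
    windows$label <- character(0); windows$spans_transition <- logical(0)
    return(windows)
  }
  if (any(windows$start_index + windows$window_size > stream_length))
    stop("window extends beyond stream")
  lab <- sample_labels(stream_length, labels)
  # cumulative count of label change points enables O(1) homogeneity checks
  chg <- cumsum(c(0L, lab[-1] != lab[-length(lab)]))
  last <- windows$start_index + windows$window_size   # 1-based index of final sample
  windows$label <- lab[last]
  windows$spans_transition <- chg[last] - chg[windows$start_index + 1L] > 0L
  windows
}

#' Segment and label a whole cohort at one or more window sizes
#'
#' Background-labelled windows are dropped (the classification task has no
#' null class); transition windows are kept, flagged.
#'
#' @param cohort list with `streams` and `labels` as from
#'   [generate_cohort()].
#' @param window_sizes integer vector (default [WINDOW_SIZES]).
#' @param step shift in samples (default 5).
#' @param keep_background keep background windows (default FALSE).
#' @return named list (one element per window size) of labelled window
#'   data.frames.
#' @export
segment_cohort <- function(cohort, window_sizes = WINDOW_SIZES, step = 5L,
                           keep_background = FALSE) {
  out <- list()
  for (w in window_sizes) {
    per_subj <- lapply(cohort$streams, function(s) {
      win <- segment_stream(s, w, step)
      lw <- label_windows(win, cohort$labels[cohort$labels$subject_id == s$subject_id, ,
                                             drop = FALSE],
                          nrow(s$samples))
      if (!keep_background) lw <- lw[lw$label != BACKGROUND, , drop = FALSE]
      lw
    })
    ww <- do.call(rbind, per_subj)
    rownames(ww) <- NULL
    out[[as.character(w)]] <- ww
  }
  out
}
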