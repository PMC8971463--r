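#' Activity template
#'
#' Describes one activity of the battery as a generative recipe: a set of
#' oscillation frequencies and amplitudes per channel group (accelerometer,
#' gyroscope), a bout-duration distribution, how often a subject repeats
#' the activity, and additive sensor noise. Playful activities are
#' repetitive whole-body sequences (several frequency components, long
#' bouts); everyday activities are single short actions.
#'
#' @param name activity identifier (snake_case).
#' @param activity_type `"playful"` or `"everyday"`.
#' @param base_frequencies list with numeric vectors `acc` and `gyr`,
#'   oscillation frequencies in Hz per channel group. All effective
#'   frequencies must stay strictly below the Nyquist frequency.
#' @param amplitudes list with numeric vectors `acc` and `gyr` (same
#'   lengths as `base_frequencies`), component amplitudes in sensor units.
#' @param bout_duration numeric length-2, mean and sd of bout duration in
#'   seconds; mean must be positive.
#' @param repeats_per_subject integer length-2 `(min, max)` repeats of the
#'   activity per subject, `min <= max`.
#' @param bouts_per_repeat integer length-2 `(min, max)` annotated bouts
#'   produced by one repeat (video coding splits e.g. one drawing session
#'   into many pencil-down bouts). Drives the bout-count imbalance.
#' @param noise_sd additive Gaussian sensor noise sd, sensor units.
#' @param tempo_factor multiplicative speed factor; two templates sharing
#'   `base_frequencies` but differing in `tempo_factor` form a confusable
#'   pair (near-identical actions executed at different speed).
#' @param p_present probability that a given subject contributes the
#'   activity at all (video/session data is not complete for every child;
#'   lowering this makes an activity rare cohort-wide).
#' @return an object of class `activity_template`.
#' @export
activity_template <- function(name, activity_type = c("playful", "everyday"),
                              base_frequencies, amplitudes,
                              bout_duration = c(3, 0.8),
                              repeats_per_subject = c(2L, 5L),
                              bouts_per_repeat = c(1L, 1L),
                              noise_sd = 0.1, tempo_factor = 1,
                              p_present = 1) {
  activity_type <- match.arg(activity_type)
  stopifnot(is.character(name), nzchar(name),
            is.list(base_frequencies), is.list(amplitudes),
            all(c("acc", "gyr") %in% names(base_frequencies)),
            all(c("acc", "gyr") %in% names(amplitudes)))
  if (bout_duration[1] <= 0) stop("bout_duration mean must be > 0")
  if (repeats_per_subject[1] > repeats_per_subject[2])
    stop("repeats_per_subject min must be <= max")
  if (any(unlist(amplitudes) < 0)) stop("amplitudes must be >= 0")
  if (any(unlist(base_frequencies) <= 0)) stop("frequencies must be > 0")
  if (tempo_factor <= 0) stop("tempo_factor must be > 0")
  if (p_present <= 0 || p_present > 1) stop("p_present must be in (0, 1]")
  structure(list(name = name, activity_type = activity_type,
                 base_frequencies = base_frequencies, amplitudes = amplitudes,
                 bout_duration = as.numeric(bout_duration),
                 repeats_per_subject = as.integer(repeats_per_subject),
                 bouts_per_repeat = as.integer(bouts_per_repeat),
                 noise_sd = noise_sd, tempo_factor = tempo_factor,
                 p_present = p_present),
            class = "activity_template")
}

#' @export
print.activity_template <- function(x, ...) {
  cat(sprintf("<activity_template> %s (%s): acc %s Hz, gyr %s Hz, bouts %.1f+-%.1fs\n",
              x$name, x$activity_type,
              paste(x$base_frequencies$acc, collapse = ","),
              paste(x$base_frequencies$gyr, collapse = ","),
              x$bout_duration[1], x$bout_duration[2]))
  invisible(x)
}

#' Subject execution profile
#'
#' Encodes inter-individual execution style: a per-channel multiplicative
#' gain, a tempo factor multiplying all oscillation frequencies, and a
#' phase offset. Strong between-subject variation in these factors is what
#' makes subject-independent cross-validation harder than window-level
#' (subject-dependent) cross-validation.
#'
#' @param subject_id identifier.
#' @param gain positive numeric vector, one gain per channel (recycled).
#' @param tempo positive scalar frequency multiplier.
#' @param phase_offset radians.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gain = 1, tempo = 1, phase_offset = 0) {
  if (any(gain <= 0)) stop("gain must be > 0")
  if (tempo <= 0) stop("tempo must be > 0")
  structure(list(subject_id = subject_id, gain = gain, tempo = tempo,
                 phase_offset = phase_offset), class = "subject_profile")
}

#' Fixed-rate multichannel IMU recording of one subject
#'
#' @param subject_id identifier.
#' @param samples numeric matrix, one row per sample, one column per channel.
#' @param sampling_rate sampling frequency in Hz (default 50).
#' @param channels ordered channel names; default 3-axis accelerometer plus
#'   3-axis gyroscope, the channels the analysis uses.
#' @return object of class `imu_stream`.
#' @export
imu_stream <- function(subject_id, samples, sampling_rate = 50,
                       channels = c("acc_x", "acc_y", "acc_z",
                                    "gyr_x", "gyr_y", "gyr_z")) {
  samples <- as.matrix(samples)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (ncol(samples) != length(channels)) stop("channel count mismatch")
  if (length(channels) < 6) stop("need at least 6 channels")
  if (anyNA(samples)) stop("stream has missing samples")
  colnames(samples) <- channels
  structure(list(subject_id = subject_id, sampling_rate = sampling_rate,
                 channels = channels, samples = samples),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %s: %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

# per-channel fixed axis weights / phase lags so the three axes of a group
# see the same oscillation projected differently
.axis_weight <- c(1, 0.75, 0.55, 1, 0.75, 0.55)
.axis_phase <- c(0, 2.1, 4.2, 0.7, 2.8, 4.9)

#' Synthesize one activity bout
#'
#' Sum of subject-modulated sinusoids at the template frequencies plus
#' additive Gaussian noise. Deterministic given the current RNG state.
#'
#' @param template [activity_template()].
#' @param profile [subject_profile()].
#' @param n_samples number of samples to generate (> 0).
#' @param sampling_rate Hz.
#' @return numeric matrix `n_samples x 6` in channel order
#'   acc_x..gyr_z.
#' @export
activity_signal <- function(template, profile, n_samples, sampling_rate = 50) {
  if (n_samples <= 0) stop("n_samples must be > 0")
  nyq <- sampling_rate / 2
  tt <- (seq_len(n_samples) - 1) / sampling_rate
  gain <- rep_len(profile$gain, 6)
  out <- matrix(0, n_samples, 6)
  for (ch in 1:6) {
    grp <- if (ch <= 3) "acc" else "gyr"
    f <- template$base_frequencies[[grp]]
    a <- template$amplitudes[[grp]]
    eff <- f * profile$tempo * template$tempo_factor
    if (any(eff >= nyq))
      stop(sprintf("effective frequency %.2f Hz >= Nyquist (%.2f Hz) for '%s'",
                   max(eff), nyq, template$name))
    sig <- 0
    for (j in seq_along(f)) {
      sig <- sig + a[j] * gain[ch] * .axis_weight[ch] *
        sin(2 * pi * eff[j] * tt + profile$phase_offset + .axis_phase[ch] + j)
    }
    out[, ch] <- sig
  }
  if (template$noise_sd > 0)
    out <- out + matrix(rnorm(n_samples * 6, 0, template$noise_sd), n_samples, 6)
  out
}

#' Default activity registry (40 activities)
#'
#' A synthetic stand-in for a 40-item child activity battery: 13 playful
#' repetitive sequences (multi-component oscillations, long bouts, many
#' coded bouts per repeat) and 27 everyday single actions (one dominant
#' frequency, short bouts). Two everyday templates (`pray`, `clapping`)
#' share their base frequencies and differ only in tempo, forming a
#' confusable pair. Frequencies and amplitudes are chosen to span the
#' gross-motor cadence range (0.6-6 Hz) well below the 25 Hz Nyquist limit
#' of a 50 Hz device.
#'
#' @return named list of [activity_template()] objects, length 40.
#' @export
batb_registry <- function() {
  playful <- c("hopscotch", "ball", "goliath", "drawing", "crab", "swimming",
               "spider", "seal", "building_blocks", "bear", "dwarf", "rabbit",
               "frog")
  everyday <- c("book", "nose", "light_on", "light_off", "door_handle", "peck",
                "glass_grabbing", "pudding_eat", "clapping", "drinking",
                "glass_lifting", "sock_on_same", "sock_on_other",
                "toothbrush_other", "hand_wash", "snack_eat", "knee_same",
                "knee_other", "shoe_on_same", "pray", "toothbrush_same",
                "glass_to_mouth", "shoe_off_other", "shoe_on_other",
                "sock_off_same", "sock_off_other", "shoe_off_same")
  reg <- list()
  for (i in seq_along(playful)) {
    f0 <- 0.6 + 0.42 * (i - 1)        # 0.6 .. 5.6 Hz fundamentals
    # repetitive sequences are coded bout-by-bout; fine-grained codings
    # (e.g. pencil strokes, block placements) yield thousands of bouts
    bpr <- if (playful[i] %in% c("drawing", "building_blocks")) c(8L, 25L)
           else c(2L, 8L)
    reg[[playful[i]]] <- activity_template(
      name = playful[i], activity_type = "playful",
      base_frequencies = list(acc = c(f0, 2 * f0), gyr = c(f0)),
      amplitudes = list(acc = c(1.2, 0.5), gyr = c(0.9)),
      bout_duration = c(2.5, 0.6),
      repeats_per_subject = c(2L, 5L),
      bouts_per_repeat = bpr,
      noise_sd = 0.15)
  }
  rare <- c("glass_to_mouth", "shoe_off_other", "sock_off_same",
            "sock_off_other", "shoe_off_same", "drinking", "glass_lifting")
  for (i in seq_along(everyday)) {
    f0 <- 0.8 + 0.17 * (i - 1)        # 0.8 .. 5.2 Hz
    reg[[everyday[i]]] <- activity_template(
      name = everyday[i], activity_type = "everyday",
      base_frequencies = list(acc = c(f0), gyr = c(0.6 * f0)),
      amplitudes = list(acc = c(0.6), gyr = c(0.4)),
      bout_duration = c(1.8, 0.5),
      repeats_per_subject = c(2L, 5L),
      bouts_per_repeat = c(1L, 2L),
      noise_sd = 0.15,
      p_present = if (everyday[i] %in% rare) 0.35 else 1)
  }
  # confusable pair: same base frequencies, different execution tempo
  f_pair <- list(acc = c(2.2), gyr = c(1.3))
  reg[["pray"]] <- activity_template("pray", "everyday", f_pair,
    amplitudes = list(acc = c(0.6), gyr = c(0.4)),
    bout_duration = c(1.8, 0.5), bouts_per_repeat = c(1L, 2L),
    noise_sd = 0.15, tempo_factor = 1)
  reg[["clapping"]] <- activity_template("clapping", "everyday", f_pair,
    amplitudes = list(acc = c(0.6), gyr = c(0.4)),
    bout_duration = c(1.8, 0.5), bouts_per_repeat = c(1L, 2L),
    noise_sd = 0.15, tempo_factor = 1.1)
  reg
}

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects (default 34).
#' @param activities named list of [activity_template()]s
#'   (default [batb_registry()], 40 activities).
#' @param sampling_rate Hz, default 50.
#' @param gap_range background gap between bouts, seconds `(min, max)`,
#'   drawn uniformly.
#' @param subject_sd list of between-subject variability parameters:
#'   `gain` (lognormal sd of per-channel gain), `tempo` (lognormal sd of
#'   the tempo factor). Phase offsets are uniform on `[0, 2*pi)`.
#' @param background_noise_sd sensor noise sd during gaps.
#' @param max_samples optional per-subject session capacity in samples;
#'   scheduling beyond it is an error.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 34, activities = batb_registry(),
                          sampling_rate = 50, gap_range = c(0.5, 2),
                          subject_sd = list(gain = 0.25, tempo = 0.1),
                          background_noise_sd = 0.1,
                          max_samples = Inf) {
  if (length(activities) < 1) stop("configuration error: empty activity registry")
  stopifnot(n_subjects >= 0, sampling_rate > 0)
  structure(list(n_subjects = n_subjects, activities = activities,
                 sampling_rate = sampling_rate, gap_range = gap_range,
                 subject_sd = subject_sd,
                 background_noise_sd = background_noise_sd,
                 max_samples = max_samples),
            class = "cohort_config")
}

# draw one subject's execution profile under the subject substream
draw_profile <- function(subject_id, sds) {
  subject_profile(subject_id,
                  gain = exp(rnorm(6, 0, sds$gain)),
                  tempo = exp(rnorm(1, 0, sds$tempo)),
                  phase_offset = runif(1, 0, 2 * pi))
}

#' Generate a labelled synthetic IMU cohort
#'
#' One continuous recording per subject: activity bouts separated by
#' background gaps, each bout annotated as a label interval (0-based,
#' half-open). The RNG is split hierarchically per subject from the root
#' seed, so adding subjects does not perturb earlier ones, and the same
#' `(config, seed)` reproduces the cohort exactly.
#'
#' @param config [cohort_config()].
#' @param seed integer root seed.
#' @return list with `streams` (list of [imu_stream()]) and `labels`
#'   (data.frame: `subject_id, activity, start_index, end_index, bout_id`),
#'   plus `profiles` (the drawn subject profiles).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$activities) < 1)
    stop("configuration error: empty activity registry")
  fs <- config$sampling_rate
  streams <- list()
  profiles <- list()
  labs <- vector("list", config$n_subjects)
  if (config$n_subjects == 0)
    return(list(streams = list(), labels = empty_labels(), profiles = list()))
  subject_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  for (si in seq_len(config$n_subjects)) {
    sid <- subject_ids[si]
    res <- with_seed(derive_seed(seed, "cohort", sid), {
      profile <- draw_profile(sid, config$subject_sd)
      # schedule: draw repeats and bout counts per activity, shuffle bouts
      sched <- list()
      for (tpl in config$activities) {
        if (tpl$p_present < 1 && runif(1) > tpl$p_present) next
        reps <- if (tpl$repeats_per_subject[1] == tpl$repeats_per_subject[2])
          tpl$repeats_per_subject[1]
        else sample(tpl$repeats_per_subject[1]:tpl$repeats_per_subject[2], 1)
        for (r in seq_len(reps)) {
          nb <- if (tpl$bouts_per_repeat[1] == tpl$bouts_per_repeat[2])
            tpl$bouts_per_repeat[1]
          else sample(tpl$bouts_per_repeat[1]:tpl$bouts_per_repeat[2], 1)
          for (b in seq_len(nb)) sched[[length(sched) + 1]] <- tpl
        }
      }
      sched <- sched[sample.int(length(sched))]
      # lay out gap, bout, gap, bout, ..., gap
      pieces <- list()
      rows <- list()
      pos <- 0L
      gap_samples <- function() {
        n <- max(1L, round(runif(1, config$gap_range[1], config$gap_range[2]) * fs))
        matrix(rnorm(n * 6, 0, config$background_noise_sd), n, 6)
      }
      g <- gap_samples(); pieces[[1]] <- g; pos <- pos + nrow(g)
      for (k in seq_along(sched)) {
        tpl <- sched[[k]]
        dur <- max(0.3, rnorm(1, tpl$bout_duration[1], tpl$bout_duration[2]))
        n <- max(5L, round(dur * fs))
        if (pos + n > config$max_samples)
          stop(sprintf("scheduling error: subject %s, activity '%s' exceeds session capacity (%d samples)",
                       sid, tpl$name, config$max_samples))
        pieces[[length(pieces) + 1]] <- activity_signal(tpl, profile, n, fs)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, activity = tpl$name,
          start_index = pos, end_index = pos + n,
          bout_id = sprintf("%s_b%04d", sid, k),
          stringsAsFactors = FALSE)
        pos <- pos + n
        g <- gap_samples(); pieces[[length(pieces) + 1]] <- g; pos <- pos + nrow(g)
      }
      list(stream = imu_stream(sid, do.call(rbind, pieces), fs),
           labels = do.call(rbind, rows), profile = profile)
    })
    streams[[sid]] <- res$stream
    profiles[[sid]] <- res$profile
    labs[[si]] <- res$labels
  }
  labels <- do.call(rbind, labs)
  rownames(labels) <- NULL
  validate_labels(labels, streams)
  list(streams = streams, labels = labels, profiles = profiles)
}

empty_labels <- function() {
  data.frame(subject_id = character(), activity = character(),
             start_index = integer(), end_index = integer(),
             bout_id = character(), stringsAsFactors = FALSE)
}

# invariants: indices in range, per-subject intervals non-overlapping
validate_labels <- function(labels, streams = NULL) {
  if (nrow(labels) == 0) return(invisible(labels))
  if (any(labels$start_index < 0) || any(labels$end_index <= labels$start_index))
    stop("label intervals must satisfy 0 <= start < end")
  for (sid in unique(labels$subject_id)) {
    li <- labels[labels$subject_id == sid, , drop = FALSE]
    li <- li[order(li$start_index), , drop = FALSE]
    if (nrow(li) > 1 && any(li$start_index[-1] < li$end_index[-nrow(li)]))
      stop(sprintf("overlapping label intervals for subject %s", sid))
    if (!is.null(streams)) {
      tmax <- nrow(streams[[sid]]$samples)
      if (any(li$end_index > tmax))
        stop(sprintf("label interval beyond stream end for subject %s", sid))
    }
  }
  invisible(labels)
}
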