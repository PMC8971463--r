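#' Write cohort streams as per-subject CSV files
#'
#' One file `<subject_id>.csv` per stream with header
#' `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`; `t` is the sample time in
#' seconds.
#'
#' @param streams list of [imu_stream()]s.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_streams <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(streams, function(s) {
    df <- data.frame(t = (seq_len(nrow(s$samples)) - 1) / s$sampling_rate,
                     s$samples, check.names = FALSE)
    p <- file.path(dir, paste0(s$subject_id, ".csv"))
    write.csv(df, p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read per-subject stream CSV files
#'
#' @param dir directory of `<subject_id>.csv` files written by
#'   [write_streams()].
#' @param sampling_rate Hz; if `NULL`, inferred from the `t` column.
#' @return named list of [imu_stream()]s.
#' @export
read_streams <- function(dir, sampling_rate = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no stream CSVs found in %s", dir))
  streams <- lapply(files, function(p) {
    df <- read_checked_csv(p, c("t", "acc_x", "acc_y", "acc_z",
                                "gyr_x", "gyr_y", "gyr_z"))
    fs <- sampling_rate
    if (is.null(fs)) {
      dt <- diff(df$t)
      if (length(dt) == 0 || any(dt <= 0)) stop(sprintf("%s: bad time column", p))
      fs <- 1 / median(dt)
    }
    imu_stream(sub("\\.csv$", "", basename(p)),
               as.matrix(df[, -1, drop = FALSE]), sampling_rate = round(fs, 6))
  })
  names(streams) <- vapply(streams, `[[`, "", "subject_id")
  streams
}

# strict CSV reader: header must match exactly, all non-id cells numeric;
# malformed rows are reported with their line number
read_checked_csv <- function(path, expected_header, character_cols = character(0)) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  if (!identical(names(df), expected_header))
    stop(sprintf("%s: header mismatch (expected %s, got %s)", path,
                 paste(expected_header, collapse = ","),
                 paste(names(df), collapse = ",")))
  num_cols <- setdiff(expected_header, character_cols)
  for (cn in num_cols) {
    v <- df[[cn]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) & !is.na(df[[cn]]) | is.na(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, cn, bad[1] + 1L))
    df[[cn]] <- v
  }
  df
}

#' Write / read label intervals
#'
#' CSV schema `subject_id,activity,start_index,end_index,bout_id`
#' (0-based, half-open). Reading validates the interval invariants
#' (ordered indices, per-subject non-overlap) and rejects violations.
#'
#' @param labels label-interval data.frame.
#' @param path CSV path.
#' @return `read_labels` returns the validated data.frame.
#' @export
write_labels <- function(labels, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "activity", "start_index",
                                 "end_index", "bout_id"),
                         character_cols = c("subject_id", "activity", "bout_id"))
  df$start_index <- as.integer(df$start_index)
  df$end_index <- as.integer(df$end_index)
  validate_labels(df)
  df
}

#' Write / read labelled windows
#'
#' CSV schema `subject_id,start_index,window_size,label,spans_transition`.
#'
#' @param windows labelled window data.frame.
#' @param path CSV path.
#' @export
write_windows <- function(windows, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "start_index", "window_size",
                                 "label", "spans_transition"),
                         character_cols = c("subject_id", "label",
                                            "spans_transition"))
  df$start_index <- as.integer(df$start_index)
  df$window_size <- as.integer(df$window_size)
  df$spans_transition <- as.logical(df$spans_transition)
  df
}

#' Write / read a feature set
#'
#' The matrix goes to `<path>` as CSV (one row per window, named feature
#' columns, prefixed by the window-provenance columns); a JSON sidecar
#' `<path>.meta.json` records feature order, window size, sampling rate
#' and band definitions.
#'
#' @param fs a `feature_set`.
#' @param path CSV path.
#' @export
write_feature_set <- function(fs, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  df <- cbind(fs$windows, as.data.frame(fs$X, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  meta <- list(feature_names = fs$names, window_size = fs$window_size,
               sampling_rate = fs$sampling_rate, bands = fs$bands)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  wcols <- c("subject_id", "start_index", "window_size", "label",
             "spans_transition")
  if (!all(wcols %in% names(df)) || !all(meta$feature_names %in% names(df)))
    stop(sprintf("%s: feature CSV does not match its sidecar metadata", path))
  windows <- df[, wcols]
  windows$spans_transition <- as.logical(windows$spans_transition)
  X <- as.matrix(df[, meta$feature_names, drop = FALSE])
  bands <- meta$bands
  if (is.matrix(bands)) bands <- lapply(seq_len(nrow(bands)), function(i) bands[i, ])
  structure(list(X = X, windows = windows, names = meta$feature_names,
                 window_size = meta$window_size,
                 sampling_rate = meta$sampling_rate, bands = bands),
            class = "feature_set")
}

#' Read a pipeline configuration file
#'
#' YAML with an `activities:` registry (either the string `default` for
#' the built-in 40-activity battery, or a list of template specs) and a
#' `cohort:` block; optional `windows`, `evaluation`, `features` blocks
#' override the experimental-grid defaults (window sizes
#' 15,32,60,81,100,149; step 5; 3 folds; 20 iterations).
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing config file: %s", path))
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' Build a pipeline configuration
#'
#' @param raw nested list as parsed from YAML (or built in code); see
#'   [read_pipeline_config()].
#' @return object of class `pipeline_config`.
#' @export
as_pipeline_config <- function(raw = list()) {
  acts <- raw$activities
  if (is.null(acts) || identical(acts, "default")) {
    activities <- batb_registry()
  } else {
    activities <- lapply(acts, function(a)
      activity_template(
        name = a$name,
        activity_type = if (is.null(a$activity_type)) "everyday" else a$activity_type,
        base_frequencies = lapply(a$base_frequencies, as.numeric),
        amplitudes = lapply(a$amplitudes, as.numeric),
        bout_duration = if (is.null(a$bout_duration)) c(3, 0.8)
                        else as.numeric(a$bout_duration),
        repeats_per_subject = if (is.null(a$repeats_per_subject)) c(2L, 5L)
                              else as.integer(a$repeats_per_subject),
        bouts_per_repeat = if (is.null(a$bouts_per_repeat)) c(1L, 1L)
                           else as.integer(a$bouts_per_repeat),
        noise_sd = if (is.null(a$noise_sd)) 0.1 else a$noise_sd,
        tempo_factor = if (is.null(a$tempo_factor)) 1 else a$tempo_factor,
        p_present = if (is.null(a$p_present)) 1 else a$p_present))
    names(activities) <- vapply(activities, `[[`, "", "name")
  }
  co <- raw$cohort
  cohort <- cohort_config(
    n_subjects = if (is.null(co$n_subjects)) 34 else co$n_subjects,
    activities = activities,
    sampling_rate = if (is.null(co$sampling_rate)) 50 else co$sampling_rate,
    gap_range = if (is.null(co$gap_range)) c(0.5, 2) else as.numeric(co$gap_range),
    subject_sd = if (is.null(co$subject_sd)) list(gain = 0.25, tempo = 0.1)
                 else co$subject_sd,
    background_noise_sd = if (is.null(co$background_noise_sd)) 0.1
                          else co$background_noise_sd)
  wi <- raw$windows
  ev <- raw$evaluation
  fe <- raw$features
  structure(list(
    cohort = cohort,
    window_sizes = if (is.null(wi$sizes)) WINDOW_SIZES else as.integer(wi$sizes),
    step = if (is.null(wi$step)) 5L else as.integer(wi$step),
    folds = if (is.null(ev$folds)) 3L else as.integer(ev$folds),
    iterations = if (is.null(ev$iterations)) 20L else as.integer(ev$iterations),
    model = if (is.null(ev$model)) list() else ev$model,
    bands = if (is.null(fe$bands)) DEFAULT_BANDS
            else lapply(fe$bands, as.numeric),
    seed = raw$seed,
    out = raw$out), class = "pipeline_config")
}
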