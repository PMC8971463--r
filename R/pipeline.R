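#' Run the full pipeline: simulate, segment, featurize, evaluate, analyze
#'
#' Executes every stage in order under one root seed (substreams per
#' stage), writes all intermediate CSVs under the output directory and
#' returns a manifest recording the configuration digest, seed, per-file
#' checksums and package version. Re-running with the same configuration
#' and seed reproduces every output byte-identically.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()] /
#'   [as_pipeline_config()]).
#' @param seed integer root seed (overrides `config$seed`).
#' @param out output directory (overrides `config$out`).
#' @return the manifest (list), invisibly written to
#'   `<out>/manifest.json`.
#' @export
run_pipeline <- function(config, seed = config$seed, out = config$out) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) stop("a seed is mandatory for the pipeline")
  if (is.null(out)) stop("an output directory is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  log_msg("INFO", "simulate", "generating cohort (%d subjects, %d activities)",
          config$cohort$n_subjects, length(config$cohort$activities))
  cohort <- generate_cohort(config$cohort, seed)
  write_streams(cohort$streams, file.path(out, "streams"))
  write_labels(cohort$labels, file.path(out, "labels.csv"))

  log_msg("INFO", "segment", "window sizes %s, step %d",
          paste(config$window_sizes, collapse = ","), config$step)
  windows <- segment_cohort(cohort, config$window_sizes, config$step)
  for (wname in names(windows))
    write_windows(windows[[wname]], file.path(out, sprintf("windows_w%s.csv", wname)))

  log_msg("INFO", "featurize", "extracting %d-signal feature vectors",
          length(feature_signal_names))
  features <- lapply(windows, function(ww) featurize_windows(cohort, ww,
                                                             config$bands))
  for (wname in names(features))
    write_feature_set(features[[wname]],
                      file.path(out, sprintf("features_w%s.csv", wname)))

  log_msg("INFO", "evaluate", "%d folds x %d iterations", config$folds,
          config$iterations)
  types <- vapply(config$cohort$activities, `[[`, "", "activity_type")
  names(types) <- names(config$cohort$activities)
  params <- do.call(gbt_params, config$model)
  res <- run_experiment(features, cohort$labels, activity_types = types,
                        k = config$folds, iterations = config$iterations,
                        seed = seed, backend = gbt_backend("gbt", params))
  write.csv(res$runs, file.path(out, "runs.csv"), row.names = FALSE)
  write.csv(res$summary, file.path(out, "summary.csv"), row.names = FALSE)

  log_msg("INFO", "analyze", "quadratic window-size response per activity")
  if (length(unique(res$runs$window_size)) >= 3) {
    rel <- classify_relevance(fit_window_response(res$runs))
    write.csv(rel$report, file.path(out, "window_fits.csv"), row.names = FALSE)
  } else {
    log_msg("WARN", "analyze",
            "fewer than 3 window sizes; quadratic response not identifiable")
    write.csv(data.frame(activity = character(), b0 = numeric(),
                         b1 = numeric(), b2 = numeric(), r2 = numeric(),
                         adj_r2 = numeric(), effect_size = numeric(),
                         local_max_window = numeric(), relevant = logical()),
              file.path(out, "window_fits.csv"), row.names = FALSE)
  }

  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = "wristhar",
    version = as.character(utils::packageVersion("wristhar")),
    seed = seed,
    config_digest = unname(tools::md5sum(write_config_tmp(config))),
    n_subjects = config$cohort$n_subjects,
    n_activities = length(config$cohort$activities),
    window_sizes = config$window_sizes,
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# serialize the config deterministically for digesting; the output
# location is run plumbing, not part of the experiment identity
write_config_tmp <- function(config) {
  p <- tempfile(fileext = ".json")
  cfg <- config
  cfg$out <- NULL
  cfg$cohort$activities <- lapply(cfg$cohort$activities, unclass)
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  p
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  cat("usage: wristhar <simulate|segment|featurize|evaluate|analyze|all> [options]\n",
      "  common options: --config FILE --seed INT --out DIR\n",
      "  segment:   --streams DIR --labels FILE --window-sizes 15,32,... --step 5\n",
      "  featurize: --windows FILE --streams DIR --out FILE\n",
      "  evaluate:  --features DIR --folds 3 --iterations 20\n",
      "  analyze:   --runs FILE --range 15:149 --threshold 0.05\n", sep = "")
}

cli_opts <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument: %s", a))
    key <- sub("^--", "", a)
    if (i == length(args)) stop(sprintf("missing value for --%s", key))
    out[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (cohort to CSVs), `segment`, `featurize`,
#' `evaluate`, `analyze`, and `all` (the full pipeline). Invoked by the
#' `inst/cli/wristhar` script; callable directly with an argument vector
#' for testing.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status 0 invisibly (errors propagate).
#' @export
har_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1]
  opt <- cli_opts(args[-1])
  seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else NULL
  config <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
            else as_pipeline_config()
  switch(cmd,
    simulate = {
      if (is.null(seed)) stop("simulate requires --seed")
      if (is.null(opt$out)) stop("simulate requires --out")
      cohort <- generate_cohort(config$cohort, seed)
      write_streams(cohort$streams, file.path(opt$out, "streams"))
      write_labels(cohort$labels, file.path(opt$out, "labels.csv"))
    },
    segment = {
      streams <- read_streams(opt$streams)
      labels <- read_labels(opt$labels)
      sizes <- if (!is.null(opt$window_sizes))
        as.integer(strsplit(opt$window_sizes, ",")[[1]]) else config$window_sizes
      step <- if (!is.null(opt$step)) as.integer(opt$step) else config$step
      ww <- segment_cohort(list(streams = streams, labels = labels), sizes, step)
      for (wname in names(ww))
        write_windows(ww[[wname]],
                      file.path(opt$out, sprintf("windows_w%s.csv", wname)))
    },
    featurize = {
      streams <- read_streams(opt$streams)
      ww <- read_windows(opt$windows)
      fs <- featurize_windows(list(streams = streams), ww, config$bands)
      write_feature_set(fs, opt$out)
    },
    evaluate = {
      if (is.null(seed)) stop("evaluate requires --seed")
      paths <- list.files(opt$features, pattern = "^features_w[0-9]+\\.csv$",
                          full.names = TRUE)
      if (length(paths) == 0) stop(sprintf("no feature CSVs in %s", opt$features))
      feats <- lapply(paths, read_feature_set)
      names(feats) <- vapply(feats, function(f) as.character(f$window_size), "")
      labels <- read_labels(file.path(opt$features, "labels.csv"))
      k <- if (!is.null(opt$folds)) as.integer(opt$folds) else config$folds
      iters <- if (!is.null(opt$iterations)) as.integer(opt$iterations)
               else config$iterations
      res <- run_experiment(feats, labels, k = k, iterations = iters, seed = seed)
      write.csv(res$runs, file.path(opt$out, "runs.csv"), row.names = FALSE)
      write.csv(res$summary, file.path(opt$out, "summary.csv"), row.names = FALSE)
    },
    analyze = {
      runs <- read.csv(opt$runs, stringsAsFactors = FALSE)
      rng <- if (!is.null(opt$range))
        as.numeric(strsplit(opt$range, ":")[[1]]) else WINDOW_RANGE
      thr <- if (!is.null(opt$threshold)) as.numeric(opt$threshold)
             else EFFECT_THRESHOLD
      rel <- classify_relevance(fit_window_response(runs, range = rng,
                                                    threshold = thr),
                                threshold = thr)
      out <- if (!is.null(opt$out)) file.path(opt$out, "window_fits.csv")
             else stdout()
      write.csv(rel$report, out, row.names = FALSE)
    },
    all = {
      run_pipeline(config, seed = seed, out = opt$out)
    },
    { cli_usage(); stop(sprintf("unknown subcommand: %s", cmd)) })
  invisible(0L)
}
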