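#' Window-size range explored by the experiment
#' @export
WINDOW_RANGE <- c(15, 149)

#' Relevance threshold for the window-size effect, in AUC units
#' @export
EFFECT_THRESHOLD <- 0.05

#' Quadratic regression of AUC on window size
#'
#' Ordinary least squares of run-level AUC on window size and its square
#' (raw sample units, uncentered). A quadratic response allows a local
#' maximum, so an optimal window size can be looked for. The effect size
#' is the achievable AUC change over the explored range (max minus min of
#' the fitted curve); the effect is flagged relevant when it reaches
#' [EFFECT_THRESHOLD].
#'
#' @param points data.frame with columns `window_size` and `auc`,
#'   run-level (fold x iteration) values; at least 3 distinct sizes.
#' @param activity optional activity identifier carried into the result.
#' @param range explored window-size range (default 15-149 samples).
#' @param threshold relevance threshold in AUC units (default 0.05).
#' @return object of class `window_size_fit`: coefficients `b0, b1, b2`,
#'   `r2`, `adjusted_r2`, `effect_size`, `local_max_window` (NA unless
#'   the fit is concave with an interior vertex), `relevant`, `n`.
#' @export
fit_quadratic <- function(points, activity = NA_character_,
                          range = WINDOW_RANGE, threshold = EFFECT_THRESHOLD) {
  stopifnot(all(c("window_size", "auc") %in% names(points)))
  w <- as.numeric(points$window_size)
  if (length(unique(w)) < 3)
    stop("need at least 3 distinct window sizes for a quadratic fit")
  fit <- lm(auc ~ w + I(w^2), data = data.frame(auc = points$auc, w = w))
  b <- unname(coef(fit))
  b[is.na(b)] <- 0
  n <- length(w)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$auc - mean(points$auc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  adj <- 1 - (1 - r2) * (n - 1) / (n - 3)
  es <- quad_effect_size(b, range)
  vertex <- if (b[3] != 0) -b[2] / (2 * b[3]) else NA_real_
  local_max <- if (!is.na(vertex) && b[3] < 0 && vertex >= range[1] &&
                   vertex <= range[2]) vertex else NA_real_
  structure(list(activity = activity, coefficients = c(b0 = b[1], b1 = b[2],
                                                       b2 = b[3]),
                 r2 = r2, adjusted_r2 = adj, effect_size = es,
                 local_max_window = local_max,
                 relevant = es >= threshold, n = n, lm = fit),
            class = "window_size_fit")
}

#' @export
print.window_size_fit <- function(x, ...) {
  cat(sprintf("<window_size_fit> %s: auc = %.4g %+.3g w %+.3g w^2 | adj.R2 %.3f, effect %.3f%s%s\n",
              ifelse(is.na(x$activity), "(unnamed)", x$activity),
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$adjusted_r2, x$effect_size,
              if (!is.na(x$local_max_window))
                sprintf(", local max @ w=%.1f", x$local_max_window) else "",
              if (x$relevant) " [RELEVANT]" else ""))
  invisible(x)
}

#' Achievable AUC change of a quadratic over a window-size range
#'
#' Closed form: a quadratic attains its extrema on a closed interval at
#' the endpoints or at the interior vertex, so the effect size is the
#' max minus min of the curve evaluated at those candidates.
#'
#' @param coefficients numeric length-3 `(b0, b1, b2)`, or a
#'   `window_size_fit`.
#' @param range closed interval `(lo, hi)` of window sizes.
#' @return effect size in AUC units (>= 0).
#' @export
quad_effect_size <- function(coefficients, range = WINDOW_RANGE) {
  if (inherits(coefficients, "window_size_fit"))
    coefficients <- coefficients$coefficients
  b <- unname(coefficients)
  cand <- range
  if (b[3] != 0) {
    v <- -b[2] / (2 * b[3])
    if (v > range[1] && v < range[2]) cand <- c(cand, v)
  }
  vals <- b[1] + b[2] * cand + b[3] * cand^2
  max(vals) - min(vals)
}

#' Fit the window-size response for every activity
#'
#' @param runs run-level results (see [run_experiment()]): columns
#'   `activity`, `window_size`, `auc`.
#' @param range,threshold see [fit_quadratic()].
#' @param aggregate fit on per-size mean AUCs instead of run-level points
#'   (default FALSE: run-level).
#' @return data.frame, one row per activity:
#'   `activity, b0, b1, b2, r2, adj_r2, effect_size, local_max_window,
#'   relevant`.
#' @export
fit_window_response <- function(runs, range = WINDOW_RANGE,
                                threshold = EFFECT_THRESHOLD,
                                aggregate = FALSE) {
  rows <- lapply(unique(runs$activity), function(a) {
    pts <- runs[runs$activity == a, c("window_size", "auc")]
    if (aggregate)
      pts <- stats::aggregate(auc ~ window_size, data = pts, FUN = mean)
    f <- fit_quadratic(pts, activity = a, range = range, threshold = threshold)
    data.frame(activity = a, b0 = f$coefficients[1], b1 = f$coefficients[2],
               b2 = f$coefficients[3], r2 = f$r2, adj_r2 = f$adjusted_r2,
               effect_size = f$effect_size,
               local_max_window = f$local_max_window,
               relevant = f$relevant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relevance report over fitted window-size responses
#'
#' Joint criterion as used in the analysis: an activity's window-size
#' effect is flagged when the achievable AUC change over the explored
#' range reaches the threshold; adjusted R-squared is reported alongside
#' as goodness of fit, so a reader can see whether both measures are
#' appreciable.
#'
#' @param fits data.frame from [fit_window_response()] (or list of
#'   `window_size_fit`s).
#' @param threshold relevance threshold (default 0.05).
#' @return list with `report` (data.frame sorted by effect size
#'   descending) and `relevant` (activity identifiers flagged).
#' @export
classify_relevance <- function(fits, threshold = EFFECT_THRESHOLD) {
  if (is.list(fits) && !is.data.frame(fits))
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(activity = f$activity, b0 = f$coefficients[1],
                 b1 = f$coefficients[2], b2 = f$coefficients[3], r2 = f$r2,
                 adj_r2 = f$adjusted_r2, effect_size = f$effect_size,
                 local_max_window = f$local_max_window,
                 relevant = f$relevant, stringsAsFactors = FALSE)))
  stopifnot(nrow(fits) >= 1)
  fits$relevant <- fits$effect_size >= threshold
  rep <- fits[order(-fits$effect_size), , drop = FALSE]
  rownames(rep) <- NULL
  list(report = rep, relevant = rep$activity[rep$relevant])
}
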