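#' Default frequency band for band-power features
#'
#' One band covering gross-motor cadence (0.5-5 Hz). Bands are
#' configuration, not ground truth; pass your own list to the extractors.
#' @export
DEFAULT_BANDS <- list(c(0.5, 5))

#' Time-domain features of one window signal
#'
#' Sample mean, median, variance, skewness, kurtosis and range. Skewness
#' and kurtosis are the standardized third and fourth central moments
#' (population moments); for a constant signal both are defined as 0 so
#' feature vectors stay finite.
#'
#' @param x numeric vector, length >= 2.
#' @return named numeric vector
#'   `(mean, median, variance, skewness, kurtosis, range)`.
#' @export
time_features <- function(x) {
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  c0 <- x - mu
  m2 <- mean(c0^2)
  c(mean = mu,
    median = median(x),
    variance = var(x),
    skewness = if (m2 > 0) mean(c0^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(c0^4) / m2^2 else 0,
    range = max(x) - min(x))
}

# One-sided periodogram of the mean-removed signal, scaled so the total
# power equals the population variance of x (Parseval). DC excluded;
# the Nyquist bin (even n) is not doubled.
periodogram <- function(x, sampling_rate) {
  n <- length(x)
  h <- n %/% 2
  xc <- x - mean(x)
  p <- abs(fft(xc))^2 / n^2
  j <- seq_len(h)
  mult <- rep(2, h)
  if (n %% 2 == 0) mult[h] <- 1
  list(freq = j * sampling_rate / n, power = mult * p[j + 1])
}

#' Frequency-domain features of one window signal
#'
#' Computed on the one-sided periodogram of the mean-removed window (no
#' taper; windows are short). Peak frequency/power exclude the DC bin.
#' Spectral entropy is the Shannon entropy (bits) of the periodogram
#' normalized to a probability mass; a signal that is constant after mean
#' removal returns peak power 0, peak frequency 0 and entropy 0.
#'
#' @param x numeric vector, length >= 4.
#' @param sampling_rate Hz.
#' @param bands list of `(lo, hi)` Hz pairs within `(0, Nyquist]`; power
#'   is summed over bins with `lo < f <= hi`.
#' @return named numeric vector: `peak_frequency`, `peak_power`, one
#'   `band_lo_hi` entry per band, `spectral_entropy`.
#' @export
freq_features <- function(x, sampling_rate = 50, bands = DEFAULT_BANDS) {
  stopifnot(length(x) >= 4)
  nyq <- sampling_rate / 2
  for (b in bands)
    if (b[1] < 0 || b[2] > nyq || b[1] >= b[2])
      stop("bands must lie within (0, Nyquist]")
  pg <- periodogram(x, sampling_rate)
  tot <- sum(pg$power)
  if (tot <= 0) {
    pk_f <- 0; pk_p <- 0; ent <- 0
    bp <- vapply(bands, function(b) 0, numeric(1))
  } else {
    i <- which.max(pg$power)
    pk_f <- pg$freq[i]; pk_p <- pg$power[i]
    bp <- vapply(bands, function(b) sum(pg$power[pg$freq > b[1] & pg$freq <= b[2]]),
                 numeric(1))
    q <- pg$power / tot
    q <- q[q > 0]
    ent <- -sum(q * log2(q))
  }
  names(bp) <- vapply(bands, function(b) sprintf("band_%g_%g", b[1], b[2]), "")
  c(peak_frequency = pk_f, peak_power = pk_p, bp, spectral_entropy = ent)
}

feature_stat_names <- function(bands = DEFAULT_BANDS) {
  c("mean", "median", "variance", "skewness", "kurtosis", "range",
    "peak_frequency", "peak_power",
    vapply(bands, function(b) sprintf("band_%g_%g", b[1], b[2]), ""),
    "spectral_entropy")
}

feature_signal_names <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                          "acc_mag")

#' Feature vector of one window
#'
#' Concatenates [time_features()] and [freq_features()] over each of the
#' six sensor channels plus the acceleration Euclidean-norm signal: with
#' the default single band, 7 signals x 10 statistics = 70 features in a
#' fixed order.
#'
#' @param samples numeric matrix, window length x 6 channels
#'   (acc_x..gyr_z).
#' @param sampling_rate Hz.
#' @param bands see [freq_features()].
#' @return named numeric vector.
#' @export
extract_features <- function(samples, sampling_rate = 50, bands = DEFAULT_BANDS) {
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("non-finite samples in window")
  mag <- sqrt(rowSums(samples[, 1:3, drop = FALSE]^2))
  sigs <- cbind(samples, acc_mag = mag)
  out <- lapply(seq_len(ncol(sigs)), function(j)
    c(time_features(sigs[, j]), freq_features(sigs[, j], sampling_rate, bands)))
  v <- unlist(out, use.names = FALSE)
  names(v) <- as.vector(outer(feature_stat_names(bands), feature_signal_names,
                              function(s, g) paste(g, s, sep = ".")))
  v
}

# batched column statistics for a (window_length x n_windows) matrix
col_time_features <- function(M) {
  w <- nrow(M)
  mu <- colMeans(M)
  C <- M - rep(mu, each = w)
  m2 <- colMeans(C^2)
  m3 <- colMeans(C^3)
  m4 <- colMeans(C^4)
  rg <- apply(M, 2, function(x) {r <- range(x); r[2] - r[1]})
  rbind(mean = mu,
        median = apply(M, 2, median),
        variance = m2 * w / (w - 1),
        skewness = ifelse(m2 > 0, m3 / m2^1.5, 0),
        kurtosis = ifelse(m2 > 0, m4 / m2^2, 0),
        range = rg)
}

col_freq_features <- function(M, sampling_rate, bands) {
  w <- nrow(M); h <- w %/% 2
  C <- M - rep(colMeans(M), each = w)
  P <- abs(stats::mvfft(C))^2 / w^2
  mult <- rep(2, h); if (w %% 2 == 0) mult[h] <- 1
  Pb <- P[1 + seq_len(h), , drop = FALSE] * mult
  freq <- seq_len(h) * sampling_rate / w
  tot <- colSums(Pb)
  imax <- max.col(t(Pb), ties.method = "first")
  pk_f <- ifelse(tot > 0, freq[imax], 0)
  pk_p <- ifelse(tot > 0, Pb[cbind(imax, seq_along(imax))], 0)
  bp <- vapply(bands, function(b) colSums(Pb[freq > b[1] & freq <= b[2], ,
                                             drop = FALSE]),
               numeric(ncol(M)))
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = 1) else bp <- t(bp)
  Q <- Pb / rep(pmax(tot, .Machine$double.xmin), each = h)
  L <- ifelse(Q > 0, Q * log2(Q), 0)
  ent <- ifelse(tot > 0, -colSums(L), 0)
  out <- rbind(peak_frequency = pk_f, peak_power = pk_p, bp,
               spectral_entropy = ent)
  rownames(out) <- c("peak_frequency", "peak_power",
                     vapply(bands, function(b) sprintf("band_%g_%g", b[1], b[2]), ""),
                     "spectral_entropy")
  out
}

#' Featurize labelled windows of a cohort
#'
#' Computes the [extract_features()] vector for every window, batched per
#' subject and channel so the FFTs run as one matrix operation.
#'
#' @param cohort list with `streams` (from [generate_cohort()]).
#' @param windows labelled window data.frame (one window size; see
#'   [segment_cohort()]).
#' @param bands see [freq_features()].
#' @return object of class `feature_set`: list with `X` (numeric matrix,
#'   windows x features), `windows` (the input data.frame), `names`,
#'   `window_size`, `sampling_rate`, `bands`.
#' @export
featurize_windows <- function(cohort, windows, bands = DEFAULT_BANDS) {
  stopifnot(nrow(windows) > 0)
  w <- unique(windows$window_size)
  stopifnot(length(w) == 1)
  fs <- cohort$streams[[1]]$sampling_rate
  nstat <- length(feature_stat_names(bands))
  fnames <- as.vector(outer(feature_stat_names(bands), feature_signal_names,
                            function(s, g) paste(g, s, sep = ".")))
  X <- matrix(NA_real_, nrow(windows), nstat * length(feature_signal_names),
              dimnames = list(NULL, fnames))
  for (sid in unique(windows$subject_id)) {
    rows <- which(windows$subject_id == sid)
    S <- cohort$streams[[sid]]$samples
    if (any(!is.finite(S)))
      stop(sprintf("non-finite samples in stream of subject %s", sid))
    idx <- outer(seq_len(w), windows$start_index[rows], `+`)  # 1-based sample rows
    mag <- sqrt(rowSums(S[, 1:3, drop = FALSE]^2))
    for (g in seq_along(feature_signal_names)) {
      sig <- if (g <= 6) S[, g] else mag
      M <- matrix(sig[idx], nrow = w)
      F <- rbind(col_time_features(M), col_freq_features(M, fs, bands))
      X[rows, ((g - 1) * nstat + 1):(g * nstat)] <- t(F)
    }
  }
  structure(list(X = X, windows = windows, names = fnames,
                 window_size = w, sampling_rate = fs, bands = bands),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d windows x %d features (window %d samples @ %g Hz)\n",
              nrow(x$X), ncol(x$X), x$window_size, x$sampling_rate))
  invisible(x)
}
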