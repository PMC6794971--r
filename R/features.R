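# feature_engineering: minute-level peak features, subject-level accelerometer
# statistics, and assembly of the 28-column feature matrix

SAMPLES_PER_MINUTE <- 600L # 60 s at 10 Hz
SAMPLES_PER_SECOND <- 10L

#' Minute-wise peak features of a 10 Hz signal
#'
#' For each complete minute (600 samples; a trailing partial minute is
#' dropped) computes:
#' \describe{
#'   \item{peaks}{number of detected local maxima in the minute;}
#'   \item{average_amplitude}{mean signal value at those maxima;}
#'   \item{differ_mean}{mean absolute difference between consecutive peak
#'     amplitudes within the minute;}
#'   \item{resting}{(ECG only) mean number of peaks per non-overlapping
#'     1-second (10-sample) window of the minute.}
#' }
#' Minutes with no peaks report 0 for every feature, and `differ_mean` is 0
#' with fewer than two peaks, keeping the feature matrix dense.
#'
#' @param x Numeric 10 Hz series.
#' @param peaks Integer peak indices into `x` (e.g. from [detect_peaks()]).
#' @param signal_kind One of `"ecg"`, `"emg"`, `"resp"`, `"bvp"`; only ECG
#'   carries the `resting` column.
#' @return Data frame with one row per complete minute.
#' @export
minute_peak_features <- function(x, peaks, signal_kind = c("ecg", "emg", "resp", "bvp")) {
  signal_kind <- match.arg(signal_kind)
  n_min <- length(x) %/% SAMPLES_PER_MINUTE
  rows <- lapply(seq_len(n_min), function(m) {
    lo <- (m - 1L) * SAMPLES_PER_MINUTE
    p <- peaks[peaks > lo & peaks <= lo + SAMPLES_PER_MINUTE]
    amps <- x[p]
    out <- data.frame(
      peaks = length(p),
      average_amplitude = if (length(p)) mean(amps) else 0,
      differ_mean = if (length(p) >= 2L) mean(abs(diff(amps))) else 0
    )
    if (signal_kind == "ecg") {
      win <- (p - lo - 1L) %/% SAMPLES_PER_SECOND # 60 windows of 1 s
      out$resting <- mean(tabulate(win + 1L, nbins = 60L))
    }
    out
  })
  if (!n_min) {
    out <- data.frame(peaks = integer(0), average_amplitude = numeric(0), differ_mean = numeric(0))
    if (signal_kind == "ecg") out$resting <- numeric(0)
    return(out)
  }
  do.call(rbind, rows)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Crest factor of a signal
#'
#' Peak value over root-mean-square amplitude — a measure of impulsiveness.
#' The RMS uses the raw (uncentred) signal with an `N - 1` normalizer, so a
#' constant positive signal of length `N` has crest `sqrt((N - 1) / N)`.
#'
#' @param x Numeric vector of length >= 2.
#' @return `max(x) / sqrt(sum(x^2) / (length(x) - 1))`.
#' @export
crest_factor <- function(x) {
  stopifnot(length(x) >= 2)
  max(x) / sqrt(sum(x^2) / (length(x) - 1))
}

#' Subject-level statistical features of a triaxial accelerometer
#'
#' Fifteen numbers per subject, broadcast later to all of the subject's
#' samples: per axis the mean, population standard deviation, excess
#' kurtosis and crest factor; per axis pair the correlation.
#'
#' Two published-formula quirks are kept configurable:
#' \itemize{
#'   \item the correlation is the `1/(N-1)` mixed moment over population
#'     standard deviations (which can exceed 1 in magnitude and is clipped to
#'     `[-1, 1]`); `method = "pearson"` gives the standard coefficient;
#'   \item kurtosis defaults to the standard `E[(x - mean)^4] / sd^4 - 3`;
#'     `kurtosis = "printed"` divides by `sd^2` instead.
#' }
#' The crest factor is `max(x) / sqrt(sum(x^2) / (N - 1))` (root-mean-square
#' of the raw, uncentred signal with an `N - 1` normalizer).
#'
#' @param acc Numeric matrix with columns x, y, z and at least 2 rows.
#' @param method Correlation form: `"moment"` (clipped mixed moment, default)
#'   or `"pearson"`.
#' @param kurtosis Kurtosis denominator: `"sigma4"` (default) or `"printed"`.
#' @return Named numeric vector of the 15 ACCL features (see
#'   [channel_blocks()] for the order).
#' @export
subject_accel_features <- function(acc, method = c("moment", "pearson"),
                                   kurtosis = c("sigma4", "printed")) {
  method <- match.arg(method)
  kurtosis <- match.arg(kurtosis)
  acc <- as.matrix(acc)
  n <- nrow(acc)
  if (ncol(acc) != 3L || n < 2L) {
    stop_mindcnn("acc must be an N x 3 matrix with N >= 2", "mindcnn_domain_error")
  }
  axes <- c("X", "Y", "Z")
  sds <- apply(acc, 2L, pop_sd)
  if (any(sds == 0)) {
    stop_mindcnn(
      sprintf("zero-variance accelerometer axis: %s", paste(axes[sds == 0], collapse = ", ")),
      "mindcnn_domain_error"
    )
  }
  means <- colMeans(acc)
  kurt <- vapply(1:3, function(j) {
    m4 <- mean((acc[, j] - means[j])^4)
    denom <- if (kurtosis == "sigma4") sds[j]^4 else sds[j]^2
    m4 / denom - 3
  }, numeric(1))
  crest <- vapply(1:3, function(j) crest_factor(acc[, j]), numeric(1))
  pair_corr <- function(j, k) {
    if (method == "pearson") {
      return(stats::cor(acc[, j], acc[, k]))
    }
    r <- sum((acc[, j] - means[j]) * (acc[, k] - means[k])) / ((n - 1) * sds[j] * sds[k])
    min(1, max(-1, r))
  }
  out <- c(
    means, sds, kurt, crest,
    pair_corr(1, 2), pair_corr(1, 3), pair_corr(2, 3)
  )
  names(out) <- FEATURE_COLUMNS$ACCL
  out
}

# minute-local peak detection over a full series: threshold adapts per minute
detect_peaks_by_minute <- function(x, params) {
  n_min <- length(x) %/% SAMPLES_PER_MINUTE
  unlist(lapply(seq_len(n_min), function(m) {
    lo <- (m - 1L) * SAMPLES_PER_MINUTE
    detect_peaks(x[(lo + 1L):(lo + SAMPLES_PER_MINUTE)], params) + lo
  }), use.names = FALSE)
}

#' Assemble the 28-column feature dataset from processed recordings
#'
#' Takes recordings already converted to SI units and resampled to 10 Hz
#' (see [process_recording()]), runs minute-local peak detection on
#' ECG/EMG/respiration/BVP, computes the subject-level accelerometer
#' statistics from the wrist accelerometer, and broadcasts: minute features
#' to all 600 samples of their minute, accelerometer features to all samples
#' of their subject. Rows falling in a trailing partial minute or carrying
#' the unlabeled sentinel are removed. Recordings shorter than one minute
#' are excluded with a warning.
#'
#' @param sampled List of `sampled_recording` objects (or a single one).
#' @param params Named list of [peak_params()] per signal kind; defaults to
#'   [default_peak_params()] for each of ecg/emg/resp/bvp.
#' @param ... Passed to [subject_accel_features()].
#' @return A [feature_dataset()].
#' @export
assemble_feature_matrix <- function(sampled, params = NULL, ...) {
  if (inherits(sampled, "sampled_recording")) sampled <- list(sampled)
  kinds <- c("ecg", "emg", "resp", "bvp")
  if (is.null(params)) {
    params <- lapply(stats::setNames(kinds, kinds), default_peak_params)
  }
  stream_of <- c(ecg = "ecg", emg = "emg", resp = "resp", bvp = "bvp")
  parts <- list()
  for (rec in sampled) {
    n_min <- length(rec$labels) %/% SAMPLES_PER_MINUTE
    if (n_min < 1L) {
      warning(sprintf(
        "subject %s: recording shorter than one minute; excluded", rec$subject_id
      ))
      next
    }
    n_keep <- n_min * SAMPLES_PER_MINUTE
    blocks <- lapply(kinds, function(kind) {
      x <- rec$streams[[stream_of[[kind]]]][seq_len(n_keep)]
      pk <- detect_peaks_by_minute(x, params[[kind]])
      mf <- minute_peak_features(x, pk, kind)
      as.matrix(mf)[rep(seq_len(n_min), each = SAMPLES_PER_MINUTE), , drop = FALSE]
    })
    accl <- subject_accel_features(rec$streams$acc_wrist[seq_len(n_keep), , drop = FALSE], ...)
    blocks <- c(blocks, list(matrix(accl, n_keep, 15L, byrow = TRUE)))
    feats <- do.call(cbind, blocks)
    labels <- rec$labels[seq_len(n_keep)]
    keep <- labels >= 0L
    parts[[length(parts) + 1L]] <- list(
      features = feats[keep, , drop = FALSE],
      labels = labels[keep],
      subject = rep(rec$subject_id, sum(keep))
    )
  }
  if (!length(parts)) {
    stop_mindcnn("no recording contributed a complete minute of data", "mindcnn_domain_error")
  }
  feature_dataset(
    do.call(rbind, lapply(parts, `[[`, "features")),
    unlist(lapply(parts, `[[`, "labels")),
    unlist(lapply(parts, `[[`, "subject"))
  )
}

#' Convert and resample a raw recording in one call
#'
#' Convenience wrapper: [convert_recording()] then [resample_recording()].
#'
#' @param rec A [raw_recording()] with `units = "raw"`.
#' @param conv A [conversion_spec()].
#' @param plan A [resample_plan()].
#' @return A `sampled_recording` at 10 Hz.
#' @export
process_recording <- function(rec, conv = conversion_spec(), plan = resample_plan()) {
  resample_recording(convert_recording(rec, conv), plan)
}
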