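# feature_engineering: local-maxima peak detector with threshold + refractory distance

#' Peak detection parameters
#'
#' A sample is a candidate peak when it strictly exceeds its left neighbour,
#' is at least its right neighbour, and exceeds `mean(x) + threshold_k * sd(x)`
#' of the series it is detected on. Peaks closer than `min_distance` samples
#' are thinned by amplitude (larger kept; ties keep the earlier index).
#'
#' Defaults per signal kind (at 10 Hz) reflect physiological refractory
#' periods: ECG 3 samples (~0.3 s minimum RR interval), EMG 2, respiration 10
#' (~max 60 breaths/min), BVP 3.
#'
#' @param threshold_k Multiplier on the series standard deviation; default 1.
#' @param min_distance Minimum index separation between reported peaks (>= 1).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(threshold_k = 1, min_distance = 3L) {
  stopifnot(is.numeric(threshold_k), length(threshold_k) == 1L, is_count(min_distance))
  structure(
    list(threshold_k = threshold_k, min_distance = as.integer(min_distance)),
    class = "peak_params"
  )
}

#' Default peak parameters per signal kind
#'
#' @param kind One of `"ecg"`, `"emg"`, `"resp"`, `"bvp"`.
#' @return A [peak_params()].
#' @export
default_peak_params <- function(kind = c("ecg", "emg", "resp", "bvp")) {
  kind <- match.arg(kind)
  dist <- c(ecg = 3L, emg = 2L, resp = 10L, bvp = 3L)[[kind]]
  peak_params(threshold_k = 1, min_distance = dist)
}

#' Detect peaks in a 10 Hz signal
#'
#' @param x Numeric series.
#' @param params A [peak_params()].
#' @param threshold Optional explicit amplitude threshold; when `NULL` it is
#'   `mean(x) + threshold_k * sd(x)` of the given series (callers working
#'   minute-wise pass each minute separately so the threshold adapts).
#' @return Increasing integer vector of peak indices; may be empty. Every
#'   returned index `i` satisfies `x[i] > x[i-1]`, `x[i] >= x[i+1]` and
#'   `x[i] > threshold`, and consecutive returned indices differ by at least
#'   `min_distance`.
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0, 3, 0), peak_params(threshold_k = 0))
#' @export
detect_peaks <- function(x, params = peak_params(), threshold = NULL) {
  n <- length(x)
  if (n < 3L) {
    return(integer(0))
  }
  if (is.null(threshold)) {
    threshold <- mean(x) + params$threshold_k * stats::sd(x)
  }
  mid <- 2:(n - 1L)
  cand <- mid[x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L] & x[mid] > threshold]
  if (length(cand) <= 1L) {
    return(cand)
  }
  # greedy thinning: highest amplitude first, earlier index wins ties
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(length(ord))
  kept_idx <- integer(0)
  for (j in seq_along(ord)) {
    i <- ord[j]
    if (!length(kept_idx) || all(abs(kept_idx - i) >= params$min_distance)) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  sort(ord[keep])
}
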