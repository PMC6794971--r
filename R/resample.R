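# resampling: harmonize all streams to 700 Hz, then block-aggregate to 10 Hz

#' Resampling plan
#'
#' All streams are first brought to a common 700 Hz grid (the chest unit's
#' native rate), then reduced to 10 Hz by aggregating non-overlapping blocks
#' of 70 samples: signals by mean (or median), labels by mode.
#'
#' @param common_hz Common intermediate rate; 700.
#' @param target_hz Final rate; 10. `common_hz` must be a multiple.
#' @param signal_agg Block aggregator for signals: `"mean"` or `"median"`.
#' @param upsample_method `"linear"` interpolation (default, for continuous
#'   signals) or `"hold"` (repeat the most recent sample).
#' @return An object of class `resample_plan` with the derived `block` size.
#' @export
resample_plan <- function(common_hz = 700, target_hz = 10,
                          signal_agg = c("mean", "median"),
                          upsample_method = c("linear", "hold")) {
  signal_agg <- match.arg(signal_agg)
  upsample_method <- match.arg(upsample_method)
  stopifnot(common_hz > 0, target_hz > 0, common_hz %% target_hz == 0)
  structure(
    list(
      common_hz = common_hz, target_hz = target_hz,
      block = common_hz %/% target_hz,
      signal_agg = signal_agg, upsample_method = upsample_method
    ),
    class = "resample_plan"
  )
}

#' Upsample a stream to the common rate
#'
#' Samples are mapped onto the common time grid by their index over the
#' native rate. Output length is `round(n * common_hz / native_hz)`. With
#' `"linear"`, original samples are passed through exactly at their mapped
#' positions and the grid is extended by holding the last value; this also
#' covers non-integer rate ratios such as 32 Hz -> 700 Hz. With `"hold"`,
#' each output sample repeats the most recent native sample.
#'
#' @param x Numeric vector or matrix (columns upsampled independently).
#' @param native_hz Positive native sampling rate.
#' @param plan A [resample_plan()].
#' @return Series at `plan$common_hz`.
#' @export
upsample <- function(x, native_hz, plan = resample_plan()) {
  if (!is.numeric(native_hz) || length(native_hz) != 1L || native_hz <= 0) {
    stop_mindcnn("native_hz must be a positive number", "mindcnn_domain_error")
  }
  if (is.matrix(x)) {
    return(apply(x, 2L, upsample, native_hz = native_hz, plan = plan))
  }
  if (native_hz == plan$common_hz) {
    return(x)
  }
  n <- length(x)
  n_out <- round_half_up(n * plan$common_hz / native_hz)
  if (n == 0L || n_out == 0L) {
    return(numeric(0))
  }
  t_out <- (seq_len(n_out) - 1) / plan$common_hz
  if (n == 1L) {
    return(rep(x, n_out))
  }
  if (plan$upsample_method == "linear") {
    stats::approx(
      x = (seq_len(n) - 1) / native_hz, y = x, xout = t_out,
      method = "linear", rule = 2
    )$y
  } else {
    idx <- pmin(floor(t_out * native_hz) + 1L, n)
    x[idx]
  }
}

#' Downsample a 700 Hz signal to 10 Hz by block aggregation
#'
#' Output element `i` aggregates samples `[block*(i-1) + 1, block*i]` with the
#' plan's aggregator; a trailing partial block is dropped (never padded).
#'
#' @param x Numeric vector or matrix at the common rate.
#' @param plan A [resample_plan()].
#' @return Series of length `floor(n / block)` at the target rate.
#' @export
downsample_signal <- function(x, plan = resample_plan()) {
  if (is.matrix(x)) {
    return(apply(x, 2L, downsample_signal, plan = plan))
  }
  b <- plan$block
  m <- length(x) %/% b
  if (m == 0L) {
    warning("series shorter than one aggregation block; empty output")
    return(numeric(0))
  }
  blocks <- matrix(x[seq_len(b * m)], nrow = b, ncol = m)
  if (plan$signal_agg == "mean") colMeans(blocks) else apply(blocks, 2L, stats::median)
}

#' Downsample a 700 Hz label stream to 10 Hz by block mode
#'
#' Each 70-sample block emits its most frequent valid label; ties break to the
#' lowest class index (deterministic). The sentinel `-1` is ignored unless a
#' block is entirely unlabeled, in which case it emits `-1`.
#'
#' @param labels Integer labels in `-1:4` at the common rate.
#' @param plan A [resample_plan()].
#' @return Integer labels at the target rate.
#' @export
downsample_labels <- function(labels, plan = resample_plan()) {
  b <- plan$block
  m <- length(labels) %/% b
  if (m == 0L) {
    warning("label stream shorter than one aggregation block; empty output")
    return(integer(0))
  }
  blocks <- matrix(as.integer(labels[seq_len(b * m)]), nrow = b, ncol = m)
  vapply(seq_len(m), function(i) {
    counts <- tabulate(blocks[, i] + 1L, nbins = 5L) # valid classes 0..4 only
    if (all(counts == 0L)) -1L else which.max(counts) - 1L
  }, integer(1))
}

#' Run the full resampling pass over an SI recording
#'
#' Upsamples every sub-700 Hz stream to the common grid, block-aggregates
#' signals and labels to 10 Hz, and truncates all outputs to a common length
#' (partial trailing blocks dropped).
#'
#' @param rec A [raw_recording()] in SI units (see [convert_recording()]).
#' @param plan A [resample_plan()].
#' @return An object of class `sampled_recording`: `subject_id`, `hz`,
#'   named 10 Hz `streams`, and 10 Hz `labels`.
#' @export
resample_recording <- function(rec, plan = resample_plan()) {
  streams <- lapply(rec$streams, function(s) {
    at_common <- upsample(s$values, s$rate_hz, plan)
    downsample_signal(at_common, plan)
  })
  labels <- downsample_labels(rec$labels, plan)
  n <- min(c(length(labels), vapply(streams, NROW, integer(1))))
  streams <- lapply(streams, function(v) if (is.matrix(v)) v[seq_len(n), , drop = FALSE] else v[seq_len(n)])
  structure(
    list(
      subject_id = rec$subject_id, hz = plan$target_hz,
      streams = streams, labels = labels[seq_len(n)]
    ),
    class = "sampled_recording"
  )
}

#' @export
print.sampled_recording <- function(x, ...) {
  cat(sprintf(
    "<sampled_recording> subject %s, %d samples at %g Hz (%d streams)\n",
    x$subject_id, length(x$labels), x$hz, length(x$streams)
  ))
  invisible(x)
}
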