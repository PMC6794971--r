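# signal_io: neutral data model for multimodal recordings + CSV-bundle reader/writer

COMMON_HZ <- 700
ADC_MAX <- 2^16

# streams that must be present for the modelling pipeline
MANDATORY_STREAMS <- c("ecg", "emg", "resp", "bvp", "acc_wrist")
OPTIONAL_STREAMS <- c("acc_chest", "eda_chest", "temp_chest", "eda_wrist", "temp_wrist")
CHEST_STREAMS <- c("ecg", "emg", "resp", "acc_chest", "eda_chest", "temp_chest")
TRIAXIAL_STREAMS <- c("acc_chest", "acc_wrist")

#' Construct a multimodal raw recording
#'
#' A `raw_recording` bundles one subject's sensor streams at their native
#' sampling rates with a 700 Hz label stream. Chest-unit streams (ECG, EMG,
#' respiration, and optionally accelerometer, EDA, temperature) are sampled at
#' 700 Hz and, in `units = "raw"`, hold non-negative 16-bit ADC integers.
#' Wrist-unit streams run at their native rates (BVP 64 Hz, accelerometer
#' 32 Hz, EDA/temperature 4 Hz). Time is implicit: sample index over rate,
#' with all streams sharing the recording start.
#'
#' @param subject_id Single string identifying the subject.
#' @param streams Named list; each element is a list with fields `rate_hz`
#'   (positive number) and `values` (numeric vector, or a 3-column matrix for
#'   triaxial accelerometers). Recognized names: `ecg`, `emg`, `resp`,
#'   `acc_chest`, `eda_chest`, `temp_chest`, `bvp`, `acc_wrist`, `eda_wrist`,
#'   `temp_wrist`.
#' @param labels Integer vector at 700 Hz with values in `-1:4`; `-1` marks
#'   unlabeled spans (see [class_levels()]).
#' @param units Either `"raw"` (ADC counts on chest streams, 1/64 g on the
#'   wrist accelerometer) or `"si"` (after [convert_recording()]).
#' @return An object of class `raw_recording`.
#' @seealso [read_recording()], [write_recording()], [generate_subject()]
#' @export
raw_recording <- function(subject_id, streams, labels, units = c("raw", "si")) {
  units <- match.arg(units)
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      streams = streams,
      labels = as.integer(labels),
      units = units
    ),
    class = "raw_recording"
  )
  validate_recording(rec)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> subject %s, %.1f s, units=%s\n",
    x$subject_id, length(x$labels) / COMMON_HZ, x$units
  ))
  for (nm in names(x$streams)) {
    s <- x$streams[[nm]]
    n <- if (is.matrix(s$values)) nrow(s$values) else length(s$values)
    ax <- if (is.matrix(s$values)) sprintf(" x%d axes", ncol(s$values)) else ""
    cat(sprintf("  %-10s %6g Hz, %d samples%s\n", nm, s$rate_hz, n, ax))
  }
  cat(sprintf(
    "  labels     %6d Hz, %d samples (%d unlabeled)\n",
    COMMON_HZ, length(x$labels), sum(x$labels < 0)
  ))
  invisible(x)
}

stream_length <- function(s) if (is.matrix(s$values)) nrow(s$values) else length(s$values)

validate_recording <- function(rec) {
  if (!length(rec$streams) || is.null(names(rec$streams))) {
    stop_mindcnn("recording has no named streams", "mindcnn_format_error")
  }
  missing <- setdiff(MANDATORY_STREAMS, names(rec$streams))
  if (length(missing)) {
    stop_mindcnn(
      sprintf("missing mandatory stream(s): %s", paste(missing, collapse = ", ")),
      "mindcnn_format_error"
    )
  }
  duration_s <- length(rec$labels) / COMMON_HZ
  for (nm in names(rec$streams)) {
    s <- rec$streams[[nm]]
    if (!is.numeric(s$rate_hz) || length(s$rate_hz) != 1L || s$rate_hz <= 0) {
      stop_mindcnn(sprintf("stream '%s' has invalid sampling rate", nm), "mindcnn_format_error")
    }
    n <- stream_length(s)
    expected <- round(duration_s * s$rate_hz)
    if (abs(n - expected) > 1) {
      stop_mindcnn(
        sprintf(
          "stream '%s' length %d inconsistent with labels (expected %d at %g Hz)",
          nm, n, expected, s$rate_hz
        ),
        "mindcnn_consistency_error"
      )
    }
    if (nm %in% TRIAXIAL_STREAMS && (!is.matrix(s$values) || ncol(s$values) != 3L)) {
      stop_mindcnn(sprintf("stream '%s' must carry three aligned axes", nm), "mindcnn_format_error")
    }
    if (rec$units == "raw" && nm %in% CHEST_STREAMS) {
      v <- s$values
      if (anyNA(v) || any(v < 0) || any(v >= ADC_MAX) || any(v != floor(v))) {
        stop_mindcnn(
          sprintf("raw chest stream '%s' must hold integers in [0, 2^16)", nm),
          "mindcnn_consistency_error"
        )
      }
    }
  }
  if (anyNA(rec$labels) || any(rec$labels < -1L) || any(rec$labels > 4L)) {
    stop_mindcnn("labels must lie in {-1, 0, ..., 4}", "mindcnn_consistency_error")
  }
  invisible(rec)
}

#' Write a recording as a CSV bundle
#'
#' The on-disk container is a directory holding one CSV per stream, a
#' `labels.csv`, and a `manifest.json` naming each file with its sampling
#' rate. Doubles are serialized at 17 significant digits so a write/read
#' round trip reproduces values exactly.
#'
#' @param rec A [raw_recording()].
#' @param path Directory to create (or reuse).
#' @param format Only `"csv_bundle"` is supported.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = "csv_bundle") {
  if (!identical(format, "csv_bundle")) {
    stop_mindcnn(sprintf("unsupported recording format '%s'", format), "mindcnn_format_error")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    subject_id = rec$subject_id,
    units = rec$units,
    labels = list(file = "labels.csv", rate_hz = COMMON_HZ, n = length(rec$labels)),
    streams = list()
  )
  for (nm in names(rec$streams)) {
    s <- rec$streams[[nm]]
    file <- paste0(nm, ".csv")
    df <- if (is.matrix(s$values)) {
      as.data.frame(s$values) |> stats::setNames(c("x", "y", "z"))
    } else {
      data.frame(value = s$values)
    }
    write_csv_precise(df, file.path(path, file))
    manifest$streams[[nm]] <- list(
      file = file, rate_hz = s$rate_hz, n = stream_length(s),
      columns = ncol(df)
    )
  }
  writeLines(as.character(rec$labels), file.path(path, "labels.csv"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a recording from a CSV bundle
#'
#' @param path Directory written by [write_recording()].
#' @param format Only `"csv_bundle"` is supported; `"hdf5"` raises an error.
#' @return A validated [raw_recording()]. Missing optional streams (EDA,
#'   temperature, chest accelerometer) are permitted and reported via a
#'   message; missing mandatory streams raise a format error naming the
#'   stream, and length/rate mismatches raise a consistency error.
#' @export
read_recording <- function(path, format = "csv_bundle") {
  if (!identical(format, "csv_bundle")) {
    stop_mindcnn(sprintf("unsupported recording format '%s'", format), "mindcnn_format_error")
  }
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_mindcnn(sprintf("no manifest.json under '%s'", path), "mindcnn_format_error")
  }
  mf <- jsonlite::read_json(mf_path)
  streams <- lapply(names(mf$streams), function(nm) {
    entry <- mf$streams[[nm]]
    df <- utils::read.csv(file.path(path, entry$file))
    values <- if (ncol(df) > 1L) as.matrix(df) else df[[1L]]
    list(rate_hz = as.numeric(entry$rate_hz), values = values)
  })
  names(streams) <- names(mf$streams)
  absent <- setdiff(OPTIONAL_STREAMS, names(streams))
  if (length(absent)) {
    message(sprintf(
      "recording '%s': optional stream(s) absent: %s",
      mf$subject_id, paste(absent, collapse = ", ")
    ))
  }
  labels <- as.integer(readLines(file.path(path, "labels.csv")))
  raw_recording(mf$subject_id, streams, labels, units = mf$units %||% "raw")
}

#' Read a cohort of recordings
#'
#' @param path Directory whose immediate subdirectories are CSV bundles
#'   (one per subject).
#' @return List of [raw_recording()] objects, ordered by directory name.
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "manifest.json"))]
  if (!length(dirs)) {
    stop_mindcnn(sprintf("no recording bundles under '%s'", path), "mindcnn_format_error")
  }
  lapply(dirs, read_recording)
}
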