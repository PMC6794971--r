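# signal_io: the 28-column feature container shared by training and evaluation

# column layout of the five channel blocks (28 columns total)
FEATURE_COLUMNS <- list(
  ECG = c("ECG_Peaks", "ECG_Average_Amplitude", "ECG_Differ_Mean", "ECG_Resting"),
  EMG = c("EMG_Peaks", "EMG_Average_Amplitude", "EMG_Differ_Mean"),
  RESP = c("RESP_Peaks", "RESP_Average_Amplitude", "RESP_Differ_Mean"),
  BVP = c("BVP_Peaks", "BVP_Average_Amplitude", "BVP_Differ_Mean"),
  ACCL = c(
    "ACC_Mean_X", "ACC_Mean_Y", "ACC_Mean_Z",
    "ACC_Std_X", "ACC_Std_Y", "ACC_Std_Z",
    "ACC_Kurt_X", "ACC_Kurt_Y", "ACC_Kurt_Z",
    "ACC_Crest_X", "ACC_Crest_Y", "ACC_Crest_Z",
    "ACC_Corr_XY", "ACC_Corr_XZ", "ACC_Corr_YZ"
  )
)

#' Channel block layout of the feature matrix
#'
#' The 28 feature columns are grouped into five channel blocks that feed the
#' five branches of the network: ECG (4 columns), EMG (3), respiration (3),
#' BVP (3) and accelerometer (15).
#'
#' @return Named list mapping channel name to the column indices of its block.
#' @export
channel_blocks <- function() {
  idx <- split(
    seq_along(unlist(FEATURE_COLUMNS, use.names = FALSE)),
    rep(names(FEATURE_COLUMNS), lengths(FEATURE_COLUMNS))
  )
  idx[names(FEATURE_COLUMNS)]
}

#' Construct a feature dataset
#'
#' One row per retained 10 Hz sample: minute-level peak features of
#' ECG/EMG/respiration/BVP broadcast across their minute, and subject-level
#' accelerometer statistics broadcast across their subject.
#'
#' @param features Numeric matrix with the 28 columns of [channel_blocks()]
#'   (in that order; column names are enforced).
#' @param labels Integer class codes in `0:4`, one per row.
#' @param subject_ids Character subject tag per row (needed for
#'   leave-one-subject-out splits).
#' @return An object of class `feature_dataset`.
#' @seealso [assemble_feature_matrix()], [write_feature_dataset()]
#' @export
feature_dataset <- function(features, labels, subject_ids) {
  expected <- unlist(FEATURE_COLUMNS, use.names = FALSE)
  features <- as.matrix(features)
  if (ncol(features) != length(expected)) {
    stop_mindcnn(
      sprintf("feature matrix must have %d columns, got %d", length(expected), ncol(features)),
      "mindcnn_format_error"
    )
  }
  colnames(features) <- expected
  labels <- as.integer(labels)
  subject_ids <- as.character(subject_ids)
  n <- nrow(features)
  if (length(labels) != n || length(subject_ids) != n) {
    stop_mindcnn("labels and subject_ids must match the number of rows", "mindcnn_consistency_error")
  }
  if (n > 0 && (!all(is.finite(features)) || any(labels < 0L) || any(labels > 4L))) {
    stop_mindcnn("features must be finite and labels in 0..4", "mindcnn_consistency_error")
  }
  structure(
    list(features = features, labels = labels, subject_ids = subject_ids),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf(
    "<feature_dataset> %d samples x %d features, %d subject(s)\n",
    nrow(x$features), ncol(x$features), length(unique(x$subject_ids))
  ))
  if (nrow(x$features)) {
    tab <- table(factor(x$labels, levels = 0:4, labels = class_levels()))
    print(tab)
  }
  invisible(x)
}

#' Write a feature dataset to CSV
#'
#' Single rectangular CSV: `subject_id`, `label`, then the 28 feature columns.
#' Doubles are serialized at 17 significant digits, so values survive a
#' round trip to well within 1e-12.
#'
#' @param ds A [feature_dataset()].
#' @param path Output file path.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_feature_dataset <- function(ds, path, format = "csv") {
  if (!identical(format, "csv")) {
    stop_mindcnn(sprintf("unsupported feature-dataset format '%s'", format), "mindcnn_format_error")
  }
  df <- data.frame(
    subject_id = ds$subject_ids, label = ds$labels,
    as.data.frame(ds$features), check.names = FALSE
  )
  write_csv_precise(df, path)
  invisible(path)
}

#' Read a feature dataset written by [write_feature_dataset()]
#'
#' Sample order is preserved exactly as stored.
#'
#' @param path CSV file path.
#' @param format Only `"csv"` is supported.
#' @return A [feature_dataset()].
#' @export
read_feature_dataset <- function(path, format = "csv") {
  if (!identical(format, "csv")) {
    stop_mindcnn(sprintf("unsupported feature-dataset format '%s'", format), "mindcnn_format_error")
  }
  expected <- unlist(FEATURE_COLUMNS, use.names = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(
    subject_id = "character", label = "integer",
    stats::setNames(rep("numeric", length(expected)), expected)
  ))
  feature_dataset(as.matrix(df[expected]), df$label, df$subject_id)
}
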