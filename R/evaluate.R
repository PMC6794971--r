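# evaluation: confusion matrix and per-class / macro precision, recall, F1

#' Confusion matrix of integer class predictions
#'
#' @param y_true,y_pred Integer class codes in `0:(n_classes - 1)`.
#' @param n_classes Number of classes; 5.
#' @return `n_classes x n_classes` count matrix, rows = true class,
#'   columns = predicted class, named by [class_levels()] when 5 classes.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 5L) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true < 0L) || any(y_true >= n_classes) ||
    any(y_pred < 0L) || any(y_pred >= n_classes)) {
    stop_mindcnn("labels out of range for the confusion matrix", "mindcnn_domain_error")
  }
  cm <- matrix(
    tabulate(y_true * n_classes + y_pred + 1L, nbins = n_classes^2),
    n_classes, n_classes,
    byrow = TRUE
  )
  nm <- if (n_classes == 5L) class_levels() else as.character(seq_len(n_classes) - 1L)
  dimnames(cm) <- list(true = nm, predicted = nm)
  cm
}

#' Per-class and macro classification report
#'
#' Recall is the diagonal over row sums (class support), precision the
#' diagonal over column sums, F1 their harmonic mean. Zero denominators
#' yield 0 with an explicit flag rather than NaN; macro averages are
#' unweighted means over the classes with nonzero support (flagged
#' zero-support classes are excluded).
#'
#' @param confusion Count matrix from [confusion_matrix()].
#' @return An object of class `eval_report`: `confusion`, `per_class` data
#'   frame (class, support, precision, recall, f1, zero_support,
#'   zero_predicted), `macro` list (precision, recall, f1), `accuracy`.
#' @export
classification_report <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  recall <- ifelse(support > 0, tp / support, 0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)) - 1L)
  per_class <- data.frame(
    class = classes, support = support, precision = precision,
    recall = recall, f1 = f1,
    zero_support = support == 0, zero_predicted = predicted == 0,
    row.names = NULL
  )
  keep <- support > 0
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      macro = list(
        precision = mean(precision[keep]),
        recall = mean(recall[keep]),
        f1 = mean(f1[keep])
      ),
      accuracy = sum(tp) / max(sum(cm), 1)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f over %d samples\n", x$accuracy, sum(x$confusion)))
  df <- x$per_class
  df[c("precision", "recall", "f1")] <- lapply(df[c("precision", "recall", "f1")], round, 4)
  print(df[c("class", "support", "precision", "recall", "f1")], row.names = FALSE)
  cat(sprintf(
    "macro: precision %.4f, recall %.4f, F1 %.4f\n",
    x$macro$precision, x$macro$recall, x$macro$f1
  ))
  invisible(x)
}

#' Export an evaluation report as a metric data frame
#'
#' One row per metric (accuracy, then per-class recall/precision/F1), in the
#' layout used by the optimizer-comparison and cross-validation tables.
#'
#' @param report An `eval_report`.
#' @return Two-column data frame (`metric`, `value`).
#' @export
report_as_table <- function(report) {
  pc <- report$per_class
  data.frame(
    metric = c(
      "accuracy",
      paste0("recall_", pc$class), paste0("precision_", pc$class), paste0("f1_", pc$class)
    ),
    value = c(report$accuracy, pc$recall, pc$precision, pc$f1)
  )
}
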