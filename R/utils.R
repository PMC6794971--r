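# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up, unlike base round() which rounds half to even
round_half_up <- function(x) floor(x + 0.5)

# stop with a classed condition so callers can distinguish error families
stop_mindcnn <- function(msg, class) {
  stop(structure(
    class = c(class, "mindcnn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# full-precision numeric formatting for text serialization (round-trips doubles)
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data frame as CSV keeping full double precision; character fields
# containing separators are quoted per RFC 4180
write_csv_precise <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      fmt_num(col)
    } else {
      out <- as.character(col)
      needs <- grepl('[",\n]', out)
      out[needs] <- paste0('"', gsub('"', '""', out[needs]), '"')
      out
    }
  })
  lines <- c(
    paste(names(df), collapse = ","),
    if (nrow(df)) do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Names of the five state-of-mind classes
#'
#' Class codes used throughout the package: `0 = baseline`, `1 = amusement`,
#' `2 = stress`, `3 = meditation`, `4 = recovery`. The sentinel `-1` marks
#' unlabeled spans in raw label streams and is dropped before modelling.
#'
#' @return Character vector of length 5 ordered by class code.
#' @export
class_levels <- function() {
  c("baseline", "amusement", "stress", "meditation", "recovery")
}
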