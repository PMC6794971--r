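# architecture: declarative five-branch network spec with shape and parameter audit

#' Adaptive kernel shape for a 1-D convolution branch
#'
#' The kernel length adapts to the branch's input feature count `x` as
#' `k = ceiling(x / 2)`: half the input width, rounded up. Both convolution
#' layers of a branch share this kernel.
#'
#' @param x Input feature count (>= 2).
#' @return Integer vector `c(k, 1)` — the 1-D kernel shape.
#' @examples
#' kernel_shape(4) # c(2, 1)
#' kernel_shape(15) # c(8, 1)
#' @export
kernel_shape <- function(x) {
  if (!is_count(x) || x < 2) {
    stop_mindcnn("kernel_shape requires an integer feature count >= 2", "mindcnn_domain_error")
  }
  c(as.integer(ceiling(x / 2)), 1L)
}

#' Build the multichannel CNN model specification
#'
#' Each channel's feature block enters its own branch: two valid (unpadded,
#' stride-1) 1-D convolutions with the branch's adaptive kernel
#' ([kernel_shape()]) and no pooling in between, then flatten, dropout, a
#' 64-unit dense layer, dropout, and a 32-unit dense layer. The five branch
#' outputs are concatenated and passed through a 32-unit dense layer and a
#' 5-way softmax output. All hidden activations are ReLU.
#'
#' @param channel_features Named integer vector of per-channel feature counts;
#'   defaults to the pipeline's `c(ECG = 4, EMG = 3, RESP = 3, BVP = 3, ACCL = 15)`.
#'   A single-entry vector yields the degenerate one-branch model used for
#'   single-channel comparisons.
#' @param conv_filters Filter counts of the two convolution layers.
#' @param dense_units Unit counts of the two per-branch dense layers.
#' @param trunk_units Units of the post-concatenation dense layer.
#' @param n_classes Softmax width; 5 states of mind.
#' @param dropout_rate Dropout probability after flatten and after the first
#'   dense layer of each branch (unprinted in the source architecture;
#'   default 0.25).
#' @return An object of class `mcnn_spec`.
#' @seealso [count_parameters()], [forward_shapes()], [train_model()]
#' @export
build_model <- function(channel_features = c(ECG = 4L, EMG = 3L, RESP = 3L, BVP = 3L, ACCL = 15L),
                        conv_filters = c(128L, 64L), dense_units = c(64L, 32L),
                        trunk_units = 32L, n_classes = 5L, dropout_rate = 0.25) {
  stopifnot(
    length(channel_features) >= 1L, !is.null(names(channel_features)),
    all(channel_features >= 2), length(conv_filters) == 2L,
    length(dense_units) == 2L, dropout_rate >= 0, dropout_rate < 1
  )
  branches <- lapply(channel_features, function(x) {
    x <- as.integer(x)
    k <- kernel_shape(x)[1L]
    L1 <- x - k + 1L
    L2 <- L1 - k + 1L
    if (L2 < 1L) {
      stop_mindcnn(
        sprintf("channel with %d features: second convolution output length %d <= 0", x, L2),
        "mindcnn_construction_error"
      )
    }
    list(x = x, k = k, L1 = L1, L2 = L2, flat = L2 * as.integer(conv_filters[2L]))
  })
  structure(
    list(
      branches = branches,
      conv_filters = as.integer(conv_filters),
      dense_units = as.integer(dense_units),
      trunk_units = as.integer(trunk_units),
      n_classes = as.integer(n_classes),
      dropout_rate = dropout_rate,
      concat_width = length(branches) * as.integer(dense_units[2L])
    ),
    class = "mcnn_spec"
  )
}

#' Per-layer trainable parameter counts of a model spec
#'
#' Convolution layers count `filters * kernel * in_channels + filters`
#' (weights plus biases); dense layers `units * in_width + units`; the
#' concatenation layer has none.
#'
#' @param spec An `mcnn_spec` from [build_model()].
#' @return Data frame with columns `layer`, `channel`, `parameters`, plus a
#'   `total` attribute; the sum of `parameters` is the trainable total.
#' @export
count_parameters <- function(spec) {
  f <- spec$conv_filters
  d <- spec$dense_units
  rows <- list()
  for (ch in names(spec$branches)) {
    b <- spec$branches[[ch]]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = c("conv1d_1", "conv1d_2", "dense_1", "dense_2"),
      channel = ch,
      parameters = c(
        f[1L] * b$k * 1L + f[1L],
        f[2L] * b$k * f[1L] + f[2L],
        d[1L] * b$flat + d[1L],
        d[2L] * d[1L] + d[2L]
      )
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = c("concatenate", "dense_trunk", "dense_output"),
    channel = "trunk",
    parameters = c(
      0L,
      spec$trunk_units * spec$concat_width + spec$trunk_units,
      spec$n_classes * spec$trunk_units + spec$n_classes
    )
  )
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$parameters)
  out
}

#' Per-layer output dimensions of a model spec
#'
#' Valid-convolution arithmetic: `L_out = L_in - k + 1`; flatten width is
#' `L * filters`.
#'
#' @param spec An `mcnn_spec` from [build_model()].
#' @return Named list: per branch the `input`, `conv1`, `conv2` shapes
#'   (`c(length, filters)`), `flatten`, `dense_1`, `dense_2` widths; plus
#'   trunk `concat`, `dense_trunk` and `output` widths.
#' @export
forward_shapes <- function(spec) {
  f <- spec$conv_filters
  d <- spec$dense_units
  branches <- lapply(spec$branches, function(b) {
    list(
      input = c(b$x, 1L),
      conv1 = c(b$L1, f[1L]),
      conv2 = c(b$L2, f[2L]),
      flatten = b$flat,
      dense_1 = d[1L],
      dense_2 = d[2L]
    )
  })
  list(
    branches = branches,
    concat = spec$concat_width,
    dense_trunk = spec$trunk_units,
    output = spec$n_classes
  )
}

#' Layer-by-layer audit table of the model
#'
#' One row per (layer, channel) combining kernel shape, trainable parameter
#' count and output dimension — the complete structural audit of the network,
#' derivable without any training.
#'
#' @param spec An `mcnn_spec` from [build_model()].
#' @return Data frame with columns `layer`, `channel`, `kernel`,
#'   `parameters`, `output_dim`, `activation`.
#' @export
audit_table <- function(spec) {
  pars <- count_parameters(spec)
  shp <- forward_shapes(spec)
  fmt_dim <- function(v) if (length(v) > 1L) sprintf("(%s)", paste(v, collapse = ", ")) else as.character(v)
  rows <- list()
  for (ch in names(spec$branches)) {
    b <- spec$branches[[ch]]
    s <- shp$branches[[ch]]
    p <- pars$parameters[pars$channel == ch]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = c("input", "conv1d_1", "conv1d_2", "flatten", "dropout", "dense_1", "dropout", "dense_2"),
      channel = ch,
      kernel = c("-", sprintf("(%d, 1)", b$k), sprintf("(%d, 1)", b$k), "-", "-", "-", "-", "-"),
      parameters = c(0L, p[1L], p[2L], 0L, 0L, p[3L], 0L, p[4L]),
      output_dim = c(
        fmt_dim(s$input), fmt_dim(s$conv1), fmt_dim(s$conv2),
        fmt_dim(s$flatten), fmt_dim(s$flatten), fmt_dim(s$dense_1),
        fmt_dim(s$dense_1), fmt_dim(s$dense_2)
      ),
      activation = c("-", "relu", "relu", "-", "-", "relu", "-", "relu")
    )
  }
  pt <- pars$parameters[pars$channel == "trunk"]
  rows[[length(rows) + 1L]] <- data.frame(
    layer = c("concatenate", "dense_trunk", "dense_output"),
    channel = "trunk",
    kernel = "-",
    parameters = pt,
    output_dim = c(fmt_dim(shp$concat), fmt_dim(shp$dense_trunk), fmt_dim(shp$output)),
    activation = c("-", "relu", "softmax")
  )
  do.call(rbind, rows)
}

#' @export
print.mcnn_spec <- function(x, ...) {
  cat(sprintf(
    "<mcnn_spec> %d branch(es), concat width %d, %d classes, dropout %.2f\n",
    length(x$branches), x$concat_width, x$n_classes, x$dropout_rate
  ))
  for (ch in names(x$branches)) {
    b <- x$branches[[ch]]
    cat(sprintf(
      "  %-5s x=%2d k=%d: conv(%d,%d) -> conv(%d,%d) -> flat %d -> dense %d -> dense %d\n",
      ch, b$x, b$k, b$L1, x$conv_filters[1], b$L2, x$conv_filters[2],
      b$flat, x$dense_units[1], x$dense_units[2]
    ))
  }
  cat(sprintf("  total trainable parameters: %d\n", attr(count_parameters(x), "total")))
  invisible(x)
}

#' Serialize a model spec to JSON
#'
#' @param spec An `mcnn_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  json <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(json)
}
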