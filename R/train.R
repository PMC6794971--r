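# training: split regimes, categorical cross-entropy, minibatch training loop,
# optimizer comparison and leave-one-subject-out cross-validation

#' Optimizer configuration
#'
#' Defaults are the tuned Adam hyperparameters found by the sequential
#' model-based search (see [smbo_search()]): learning rate 0.00125,
#' beta_1 = 0.9765841, beta_2 = 0.8541287, decay 0.000235. The decay applies
#' the schedule `lr_t = lr / (1 + decay * t)` over optimizer steps. For
#' RMSprop and SGD only the learning rate and decay apply; the betas are
#' Adam-specific.
#'
#' @param name One of `"adam"`, `"rmsprop"`, `"sgd"`.
#' @param learning_rate Positive step size.
#' @param beta_1,beta_2 Adam moment decay rates in (0, 1).
#' @param decay Learning-rate decay per step (>= 0).
#' @param epochs Training epochs; 100.
#' @param batch_size Minibatch size; 256.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(name = c("adam", "rmsprop", "sgd"),
                             learning_rate = 0.00125,
                             beta_1 = 0.9765841, beta_2 = 0.8541287,
                             decay = 0.000235, epochs = 100L, batch_size = 256L) {
  name <- match.arg(name)
  stopifnot(
    learning_rate >= 0, decay >= 0,
    beta_1 > 0, beta_1 < 1, beta_2 > 0, beta_2 < 1,
    is_count(epochs), is_count(batch_size)
  )
  structure(
    list(
      name = name, learning_rate = learning_rate, beta_1 = beta_1,
      beta_2 = beta_2, decay = decay, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size)
    ),
    class = "optimizer_config"
  )
}

new_split_plan <- function(regime, train, val, test, seed, held_out_subject = NULL) {
  structure(
    list(
      regime = regime, train = train, val = val, test = test,
      seed = seed, held_out_subject = held_out_subject
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %s: train %d / val %d / test %d%s (seed %s)\n",
    x$regime, length(x$train), length(x$val), length(x$test),
    if (!is.null(x$held_out_subject)) sprintf(" [held out: %s]", x$held_out_subject) else "",
    format(x$seed)
  ))
  invisible(x)
}

#' Randomized 70/20/10 split (Type I)
#'
#' Samples are assigned uniformly at random: `round(0.7 n)` to training,
#' `round(0.2 n)` to validation (round half up), and the remainder to
#' testing. Deterministic given the seed.
#'
#' @param n_samples Total sample count (>= 10).
#' @param seed Integer RNG seed.
#' @param fractions Train and validation fractions; test takes the rest.
#' @return A `split_plan` with disjoint index sets covering `1:n_samples`.
#' @export
split_type1 <- function(n_samples, seed = 1L, fractions = c(train = 0.7, val = 0.2)) {
  stopifnot(is_count(n_samples), n_samples >= 10, sum(fractions) < 1)
  n_train <- round_half_up(fractions[[1L]] * n_samples)
  n_val <- round_half_up(fractions[[2L]] * n_samples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n_samples)
  new_split_plan(
    "type1",
    train = idx[seq_len(n_train)],
    val = idx[n_train + seq_len(n_val)],
    test = idx[(n_train + n_val + 1L):n_samples],
    seed = seed
  )
}

#' Leave-one-subject-out split (Type II)
#'
#' The held-out subject's samples form the entire test set; the remaining
#' samples are split 80:20 into training and validation uniformly at random.
#'
#' @param x A [feature_dataset()] or a character vector of per-sample
#'   subject ids.
#' @param held_out_subject Subject id to hold out.
#' @param seed Integer RNG seed.
#' @param train_fraction Training share of the non-held-out pool; 0.8.
#' @return A `split_plan` with `held_out_subject` recorded.
#' @export
split_type2 <- function(x, held_out_subject, seed = 1L, train_fraction = 0.8) {
  subject_ids <- if (inherits(x, "feature_dataset")) x$subject_ids else as.character(x)
  test <- which(subject_ids == held_out_subject)
  if (!length(test)) {
    stop_mindcnn(sprintf("unknown subject '%s'", held_out_subject), "mindcnn_domain_error")
  }
  rest <- which(subject_ids != held_out_subject)
  if (!length(rest)) {
    stop_mindcnn("cohort has a single subject: empty training pool", "mindcnn_domain_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rest <- sample(rest)
  n_train <- round_half_up(train_fraction * length(rest))
  new_split_plan(
    "type2",
    train = rest[seq_len(n_train)],
    val = rest[(n_train + 1L):length(rest)],
    test = test,
    seed = seed, held_out_subject = held_out_subject
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' One-hot encode class labels
#'
#' @param labels Integer codes in `0:(n_classes - 1)`.
#' @param n_classes Number of classes.
#' @return `length(labels) x n_classes` 0/1 matrix.
#' @export
one_hot <- function(labels, n_classes = 5L) {
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= n_classes)) {
    stop_mindcnn("labels out of range for one-hot encoding", "mindcnn_domain_error")
  }
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Categorical cross-entropy loss
#'
#' `-(1/n) * sum_i sum_j y_ij log(p_ij)`: the mean negative log predicted
#' probability of the true class. Zero predicted probabilities at a true
#' class are clipped at `eps` (with a warning) rather than raising.
#'
#' @param y_true One-hot `n x C` matrix, or an integer label vector in
#'   `0:(C-1)`.
#' @param y_pred `n x C` matrix of predicted probabilities; rows must sum to
#'   1 within 1e-6.
#' @param eps Clipping floor for predicted probabilities.
#' @return Non-negative scalar loss; 0 iff every true class has probability 1.
#' @export
categorical_cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  y_pred <- as.matrix(y_pred)
  if (!is.matrix(y_true)) y_true <- one_hot(y_true, ncol(y_pred))
  stopifnot(nrow(y_true) == nrow(y_pred), ncol(y_true) == ncol(y_pred))
  if (any(abs(rowSums(y_pred) - 1) > 1e-6)) {
    stop_mindcnn("rows of y_pred must sum to 1", "mindcnn_domain_error")
  }
  p_true <- rowSums(y_true * y_pred)
  if (any(p_true <= 0)) {
    warning(sprintf("%d zero predicted probabilities clipped at %g", sum(p_true <= 0), eps))
  }
  # `+ 0` normalizes IEEE negative zero when every probability is exactly 1
  -mean(log(pmin(pmax(p_true, eps), 1))) + 0
}

split_channels <- function(features, spec) {
  blocks <- channel_blocks()
  out <- lapply(names(spec$branches), function(ch) {
    idx <- blocks[[ch]]
    if (is.null(idx) || length(idx) != spec$branches[[ch]]$x) {
      stop_mindcnn(
        sprintf("channel '%s' does not match the feature layout", ch),
        "mindcnn_format_error"
      )
    }
    features[, idx, drop = FALSE]
  })
  names(out) <- names(spec$branches)
  out
}

eval_in_chunks <- function(weights, spec, Xlist, chunk = 4096L) {
  n <- nrow(Xlist[[1L]])
  out <- matrix(0, n, spec$n_classes)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    sub <- lapply(Xlist, function(m) m[lo:hi, , drop = FALSE])
    out[lo:hi, ] <- mcnn_forward(weights, spec, sub)$probs
  }
  out
}

#' Train the multichannel network
#'
#' Minibatch training with categorical cross-entropy. Feature columns are
#' standardized (z-scored) using training-set statistics by default — the
#' engineered features span very different scales (counts per minute vs
#' millivolt amplitudes). Fully reproducible given `(seed, opt)`.
#'
#' @param spec An `mcnn_spec` from [build_model()].
#' @param ds A [feature_dataset()].
#' @param plan A `split_plan` indexing into `ds`.
#' @param opt An [optimizer_config()].
#' @param epochs,batch_size Override the config's values.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param standardize Z-score features with training-set mean/sd.
#' @param class_weights Optional numeric vector of length `n_classes`
#'   reweighting the loss per class; `NULL` (default) leaves class imbalance
#'   unaddressed.
#' @param verbose Print per-epoch metrics.
#' @return An object of class `mcnn_fit`: `weights`, `spec`, `scaler`,
#'   `history` (one row per epoch with train/val loss and accuracy),
#'   `config`, `plan`.
#' @export
train_model <- function(spec, ds, plan, opt = optimizer_config(),
                        epochs = NULL, batch_size = NULL, seed = 1L,
                        standardize = TRUE, class_weights = NULL,
                        verbose = FALSE) {
  epochs <- epochs %||% opt$epochs
  batch_size <- batch_size %||% opt$batch_size
  idx_all <- c(plan$train, plan$val, plan$test)
  if (!length(plan$train) || !length(plan$val)) {
    stop_mindcnn("split plan has an empty train or validation member", "mindcnn_domain_error")
  }
  if (max(idx_all) > nrow(ds$features) || min(idx_all) < 1L) {
    stop_mindcnn("split plan indexes outside the dataset", "mindcnn_consistency_error")
  }
  X <- ds$features
  scaler <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  if (standardize) {
    scaler$center <- colMeans(X[plan$train, , drop = FALSE])
    scaler$scale <- apply(X[plan$train, , drop = FALSE], 2L, stats::sd)
    scaler$scale[scaler$scale == 0 | !is.finite(scaler$scale)] <- 1
  }
  X <- sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, `/`)
  Xlist <- split_channels(X, spec)
  Ytr <- one_hot(ds$labels[plan$train], spec$n_classes)
  tr_list <- lapply(Xlist, function(m) m[plan$train, , drop = FALSE])
  val_list <- lapply(Xlist, function(m) m[plan$val, , drop = FALSE])
  yval <- ds$labels[plan$val]
  ytr <- ds$labels[plan$train]
  sw_of <- function(lab) {
    if (is.null(class_weights)) NULL else class_weights[lab + 1L]
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  weights <- init_weights(spec)
  state <- init_opt_state(weights, opt)
  n_tr <- length(plan$train)
  step <- 0L
  history <- data.frame(
    epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0),
    train_acc = numeric(0), val_acc = numeric(0)
  )
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n_tr)
    for (lo in seq(1L, n_tr, by = batch_size)) {
      bidx <- perm[lo:min(lo + batch_size - 1L, n_tr)]
      bX <- lapply(tr_list, function(m) m[bidx, , drop = FALSE])
      lg <- mcnn_loss_grad(weights, spec, bX, Ytr[bidx, , drop = FALSE],
        sample_weights = sw_of(ytr[bidx])
      )
      step <- step + 1L
      upd <- opt_step(weights, lg$grads, state, opt, step)
      weights <- upd$weights
      state <- upd$state
    }
    ptr <- eval_in_chunks(weights, spec, tr_list)
    pva <- eval_in_chunks(weights, spec, val_list)
    row <- data.frame(
      epoch = ep,
      train_loss = suppressWarnings(categorical_cross_entropy(ytr, ptr)),
      val_loss = suppressWarnings(categorical_cross_entropy(yval, pva)),
      train_acc = mean(max.col(ptr) - 1L == ytr),
      val_acc = mean(max.col(pva) - 1L == yval)
    )
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f / %.4f  acc %.4f / %.4f",
        ep, row$train_loss, row$val_loss, row$train_acc, row$val_acc
      ))
    }
  }
  structure(
    list(
      weights = weights, spec = spec, scaler = scaler, history = history,
      config = opt, plan = plan, seed = seed
    ),
    class = "mcnn_fit"
  )
}

#' @export
print.mcnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<mcnn_fit> %s, %d epochs; final loss %.4f/%.4f, acc %.4f/%.4f (train/val)\n",
    x$config$name, nrow(x$history), last$train_loss, last$val_loss,
    last$train_acc, last$val_acc
  ))
  invisible(x)
}

#' Predict classes or probabilities from a trained model
#'
#' @param object An `mcnn_fit`.
#' @param newdata A [feature_dataset()] or a feature matrix with the
#'   28 pipeline columns.
#' @param type `"prob"` for the softmax matrix, `"class"` for integer class
#'   codes (argmax).
#' @param thresholds Optional per-class probability floors: classes whose
#'   predicted probability falls below their threshold are excluded from the
#'   argmax (plain argmax is used when all classes fall below).
#' @param ... Unused.
#' @return Probability matrix or integer class vector (codes `0:4`).
#' @export
predict.mcnn_fit <- function(object, newdata, type = c("prob", "class"),
                             thresholds = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_dataset")) newdata$features else as.matrix(newdata)
  X <- sweep(sweep(X, 2L, object$scaler$center), 2L, object$scaler$scale, `/`)
  probs <- eval_in_chunks(object$weights, object$spec, split_channels(X, object$spec))
  if (type == "prob") {
    return(probs)
  }
  if (is.null(thresholds)) {
    return(max.col(probs) - 1L)
  }
  masked <- sweep(probs, 2L, thresholds, function(p, th) ifelse(p >= th, p, 0))
  none <- rowSums(masked) == 0
  masked[none, ] <- probs[none, , drop = FALSE]
  max.col(masked) - 1L
}

#' Compare optimizers on a fixed split
#'
#' Trains one model per configuration on identical train/validation/test
#' indices and reports test-set metrics through the evaluation module.
#'
#' @param spec An `mcnn_spec`.
#' @param ds A [feature_dataset()].
#' @param plan A `split_plan` reused across optimizers.
#' @param configs List of [optimizer_config()]s (>= 1).
#' @param seed,epochs,batch_size Passed to [train_model()].
#' @return List with `table` (data frame: one metric column per optimizer —
#'   accuracy plus per-class recall/precision/F1) and `reports` (one
#'   [classification_report()] per optimizer).
#' @export
compare_optimizers <- function(spec, ds, plan, configs, seed = 1L,
                               epochs = NULL, batch_size = NULL) {
  stopifnot(length(configs) >= 1L)
  reports <- list()
  cols <- list()
  for (cfg in configs) {
    fit <- train_model(spec, ds, plan, cfg,
      epochs = epochs, batch_size = batch_size, seed = seed
    )
    pred <- predict(fit, ds$features[plan$test, , drop = FALSE], type = "class")
    rep <- classification_report(
      confusion_matrix(ds$labels[plan$test], pred, spec$n_classes)
    )
    reports[[cfg$name]] <- rep
    cols[[cfg$name]] <- c(
      accuracy = rep$accuracy,
      stats::setNames(rep$per_class$recall, paste0("recall_", rep$per_class$class)),
      stats::setNames(rep$per_class$precision, paste0("precision_", rep$per_class$class)),
      stats::setNames(rep$per_class$f1, paste0("f1_", rep$per_class$class))
    )
  }
  tab <- data.frame(metric = names(cols[[1L]]), check.names = FALSE)
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]])
  list(table = tab, reports = reports)
}

#' Leave-one-subject-out cross-validation
#'
#' Runs one Type II fold per subject: train on the rest, test on the held-out
#' subject, and report per-fold metrics.
#'
#' @param spec An `mcnn_spec`.
#' @param ds A [feature_dataset()].
#' @param opt An [optimizer_config()].
#' @param seed,epochs,batch_size Passed to [train_model()].
#' @return List with `reports` (named per subject) and `table` (one metric
#'   column per subject).
#' @export
loso_evaluate <- function(spec, ds, opt = optimizer_config(), seed = 1L,
                          epochs = NULL, batch_size = NULL) {
  subjects <- unique(ds$subject_ids)
  reports <- list()
  cols <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    plan <- split_type2(ds, s, seed = seed + i)
    fit <- train_model(spec, ds, plan, opt,
      epochs = epochs, batch_size = batch_size, seed = seed + i
    )
    pred <- predict(fit, ds$features[plan$test, , drop = FALSE], type = "class")
    rep <- classification_report(
      confusion_matrix(ds$labels[plan$test], pred, spec$n_classes)
    )
    reports[[s]] <- rep
    cols[[s]] <- c(
      accuracy = rep$accuracy,
      stats::setNames(rep$per_class$recall, paste0("recall_", rep$per_class$class)),
      stats::setNames(rep$per_class$precision, paste0("precision_", rep$per_class$class)),
      stats::setNames(rep$per_class$f1, paste0("f1_", rep$per_class$class))
    )
  }
  tab <- data.frame(metric = names(cols[[1L]]), check.names = FALSE)
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]])
  list(table = tab, reports = reports)
}
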