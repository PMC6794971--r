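# numerical implementation of the multichannel network: seeded Glorot
# initialization, forward pass, exact backprop, and the three optimizers.
# Shapes follow the mcnn_spec exactly (valid convolutions, stride 1).

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# weights are a nested list mirroring the spec; rows of W2 are ordered
# position-major within input filter, matching the patch flattening below
init_weights <- function(spec) {
  f <- spec$conv_filters
  d <- spec$dense_units
  branches <- lapply(spec$branches, function(b) {
    list(
      W1 = glorot(b$k, b$k * f[1L], c(b$k, f[1L])), b1 = numeric(f[1L]),
      W2 = glorot(b$k * f[1L], b$k * f[2L], c(b$k * f[1L], f[2L])), b2 = numeric(f[2L]),
      W3 = glorot(b$flat, d[1L], c(b$flat, d[1L])), b3 = numeric(d[1L]),
      W4 = glorot(d[1L], d[2L], c(d[1L], d[2L])), b4 = numeric(d[2L])
    )
  })
  list(
    branches = branches,
    trunk = list(
      W5 = glorot(spec$concat_width, spec$trunk_units, c(spec$concat_width, spec$trunk_units)),
      b5 = numeric(spec$trunk_units),
      W6 = glorot(spec$trunk_units, spec$n_classes, c(spec$trunk_units, spec$n_classes)),
      b6 = numeric(spec$n_classes)
    )
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(m, b) sweep(m, 2L, b, `+`)

# forward pass over a list of per-channel input matrices (n x x_ch).
# training = TRUE draws inverted-dropout masks from the current RNG stream;
# keep_cache retains the activations needed by backprop.
mcnn_forward <- function(weights, spec, Xlist, training = FALSE,
                         keep_cache = training, return_branches = FALSE) {
  f <- spec$conv_filters
  keep <- 1 - if (training) spec$dropout_rate else 0
  n <- nrow(Xlist[[1L]])
  cache <- list(branches = list())
  H2s <- list()
  for (ch in names(spec$branches)) {
    b <- spec$branches[[ch]]
    w <- weights$branches[[ch]]
    X <- Xlist[[ch]]
    Z1 <- array(0, c(n, b$L1, f[1L]))
    for (t in seq_len(b$L1)) {
      Z1[, t, ] <- X[, t:(t + b$k - 1L), drop = FALSE] %*% w$W1
    }
    Z1 <- sweep(Z1, 3L, w$b1, `+`)
    A1 <- pmax(Z1, 0)
    Z2 <- array(0, c(n, b$L2, f[2L]))
    patches <- vector("list", b$L2)
    for (t in seq_len(b$L2)) {
      P <- A1[, t:(t + b$k - 1L), , drop = FALSE]
      dim(P) <- c(n, b$k * f[1L])
      patches[[t]] <- P
      Z2[, t, ] <- P %*% w$W2
    }
    Z2 <- sweep(Z2, 3L, w$b2, `+`)
    A2 <- pmax(Z2, 0)
    Fm <- matrix(A2, n, b$flat)
    M1 <- if (keep < 1) matrix((stats::runif(n * b$flat) < keep) / keep, n, b$flat) else 1
    D1 <- Fm * M1
    H1pre <- add_bias(D1 %*% w$W3, w$b3)
    H1 <- pmax(H1pre, 0)
    M2 <- if (keep < 1) matrix((stats::runif(length(H1)) < keep) / keep, nrow(H1), ncol(H1)) else 1
    D2 <- H1 * M2
    H2pre <- add_bias(D2 %*% w$W4, w$b4)
    H2 <- pmax(H2pre, 0)
    H2s[[ch]] <- H2
    cache$branches[[ch]] <- list(
      X = X, Z1 = Z1, A1 = A1, Z2 = Z2, patches = patches,
      M1 = M1, D1 = D1, H1pre = H1pre, M2 = M2, D2 = D2, H2pre = H2pre
    )
  }
  C <- do.call(cbind, H2s)
  T1pre <- add_bias(C %*% weights$trunk$W5, weights$trunk$b5)
  T1 <- pmax(T1pre, 0)
  logits <- add_bias(T1 %*% weights$trunk$W6, weights$trunk$b6)
  probs <- softmax_rows(logits)
  out <- list(probs = probs)
  if (return_branches) out$branch_outputs <- H2s
  if (keep_cache) {
    out$cache <- cache
    out$C <- C
    out$T1pre <- T1pre
    out$T1 <- T1
  }
  out
}

# loss + full gradient for one (already dropout-masked) forward pass
mcnn_loss_grad <- function(weights, spec, Xlist, Y, training = TRUE,
                           sample_weights = NULL) {
  fw <- mcnn_forward(weights, spec, Xlist, training = training, keep_cache = TRUE)
  n <- nrow(Y)
  P <- pmin(pmax(fw$probs, 1e-12), 1)
  sw <- sample_weights %||% rep(1, n)
  loss <- -sum(sw * rowSums(Y * log(P))) / sum(sw) + 0
  if (!is.finite(loss)) {
    stop_mindcnn("non-finite training loss; aborting (check inputs/learning rate)", "mindcnn_numeric_error")
  }
  dlogits <- (fw$probs - Y) * (sw / sum(sw))
  tr <- weights$trunk
  gW6 <- crossprod(fw$T1, dlogits)
  gb6 <- colSums(dlogits)
  dT1 <- dlogits %*% t(tr$W6)
  dT1pre <- dT1 * (fw$T1pre > 0)
  gW5 <- crossprod(fw$C, dT1pre)
  gb5 <- colSums(dT1pre)
  dC <- dT1pre %*% t(tr$W5)
  f <- spec$conv_filters
  d2 <- spec$dense_units[2L]
  grads <- list(branches = list(), trunk = list(W5 = gW5, b5 = gb5, W6 = gW6, b6 = gb6))
  col0 <- 0L
  for (ch in names(spec$branches)) {
    b <- spec$branches[[ch]]
    w <- weights$branches[[ch]]
    cc <- fw$cache$branches[[ch]]
    dH2 <- dC[, (col0 + 1L):(col0 + d2), drop = FALSE]
    col0 <- col0 + d2
    dH2pre <- dH2 * (cc$H2pre > 0)
    gW4 <- crossprod(cc$D2, dH2pre)
    gb4 <- colSums(dH2pre)
    dD2 <- dH2pre %*% t(w$W4)
    dH1pre <- (dD2 * cc$M2) * (cc$H1pre > 0)
    gW3 <- crossprod(cc$D1, dH1pre)
    gb3 <- colSums(dH1pre)
    dD1 <- dH1pre %*% t(w$W3)
    dFm <- dD1 * cc$M1
    nb <- nrow(dFm)
    dA2 <- array(dFm, c(nb, b$L2, f[2L]))
    dZ2 <- dA2 * (cc$Z2 > 0)
    gW2 <- array(0, dim(w$W2))
    gb2 <- numeric(f[2L])
    dA1 <- array(0, c(nb, b$L1, f[1L]))
    for (t in seq_len(b$L2)) {
      dZ2t <- matrix(dZ2[, t, ], nb, f[2L])
      gW2 <- gW2 + crossprod(cc$patches[[t]], dZ2t)
      gb2 <- gb2 + colSums(dZ2t)
      dP <- dZ2t %*% t(w$W2)
      dim(dP) <- c(nb, b$k, f[1L])
      dA1[, t:(t + b$k - 1L), ] <- dA1[, t:(t + b$k - 1L), , drop = FALSE] + dP
    }
    dZ1 <- dA1 * (cc$Z1 > 0)
    gW1 <- array(0, dim(w$W1))
    gb1 <- numeric(f[1L])
    for (t in seq_len(b$L1)) {
      dZ1t <- matrix(dZ1[, t, ], nb, f[1L])
      gW1 <- gW1 + crossprod(cc$X[, t:(t + b$k - 1L), drop = FALSE], dZ1t)
      gb1 <- gb1 + colSums(dZ1t)
    }
    grads$branches[[ch]] <- list(
      W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
      W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4
    )
  }
  list(loss = loss, grads = grads, probs = fw$probs)
}

# ---- optimizers ---------------------------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else array(0, dim = dim(p) %||% length(p))
}

init_opt_state <- function(weights, opt) {
  switch(opt$name,
    sgd = list(),
    rmsprop = list(v = zeros_like(weights)),
    adam = list(m = zeros_like(weights), v = zeros_like(weights))
  )
}

# one optimizer step over the nested parameter list; t is the global step count
opt_step <- function(weights, grads, state, opt, t) {
  lr <- opt$learning_rate / (1 + opt$decay * t)
  eps <- 1e-8
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], if (is.null(m)) NULL else m[[nm]], if (is.null(v)) NULL else v[[nm]])
        out$p[[nm]] <- r$p
        if (!is.null(m)) out$m[[nm]] <- r$m
        if (!is.null(v)) out$v[[nm]] <- r$v
      }
      return(out)
    }
    switch(opt$name,
      sgd = list(p = p - lr * g, m = NULL, v = NULL),
      rmsprop = {
        v2 <- 0.9 * v + 0.1 * g^2
        list(p = p - lr * g / (sqrt(v2) + eps), m = NULL, v = v2)
      },
      adam = {
        m2 <- opt$beta_1 * m + (1 - opt$beta_1) * g
        v2 <- opt$beta_2 * v + (1 - opt$beta_2) * g^2
        mhat <- m2 / (1 - opt$beta_1^t)
        vhat <- v2 / (1 - opt$beta_2^t)
        list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
      }
    )
  }
  r <- walk(weights, grads, state$m, state$v)
  list(weights = r$p, state = list(m = r$m, v = r$v))
}
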