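# Independent brute-force oracles. These deliberately re-derive results with
# naive loops so they share no code path with the package implementation.

# O(n * w) peak scan: local maxima above threshold, thinned by repeatedly
# keeping the largest remaining candidate (earlier index on ties) and
# discarding everything within min_distance of it
oracle_peaks <- function(x, min_distance, threshold) {
  cand <- integer(0)
  for (i in 2:(length(x) - 1L)) {
    if (x[i] > x[i - 1L] && x[i] >= x[i + 1L] && x[i] > threshold) cand <- c(cand, i)
  }
  kept <- integer(0)
  while (length(cand)) {
    best <- cand[which.max(x[cand])] # which.max returns the first maximum
    kept <- c(kept, best)
    cand <- cand[abs(cand - best) >= min_distance]
  }
  sort(kept)
}

# per-sample negative log predicted probability of the true class
oracle_logloss <- function(labels, probs, eps = 1e-12) {
  total <- 0
  for (i in seq_along(labels)) {
    p <- probs[i, labels[i] + 1L]
    total <- total - log(max(p, eps))
  }
  total / length(labels)
}

# pairwise counting
oracle_confusion <- function(y_true, y_pred, k) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

# block means computed one block at a time
oracle_block_means <- function(x, b) {
  m <- length(x) %/% b
  out <- numeric(m)
  for (i in seq_len(m)) out[i] <- mean(x[((i - 1L) * b + 1L):(i * b)])
  out
}
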