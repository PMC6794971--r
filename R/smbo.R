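# smbo: sequential model-based optimization over training hyperparameters.
# Gaussian-process surrogate (Matern 5/2) with an expected-improvement
# acquisition maximized over Latin-hypercube candidate pools.

#' Hyperparameter search space
#'
#' Box constraints per dimension, with optional log10 scaling for parameters
#' spanning orders of magnitude (the learning rate). Defaults cover the four
#' Adam hyperparameters tuned by the pipeline.
#'
#' @param lower,upper Named numeric vectors of bounds (`lower < upper`).
#' @param log Logical vector: search the dimension on a log10 scale.
#' @param n_initial Size of the initial Latin-hypercube design (>= 2).
#' @param n_iterations Number of model-guided evaluations after the design.
#' @param seed Integer RNG seed.
#' @return An object of class `hyper_space`.
#' @export
hyper_space <- function(lower = c(learning_rate = 1e-5, beta_1 = 0.8, beta_2 = 0.8, decay = 0),
                        upper = c(learning_rate = 1e-2, beta_1 = 0.999, beta_2 = 0.9999, decay = 1e-3),
                        log = c(TRUE, FALSE, FALSE, FALSE),
                        n_initial = 8L, n_iterations = 20L, seed = 1L) {
  stopifnot(
    length(lower) == length(upper), all(lower < upper),
    length(log) == length(lower), !is.null(names(lower)),
    is_count(n_initial), n_initial >= 2, n_iterations >= 0
  )
  structure(
    list(
      lower = lower, upper = upper, log = log,
      names = names(lower), d = length(lower),
      n_initial = as.integer(n_initial),
      n_iterations = as.integer(n_iterations), seed = as.integer(seed)
    ),
    class = "hyper_space"
  )
}

# unit-cube <-> natural scale transforms
space_from_unit <- function(space, U) {
  U <- matrix(U, ncol = space$d)
  out <- U
  for (j in seq_len(space$d)) {
    if (space$log[j]) {
      lo <- log10(space$lower[j])
      hi <- log10(space$upper[j])
      out[, j] <- 10^(lo + U[, j] * (hi - lo))
    } else {
      out[, j] <- space$lower[j] + U[, j] * (space$upper[j] - space$lower[j])
    }
  }
  colnames(out) <- space$names
  out
}

#' Expected improvement under a Gaussian surrogate
#'
#' For a maximization problem with posterior mean `mu`, posterior standard
#' deviation `sigma` and incumbent `f_star`:
#' `EI = (mu - f_star) * pnorm(z) + sigma * dnorm(z)` with
#' `z = (mu - f_star) / sigma`; when `sigma = 0` it degenerates to
#' `max(mu - f_star, 0)`. This is the closed form of
#' `E[max(f(x) - f_star, 0)]` for Gaussian `f(x)`.
#'
#' @param mu Surrogate posterior mean (vectorized).
#' @param sigma Surrogate posterior standard deviation (>= 0).
#' @param f_star Best objective value observed so far.
#' @return Non-negative expected improvement, same length as `mu`.
#' @export
expected_improvement <- function(mu, sigma, f_star) {
  stopifnot(all(sigma >= 0))
  imp <- mu - f_star
  out <- pmax(imp, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- imp[pos] / sigma[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  out
}

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

# small exact GP on the unit cube; lengthscale chosen from a grid by
# log marginal likelihood. Inputs X in [0,1]^d, y standardized internally.
gp_fit <- function(X, y, noise = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  D <- as.matrix(stats::dist(X))
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.5, 1, 2) * sqrt(ncol(X))) {
    K <- matern52(D, ell) + diag(noise + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(L, forwardsolve(t(L), yz))
    lml <- -0.5 * sum(yz * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
    if (is.null(best) || lml > best$lml) {
      best <- list(ell = ell, L = L, alpha = alpha, lml = lml)
    }
  }
  if (is.null(best)) {
    stop_mindcnn("Gaussian-process fit failed for every lengthscale", "mindcnn_numeric_error")
  }
  list(X = X, L = best$L, alpha = best$alpha, ell = best$ell, ym = ym, ys = ys, noise = noise)
}

gp_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  cross <- matrix(0, nrow(fit$X), nrow(Xnew))
  for (j in seq_len(nrow(Xnew))) {
    d <- sqrt(rowSums((fit$X - matrix(Xnew[j, ], nrow(fit$X), ncol(fit$X), byrow = TRUE))^2))
    cross[, j] <- matern52(d, fit$ell)
  }
  mu <- fit$ym + fit$ys * drop(crossprod(cross, fit$alpha))
  v <- forwardsolve(t(fit$L), cross)
  var <- pmax(1 + fit$noise - colSums(v^2), 0) * fit$ys^2
  list(mu = mu, sd = sqrt(var))
}

#' Sequential model-based hyperparameter search
#'
#' Maximizes `objective` over the space: an initial Latin-hypercube design of
#' `n_initial` points, then `n_iterations` rounds of fitting the
#' Gaussian-process surrogate to all finite observations and evaluating the
#' point with the highest [expected_improvement()] among 1024 fresh
#' Latin-hypercube candidates. Objective errors (or non-finite returns) are
#' recorded as failed evaluations and the search continues. Deterministic
#' given the space's seed (and a deterministic objective).
#'
#' @param objective Function taking a named numeric vector (natural scale)
#'   and returning a scalar to maximize.
#' @param space A [hyper_space()].
#' @param n_candidates Candidate pool size per iteration.
#' @return An object of class `smbo_result`: `best_point` (named list),
#'   `best_value`, and `trace` (data frame: phase, the parameters, and the
#'   observed objective of every evaluation, in order).
#' @export
smbo_search <- function(objective, space = hyper_space(), n_candidates = 1024L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(space$seed)
  U <- lhs::randomLHS(space$n_initial, space$d)
  evaluate <- function(u) {
    x <- drop(space_from_unit(space, matrix(u, 1L)))
    val <- tryCatch(objective(x), error = function(e) NA_real_)
    if (!is.finite(val)) val <- NA_real_
    list(x = x, val = val)
  }
  X_unit <- matrix(numeric(0), 0L, space$d)
  X_nat <- matrix(numeric(0), 0L, space$d, dimnames = list(NULL, space$names))
  y <- numeric(0)
  phase <- character(0)
  for (i in seq_len(space$n_initial)) {
    r <- evaluate(U[i, ])
    X_unit <- rbind(X_unit, U[i, ])
    X_nat <- rbind(X_nat, r$x)
    y <- c(y, r$val)
    phase <- c(phase, "initial")
  }
  for (it in seq_len(space$n_iterations)) {
    ok <- is.finite(y)
    cand <- lhs::randomLHS(n_candidates, space$d)
    if (sum(ok) >= 2L && stats::sd(y[ok]) > 0) {
      fit <- gp_fit(X_unit[ok, , drop = FALSE], y[ok])
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mu, pr$sd, max(y[ok]))
      pick <- which.max(ei)
    } else {
      pick <- 1L # no usable surrogate yet: fall back to a random candidate
    }
    r <- evaluate(cand[pick, ])
    X_unit <- rbind(X_unit, cand[pick, ])
    X_nat <- rbind(X_nat, r$x)
    y <- c(y, r$val)
    phase <- c(phase, "smbo")
  }
  if (!any(is.finite(y))) {
    stop_mindcnn("every objective evaluation failed", "mindcnn_numeric_error")
  }
  best <- which.max(ifelse(is.finite(y), y, -Inf))
  trace <- data.frame(
    eval = seq_along(y), phase = phase,
    as.data.frame(X_nat), objective = y, check.names = FALSE
  )
  structure(
    list(
      best_point = as.list(X_nat[best, ]),
      best_value = y[best],
      trace = trace
    ),
    class = "smbo_result"
  )
}

#' @export
print.smbo_result <- function(x, ...) {
  cat(sprintf(
    "<smbo_result> %d evaluations, best objective %.6g at:\n",
    nrow(x$trace), x$best_value
  ))
  for (nm in names(x$best_point)) cat(sprintf("  %s = %.6g\n", nm, x$best_point[[nm]]))
  invisible(x)
}

#' Turn an SMBO best point into an optimizer configuration
#'
#' @param result An `smbo_result` whose searched parameters are among the
#'   [optimizer_config()] fields.
#' @param ... Overrides passed to [optimizer_config()].
#' @return An [optimizer_config()].
#' @export
as_optimizer_config <- function(result, ...) {
  args <- utils::modifyList(result$best_point, list(...))
  do.call(optimizer_config, args)
}
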