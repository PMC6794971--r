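test_that("expected improvement hits its closed-form anchors", {
  expect_equal(expected_improvement(1, 0, 1), 0) # no improvement possible
  expect_equal(expected_improvement(2, 1e-12, 1), 1, tolerance = 1e-9) # sure gain
  expect_equal(expected_improvement(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_error(expected_improvement(0, -1, 0))
})

test_that("closed-form EI agrees with Monte-Carlo within 3 standard errors", {
  set.seed(77)
  n_mc <- 1e6
  for (case in list(c(0, 1), c(0.5, 0.3), c(-0.5, 2), c(1.2, 0.05))) {
    mu <- case[1]
    sigma <- case[2]
    draws <- pmax(rnorm(n_mc, mu, sigma) - 0, 0) # f_star = 0
    mc <- mean(draws)
    se <- sd(draws) / sqrt(n_mc)
    expect_lt(abs(expected_improvement(mu, sigma, 0) - mc), 3 * se)
  }
})

test_that("SMBO locates a 1-D quadratic optimum and is reproducible", {
  space <- hyper_space(
    lower = c(x = 0), upper = c(x = 1), log = FALSE,
    n_initial = 6, n_iterations = 14, seed = 10
  )
  objective <- function(p) -(p[["x"]] - 0.3)^2
  res <- smbo_search(objective, space)
  expect_equal(nrow(res$trace), 20)
  expect_lt(abs(res$best_point$x - 0.3), 0.05)
  expect_equal(res$best_value, max(res$trace$objective, na.rm = TRUE))
  res2 <- smbo_search(objective, space)
  expect_identical(res$trace, res2$trace) # same seed -> same trace

  # no iterations: best of the initial design only
  space0 <- hyper_space(
    lower = c(x = 0), upper = c(x = 1), log = FALSE,
    n_initial = 5, n_iterations = 0, seed = 3
  )
  res0 <- smbo_search(objective, space0)
  expect_equal(nrow(res0$trace), 5)
  expect_true(all(res0$trace$phase == "initial"))
})

test_that("failing objective evaluations are recorded and skipped", {
  space <- hyper_space(
    lower = c(x = 0), upper = c(x = 1), log = FALSE,
    n_initial = 4, n_iterations = 6, seed = 2
  )
  objective <- function(p) if (p[["x"]] > 0.5) stop("boom") else p[["x"]]
  res <- smbo_search(objective, space)
  expect_equal(nrow(res$trace), 10)
  expect_true(anyNA(res$trace$objective))
  expect_lte(res$best_value, 0.5)
})

test_that("model-guided search beats random search on a smooth objective", {
  objective <- function(p) -((p[["a"]] - 0.3)^2 + (p[["b"]] - 0.7)^2)
  wins <- 0
  for (rep_i in 1:20) {
    space <- hyper_space(
      lower = c(a = 0, b = 0), upper = c(a = 1, b = 1),
      log = c(FALSE, FALSE), n_initial = 6, n_iterations = 10, seed = 100 + rep_i
    )
    smbo_best <- smbo_search(objective, space)$best_value
    set.seed(100 + rep_i)
    U <- lhs::randomLHS(16, 2)
    rand_best <- max(apply(U, 1, function(u) objective(c(a = u[1], b = u[2]))))
    if (smbo_best >= rand_best) wins <- wins + 1
  }
  expect_gte(wins, 16) # >= 80% of 20 repetitions
})

test_that("log-scaled dimensions map the unit cube multiplicatively", {
  space <- hyper_space(n_initial = 2, n_iterations = 0, seed = 1)
  pts <- mindcnn:::space_from_unit(space, matrix(c(0, 0.5, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 3))
  expect_equal(pts[, "learning_rate"], c(1e-5, 10^(-3.5), 1e-2))
  best <- structure(
    list(best_point = list(
      learning_rate = 0.002, beta_1 = 0.9,
      beta_2 = 0.9, decay = 1e-4
    )),
    class = "smbo_result"
  )
  cfg <- as_optimizer_config(best, name = "adam")
  expect_s3_class(cfg, "optimizer_config")
  expect_equal(cfg$learning_rate, 0.002)
})
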