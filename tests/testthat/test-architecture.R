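test_that("adaptive kernel rule reproduces every printed kernel length", {
  expect_equal(kernel_shape(4), c(2L, 1L))
  expect_equal(kernel_shape(3), c(2L, 1L))
  expect_equal(kernel_shape(15), c(8L, 1L))
  expect_equal(kernel_shape(2), c(1L, 1L))
  expect_error(kernel_shape(1), class = "mindcnn_domain_error")
})

test_that("full layer audit matches the published architecture table", {
  spec <- build_model()
  pars <- count_parameters(spec)
  get <- function(layer, ch) pars$parameters[pars$layer == layer & pars$channel == ch]
  # first convolution: 384 per 3/4-feature channel, 1152 for the accelerometer
  for (ch in c("ECG", "EMG", "RESP", "BVP")) expect_equal(get("conv1d_1", ch), 384)
  expect_equal(get("conv1d_1", "ACCL"), 1152)
  # second convolution
  for (ch in c("ECG", "EMG", "RESP", "BVP")) expect_equal(get("conv1d_2", ch), 16448)
  expect_equal(get("conv1d_2", "ACCL"), 65600)
  # dense layers
  expect_equal(get("dense_1", "ECG"), 8256)
  for (ch in c("EMG", "RESP", "BVP", "ACCL")) expect_equal(get("dense_1", ch), 4160)
  for (ch in names(spec$branches)) expect_equal(get("dense_2", ch), 2080)
  expect_equal(get("dense_trunk", "trunk"), 5152)
  expect_equal(get("dense_output", "trunk"), 165)
  expect_equal(get("concatenate", "trunk"), 0)

  shp <- forward_shapes(spec)
  expect_equal(shp$branches$ECG$conv1, c(3L, 128L))
  expect_equal(shp$branches$ECG$conv2, c(2L, 64L))
  expect_equal(shp$branches$ECG$flatten, 128L)
  expect_equal(shp$branches$EMG$conv1, c(2L, 128L))
  expect_equal(shp$branches$EMG$conv2, c(1L, 64L))
  expect_equal(shp$branches$ACCL$conv1, c(8L, 128L))
  expect_equal(shp$branches$ACCL$conv2, c(1L, 64L))
  expect_equal(shp$concat, 160L)
  expect_equal(shp$dense_trunk, 32L)
  expect_equal(shp$output, 5L)
})

test_that("single-channel degenerate build is valid with trunk width 32", {
  spec <- build_model(c(X = 4L))
  expect_equal(spec$concat_width, 32L)
  expect_equal(forward_shapes(spec)$output, 5L)
  expect_gt(attr(count_parameters(spec), "total"), 0)
})

test_that("valid-convolution geometry stays positive for any feature count", {
  # with k = ceiling(x/2), the second conv output is x - 2k + 2, i.e. 1 or 2
  for (x in 2:40) {
    spec <- build_model(stats::setNames(as.integer(x), "X"))
    expect_gte(spec$branches$X$L2, 1L)
    expect_lte(spec$branches$X$L2, 2L)
  }
})

test_that("parameter audit agrees with the actual initialized weight arrays", {
  spec <- build_model()
  set.seed(1)
  w <- mindcnn:::init_weights(spec)
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  expect_equal(count(w), attr(count_parameters(spec), "total"))
  for (ch in names(spec$branches)) {
    b <- w$branches[[ch]]
    pars <- count_parameters(spec)
    expect_equal(
      length(b$W1) + length(b$b1),
      pars$parameters[pars$layer == "conv1d_1" & pars$channel == ch]
    )
    expect_equal(
      length(b$W2) + length(b$b2),
      pars$parameters[pars$layer == "conv1d_2" & pars$channel == ch]
    )
  }
})

test_that("branches are isolated until concatenation and softmax is normalized", {
  spec <- build_model(dropout_rate = 0)
  set.seed(7)
  w <- mindcnn:::init_weights(spec)
  n <- 6
  blocks <- channel_blocks()
  X <- lapply(blocks, function(idx) matrix(rnorm(n * length(idx)), n))
  names(X) <- names(blocks)
  base <- mindcnn:::mcnn_forward(w, spec, X, return_branches = TRUE)
  X2 <- X
  X2$ECG <- X2$ECG + 10 # perturb one channel only
  pert <- mindcnn:::mcnn_forward(w, spec, X2, return_branches = TRUE)
  for (ch in c("EMG", "RESP", "BVP", "ACCL")) {
    expect_identical(base$branch_outputs[[ch]], pert$branch_outputs[[ch]])
  }
  expect_false(identical(base$branch_outputs$ECG, pert$branch_outputs$ECG))
  expect_equal(rowSums(base$probs), rep(1, n), tolerance = 1e-6)
  expect_true(all(base$probs >= 0))
})

test_that("audit table prints one row per layer/channel and serializes", {
  spec <- build_model()
  tab <- audit_table(spec)
  expect_equal(sum(tab$channel == "trunk"), 3)
  expect_equal(sum(tab$parameters), attr(count_parameters(spec), "total"))
  json <- spec_to_json(spec)
  expect_true(jsonlite::validate(json))
})
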