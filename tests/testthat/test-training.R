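test_that("randomized 70/20/10 split reproduces the published sample counts", {
  plan <- split_type1(880590, seed = 3)
  expect_length(plan$train, 616413)
  expect_length(plan$val, 176118)
  expect_length(plan$test, 88059)
  expect_equal(sort(c(plan$train, plan$val, plan$test)), 1:880590)

  small <- split_type1(10, seed = 1)
  expect_equal(lengths(small[c("train", "val", "test")]), c(train = 7L, val = 2L, test = 1L))

  again <- split_type1(880590, seed = 3)
  expect_identical(plan$train, again$train) # determinism
  different <- split_type1(880590, seed = 4)
  expect_false(identical(plan$train, different$train))
})

test_that("leave-one-subject-out split reproduces the published fold sizes", {
  # per-fold test-set sizes of the 15-subject cohort
  test_sizes <- c(
    59500, 62860, 62760, 60720, 68940, 50910, 53140, 50410,
    53430, 50810, 67420, 57640, 62450, 63110, 56490
  )
  expect_equal(sum(test_sizes), 880590)
  ids <- rep(paste0("Subject ", 1:15), times = test_sizes)
  plan <- split_type2(ids, "Subject 1", seed = 2)
  expect_length(plan$test, 59500)
  expect_length(plan$train, 656872)
  expect_length(plan$val, 164218)
  # spot-check two more folds
  p5 <- split_type2(ids, "Subject 5", seed = 2)
  expect_equal(lengths(p5[c("train", "val", "test")]),
    c(train = 649320L, val = 162330L, test = 68940L),
    ignore_attr = TRUE
  )
  p15 <- split_type2(ids, "Subject 15", seed = 2)
  expect_length(p15$train, 659280)
})

test_that("held-out subjects never leak into train or validation", {
  ds <- blob_dataset(200)
  for (s in unique(ds$subject_ids)) {
    plan <- split_type2(ds, s, seed = 8)
    expect_setequal(plan$test, which(ds$subject_ids == s))
    expect_length(intersect(plan$test, c(plan$train, plan$val)), 0)
    expect_setequal(c(plan$train, plan$val, plan$test), seq_along(ds$labels))
  }
  expect_error(split_type2(ds, "nobody"), class = "mindcnn_domain_error")
  expect_error(split_type2(rep("only", 50), "only"), class = "mindcnn_domain_error")
})

test_that("categorical cross-entropy matches hand values and the oracle", {
  perfect <- one_hot(c(0L, 3L), 5)
  expect_equal(categorical_cross_entropy(c(0L, 3L), perfect), 0)
  uniform <- matrix(0.2, 4, 5)
  expect_equal(categorical_cross_entropy(c(0L, 1L, 2L, 4L), uniform), log(5))
  # n = 2, predicted probability 0.5 and 0.25 at the true classes
  pred <- matrix(c(
    0.5, 0.2, 0.1, 0.1, 0.1,
    0.25, 0.25, 0.25, 0.25, 0
  ), 2, 5, byrow = TRUE)
  expect_equal(
    categorical_cross_entropy(c(0L, 3L), pred),
    (-log(0.5) - log(0.25)) / 2,
    tolerance = 1e-12
  )
  set.seed(31)
  n <- 400
  raw <- matrix(rexp(n * 5), n, 5)
  probs <- raw / rowSums(raw)
  labels <- sample(0:4, n, TRUE)
  expect_equal(
    categorical_cross_entropy(labels, probs),
    oracle_logloss(labels, probs),
    tolerance = 1e-10
  )
  # zero probability at a true class is clipped with a warning, not an error
  pz <- matrix(c(0, 1, 0, 0, 0), 1)
  expect_warning(v <- categorical_cross_entropy(0L, pz), "clipped")
  expect_equal(v, -log(1e-12))
  expect_error(
    categorical_cross_entropy(0L, matrix(0.3, 1, 5)),
    class = "mindcnn_domain_error"
  )
})

test_that("training is reproducible and a zero learning rate freezes the model", {
  ds <- blob_dataset(40, seed = 6)
  plan <- split_type1(nrow(ds$features), seed = 2)
  spec <- build_model()
  f1 <- train_model(spec, ds, plan, optimizer_config(), epochs = 2, seed = 5)
  f2 <- train_model(spec, ds, plan, optimizer_config(), epochs = 2, seed = 5)
  expect_identical(f1$history, f2$history) # bit-identical under one seed
  frozen <- train_model(spec, ds, plan,
    optimizer_config(learning_rate = 0),
    epochs = 3, seed = 5
  )
  expect_equal(length(unique(frozen$history$train_loss)), 1)
  expect_equal(length(unique(frozen$history$val_loss)), 1)
})

test_that("well-separated classes are learned to high held-out macro recall", {
  ds <- blob_dataset(600, seed = 3)
  plan <- split_type1(nrow(ds$features), seed = 5)
  fit <- train_model(build_model(), ds, plan, optimizer_config(), epochs = 20, seed = 5)
  expect_lt(fit$history$train_loss[20], fit$history$train_loss[1])
  pred <- predict(fit, ds$features[plan$test, , drop = FALSE], type = "class")
  rep <- classification_report(confusion_matrix(ds$labels[plan$test], pred))
  expect_gte(rep$macro$recall, 0.9)
})

test_that("optimizer comparison reuses the split and reports full blocks", {
  ds <- blob_dataset(60, seed = 9)
  plan <- split_type1(nrow(ds$features), seed = 4)
  cmp <- compare_optimizers(
    build_model(), ds, plan,
    list(optimizer_config("adam"), optimizer_config("sgd", learning_rate = 0.05)),
    seed = 4, epochs = 3
  )
  expect_equal(names(cmp$table), c("metric", "adam", "sgd"))
  expect_equal(nrow(cmp$table), 16) # accuracy + 5 classes x 3 metrics
  expect_true(all(is.finite(cmp$table$adam)))
  expect_true(all(is.finite(cmp$table$sgd)))
  single <- compare_optimizers(build_model(), ds, plan,
    list(optimizer_config("rmsprop")),
    seed = 4, epochs = 2
  )
  expect_equal(ncol(single$table), 2)
})
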