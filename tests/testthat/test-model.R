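test_that("weight initialization is deterministic under the seed", {
  a <- build_model(tiny_arch(), seed = 11L)
  b <- build_model(tiny_arch(), seed = 11L)
  expect_identical(a$params, b$params)
  c <- build_model(tiny_arch(), seed = 12L)
  expect_false(identical(a$params, c$params))
})

test_that("predictions are non-negative and batch-partition invariant", {
  arch <- tiny_arch()
  model <- build_model(arch, seed = 2L)
  batch <- random_batch(7, dims = arch$input_dims, nc = arch$in_channels,
                        seed = 3)
  p_all <- predict_ages(model, batch)
  expect_true(all(p_all >= 0))
  # one-at-a-time prediction must match the joint batch (eval-mode BN)
  p_single <- vapply(seq_len(7), function(i) {
    b1 <- structure(list(data = batch$data[i, , , , , drop = FALSE],
                         subject_ids = batch$subject_ids[i]),
                    class = "batch_tensor")
    unname(predict_ages(model, b1))
  }, 1)
  expect_equal(unname(p_all), p_single, tolerance = 1e-12)
  # a duplicated subject gets an identical prediction
  dup <- structure(list(data = batch$data[c(1, 1, 2), , , , , drop = FALSE],
                        subject_ids = c("A", "B", "C")),
                   class = "batch_tensor")
  pd <- predict_ages(model, dup)
  expect_identical(unname(pd["A"]), unname(pd["B"]))
})

test_that("learning rate zero leaves the weights unchanged", {
  arch <- tiny_arch()
  model <- build_model(arch, seed = 4L)
  batch <- random_batch(6, dims = arch$input_dims, nc = arch$in_channels)
  cfg <- train_config(learning_rate = 0, batch_size = 3L, max_epochs = 3L,
                      seed = 9L, init_output_bias = FALSE)
  res <- train_model(model, list(x = batch, ages = runif(6, 8, 80)),
                     cfg = cfg)
  expect_equal(res$model$params, model$params, tolerance = 0)
})

test_that("a single subject is memorized given enough steps", {
  arch <- arch_config(in_channels = 1L, input_dims = c(6L, 6L, 6L),
                      block_filters = 2L, fc_widths = 3L, dropout_rate = 0)
  model <- build_model(arch, seed = 6L)
  batch <- random_batch(1, dims = arch$input_dims, nc = 1, seed = 8)
  cfg <- train_config(learning_rate = 0.05, batch_size = 1L,
                      max_epochs = 120L, seed = 1L)
  res <- train_model(model, list(x = batch, ages = 37), cfg = cfg)
  expect_lt(min(res$log$train_mae), 1.0)
})

test_that("training is deterministic under the config seed", {
  arch <- tiny_arch(dropout = 0.3)
  batch <- random_batch(8, dims = arch$input_dims, nc = arch$in_channels)
  ages <- runif(8, 8, 80)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4L, max_epochs = 2L,
                      seed = 21L)
  r1 <- train_model(build_model(arch, 1L), list(x = batch, ages = ages),
                    cfg = cfg)
  r2 <- train_model(build_model(arch, 1L), list(x = batch, ages = ages),
                    cfg = cfg)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$log, r2$log)
})

test_that("overlapping train/validation ids and empty training sets error", {
  arch <- tiny_arch()
  model <- build_model(arch, seed = 1L)
  batch <- random_batch(6, dims = arch$input_dims, nc = arch$in_channels)
  expect_error(
    train_model(model, list(x = batch, ages = runif(6, 8, 80)),
                val = list(x = batch, ages = runif(6, 8, 80)),
                cfg = train_config(max_epochs = 1L)),
    "overlap")
  expect_error(
    train_model(model, list(x = structure(list(data = batch$data[0, , , , ,
                                                                 drop = FALSE],
                                               subject_ids = character(0)),
                                          class = "batch_tensor"),
                            ages = numeric(0)),
                cfg = train_config(max_epochs = 1L)),
    "empty")
})

test_that("gradients match finite differences through the full stack", {
  arch <- tiny_arch(dropout = 0)
  model <- build_model(arch, seed = 7L)
  set.seed(42)
  n <- 3L
  nvox <- prod(arch$input_dims)
  X <- matrix(rnorm(nvox * n * arch$in_channels), nvox * n, arch$in_channels)
  ages <- c(10, 40, 70)
  fw <- brainpad:::cnn_forward(model, X, n, train = TRUE,
                               update_running = FALSE)
  grads <- brainpad:::cnn_backward(model, fw$cache, (fw$pred - ages) / n)
  loss <- function(m) {
    f <- brainpad:::cnn_forward(m, X, n, train = TRUE, update_running = FALSE)
    mean((f$pred - ages)^2) / 2
  }
  eps <- 1e-6
  for (nm in names(model$params)) {
    pv <- model$params[[nm]]
    for (j in sample(length(pv), min(2, length(pv)))) {
      m2 <- model; m2$params[[nm]][j] <- pv[j] + eps
      m3 <- model; m3$params[[nm]][j] <- pv[j] - eps
      fd <- (loss(m2) - loss(m3)) / (2 * eps)
      expect_equal(grads[[nm]][j], fd, tolerance = 1e-4)
    }
  }
})

test_that("training loss trends downward on a noiseless age-coded input", {
  # each subject's channels are a fixed spatial pattern scaled by age: a
  # linearly decodable signal the optimizer should fit monotonically in the
  # long-run average
  arch <- arch_config(in_channels = 1L, input_dims = c(6L, 6L, 6L),
                      block_filters = c(2L, 3L), fc_widths = 4L,
                      dropout_rate = 0)
  set.seed(99)
  pattern <- array(abs(rnorm(216)), c(6, 6, 6))
  ages <- seq(10, 70, length.out = 12)
  data <- array(0, c(12, 1, 6, 6, 6))
  for (i in 1:12) data[i, 1, , , ] <- pattern * (ages[i] / 40)
  batch <- structure(list(data = data, subject_ids = sprintf("A%02d", 1:12)),
                     class = "batch_tensor")
  cfg <- train_config(learning_rate = 5e-3, batch_size = 4L,
                      max_epochs = 60L, seed = 2L)
  res <- train_model(build_model(arch, 3L), list(x = batch, ages = ages),
                     cfg = cfg)
  mae <- res$log$train_mae
  # clearly decreasing in the long-run average, allowing local wiggles
  expect_lt(mean(utils::tail(mae, 10)), 0.6 * mean(utils::head(mae, 5)))
  expect_lt(coef(lm(mae ~ seq_along(mae)))[2], 0)
})
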