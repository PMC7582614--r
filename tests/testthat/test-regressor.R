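test_that("split fractions produce exact sizes and reproducible parts", {
  d <- generate_feature_dataset(100, seed = 1)
  parts <- split_dataset(d$features, d$labels, seed = 5)
  expect_equal(nrow(parts$train$features), 70)
  expect_equal(nrow(parts$test$features), 20)
  expect_equal(nrow(parts$validation$features), 10)
  # disjoint and exhaustive
  all_idx <- c(parts$train$indices, parts$test$indices,
               parts$validation$indices)
  expect_setequal(all_idx, 1:100)
  parts2 <- split_dataset(d$features, d$labels, seed = 5)
  expect_identical(parts$train$indices, parts2$train$indices)
  all_train <- split_dataset(d$features, d$labels, c(1, 0, 0), seed = 5)
  expect_equal(nrow(all_train$train$features), 100)
  expect_equal(nrow(all_train$test$features), 0)
  expect_error(split_dataset(d$features[1:5, ], d$labels[1:5, ]), "10 rows")
})

test_that("forward pass follows the affine-plus-ReLU composition", {
  cfg <- regressor_config(input_dim = 2, hidden_widths = 1, max_epochs = 0,
                          seed = 1)
  fit <- train_regressor(cfg, list(features = matrix(rnorm(20), 10, 2),
                                   labels = matrix(rnorm(20), 10, 2)))
  net <- fit$network
  # hand-set weights: hidden unit h = relu(2 x1 - 1 x2 + 0.5), out = (3h+1, -h+2)
  net$W[[1]] <- matrix(c(2, -1), 2, 1)
  net$b[[1]] <- 0.5
  net$W[[2]] <- matrix(c(3, -1), 1, 2)
  net$b[[2]] <- c(1, 2)
  h <- max(2 * 0.7 - 1 * 0.2 + 0.5, 0)
  expect_equal(unname(mlp_forward(net, c(0.7, 0.2))[1, ]),
               c(3 * h + 1, -h + 2))
  # negative pre-activation contributes zero downstream
  h2 <- max(2 * (-1) - 1 * 0.5 + 0.5, 0)
  expect_equal(h2, 0)
  expect_equal(unname(mlp_forward(net, c(-1, 0.5))[1, ]), c(1, 2))
  # all-zero weights and biases give zero output
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  expect_equal(unname(mlp_forward(net, c(5, -3))[1, ]), c(0, 0))
  expect_error(mlp_forward(net, c(1, 2, 3)), "expects")
})

test_that("forward pass agrees with a loop-based oracle on random nets", {
  set.seed(303)
  for (trial in 1:25) {
    din <- sample(2:5, 1)
    widths <- sample(1:6, sample(1:3, 1), replace = TRUE)
    cfg <- regressor_config(input_dim = din, hidden_widths = widths,
                            max_epochs = 0, seed = trial)
    fit <- train_regressor(cfg, list(
      features = matrix(rnorm(20 * din), 20, din),
      labels = matrix(rnorm(40), 20, 2)))
    x <- rnorm(din)
    got <- mlp_forward(fit$network, x)[1, ]
    expect_equal(unname(got),
                 oracle_forward(fit$network$W, fit$network$b, x),
                 tolerance = 1e-6)
  }
})

test_that("zero training epochs return the initial network unchanged", {
  cfg <- regressor_config(input_dim = 4, hidden_widths = c(3, 3),
                          max_epochs = 0, seed = 9)
  d <- list(features = matrix(rnorm(40), 10, 4),
            labels = matrix(rnorm(20), 10, 2))
  f1 <- train_regressor(cfg, d)
  f2 <- train_regressor(cfg, d)
  expect_identical(f1$network$W, f2$network$W)
  expect_equal(f1$best_epoch, 0L)
  expect_equal(nrow(f1$history), 0)
})

test_that("training recovers a noiseless affine map at small scale", {
  d <- generate_feature_dataset(1000, label_noise_sd = 0, seed = 21)
  parts <- split_dataset(d$features, d$labels, seed = 22)
  cfg <- regressor_config(input_dim = 32, hidden_widths = c(16, 16),
                          batch_size = 128, max_epochs = 150, patience = 30,
                          seed = 23)
  fit <- train_regressor(cfg, parts$train, parts$validation)
  expect_lt(min(fit$history$val_rmse), 1.5)
  expect_true(all(c("train_rmse", "train_mae", "val_rmse", "val_mae")
                  %in% names(fit$history)))
  # training-set predictions hit the same floor
  expect_lt(bp_rmse(parts$train$labels[, 1],
                    predict(fit, parts$train$features)[, 1]), 2)
})

test_that("prediction is batch-invariant and permutation-equivariant", {
  d <- generate_feature_dataset(200, seed = 31)
  parts <- split_dataset(d$features, d$labels, seed = 31)
  cfg <- regressor_config(input_dim = 32, hidden_widths = c(8, 8),
                          max_epochs = 5, seed = 31)
  fit <- train_regressor(cfg, parts$train, parts$validation)
  X <- parts$test$features
  batch <- predict(fit, X)
  single <- predict(fit, X[3, ])
  expect_equal(single[1, ], batch[3, ], tolerance = 1e-12)
  perm <- c(5, 1, 4, 2, 3)
  expect_equal(predict(fit, X[perm, ]), batch[perm, ], tolerance = 1e-12)
  expect_equal(nrow(batch), nrow(X))
  expect_error(predict(fit, X[, 1:5]), "expects")
})

test_that("configuration validation rejects bad settings", {
  expect_error(regressor_config(hidden_widths = c(4, 0)), "positive")
  expect_error(regressor_config(split_fractions = c(0.5, 0.2, 0.1)), "sum")
  expect_error(regressor_config(activation = "tanh"), "ReLU")
  expect_error(regressor_config(optimizer = "sgd"), "Nadam")
  cfg <- regressor_config(input_dim = 4)
  expect_error(train_regressor(cfg, list(
    features = matrix(rnorm(40), 10, 4),
    labels = matrix(c(NA, rnorm(19)), 10, 2))), "NA")
})
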