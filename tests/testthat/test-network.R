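test_that("parameter counts follow the closed-form architecture formula", {
  # LSTM(4(DH + H^2 + H)) + dense(H_d * H + H_d) + out(k * H_d + k)
  cfg <- network_config("lstm", recurrent_units = 1, dense_units = 1,
                        n_classes = 2, dropout_rate = 0)
  m <- build_classifier(cfg, input_dim = 1, seed = 1)
  expect_equal(n_parameters(m), 4 * (1 + 1 + 1) + (1 + 1) + (2 + 2))

  cfg2 <- network_config("lstm", recurrent_units = 8, dense_units = 16,
                         n_classes = 3)
  m2 <- build_classifier(cfg2, input_dim = 5, seed = 1)
  expect_equal(n_parameters(m2),
               4 * (8 * 5 + 64 + 8) + (16 * 8 + 16) + (3 * 16 + 3))

  # bidirectional recurrent output is 2H wide
  cfg3 <- network_config("bilstm", recurrent_units = 128)
  m3 <- build_classifier(cfg3, input_dim = 20, seed = 1)
  expect_equal(ncol(m3$w1), 256)

  # same seed, identical initial weights
  a <- build_classifier(cfg2, input_dim = 5, seed = 99)
  b <- build_classifier(cfg2, input_dim = 5, seed = 99)
  expect_identical(a, b)
})

test_that("predictions are normalized, symmetric at init, and batch-invariant", {
  cfg <- network_config("icgn", recurrent_units = 4, dense_units = 4,
                        n_classes = 3)
  m <- build_classifier(cfg, input_dim = 2, seed = 3)
  X <- array(rnorm(5 * 6 * 2), dim = c(5, 6, 2))
  pr <- predict(m, X)
  expect_equal(rowSums(pr$probabilities), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pr$probabilities >= 0 & pr$probabilities <= 1))

  # zero-weight model with softmax head: exactly uniform probabilities
  mz <- m
  mz$w1[] <- 0; mz$b1[] <- 0; mz$w2[] <- 0; mz$b2[] <- 0
  przz <- predict(mz, X)
  expect_equal(przz$probabilities, matrix(1 / 3, 5, 3), tolerance = 1e-12)

  # single-sample prediction equals that row of the batch prediction
  one <- predict(m, X[2, , ])
  expect_equal(one$probabilities[1, ], pr$probabilities[2, ],
               tolerance = 1e-12)
})

test_that("training separates a linearly separable toy problem", {
  toy <- toy_sequences(n = 200, sd = 0.3, seed = 10)
  # independent sanity bound: logistic regression on window features
  expect_gte(logistic_window_oracle(toy, toy), 95)

  cfg <- network_config("icgn", recurrent_units = 6, dense_units = 8,
                        dropout_rate = 0.1, window_length = 10)
  m <- build_classifier(cfg, input_dim = 2, seed = 5)
  tc <- training_config(epochs = 30, batch_size = 32, seed = 5)
  fit <- train_classifier(m, toy, config = tc)
  expect_gte(utils::tail(fit$history$accuracy, 1), 95)
  expect_equal(nrow(fit$history), 30)

  # loss mostly non-increasing over epochs
  d <- diff(fit$history$loss)
  expect_gte(mean(d <= 1e-6), 0.8)
})

test_that("shuffled labels yield chance-level validation accuracy", {
  toy <- toy_sequences(n = 200, sd = 0.3, seed = 20)
  set.seed(1)
  shuffled <- list(x = toy$x, y = sample(toy$y))
  val <- toy_sequences(n = 100, sd = 0.3, seed = 21)
  cfg <- network_config("lstm", recurrent_units = 4, dense_units = 8,
                        dropout_rate = 0, window_length = 10)
  m <- build_classifier(cfg, input_dim = 2, seed = 6)
  fit <- train_classifier(m, shuffled, val = val,
                          config = training_config(epochs = 10, seed = 6))
  acc <- utils::tail(fit$history$val_accuracy, 1)
  expect_gte(acc, 40)
  expect_lte(acc, 60)
})

test_that("training is reproducible and inference is dropout-free", {
  toy <- toy_sequences(n = 60, sd = 0.5, seed = 30)
  cfg <- network_config("icgn", recurrent_units = 3, dense_units = 4,
                        dropout_rate = 0.3, window_length = 10)
  tc <- training_config(epochs = 3, seed = 17)
  f1 <- train_classifier(build_classifier(cfg, 2, seed = 17), toy,
                         config = tc)
  f2 <- train_classifier(build_classifier(cfg, 2, seed = 17), toy,
                         config = tc)
  expect_identical(f1$history, f2$history)
  # repeated prediction identical (no dropout at inference)
  p1 <- predict(f1$model, toy$x)
  p2 <- predict(f1$model, toy$x)
  expect_identical(p1, p2)

  # training errors
  expect_error(train_classifier(f1$model,
                                list(x = toy$x, y = toy$y + 5), config = tc),
               "labels")
  expect_error(train_classifier(f1$model,
                                list(x = array(0, c(0, 10, 2)),
                                     y = integer(0)), config = tc),
               "empty")
})

test_that("mean-squared-error loss also trains the softmax head", {
  toy <- toy_sequences(n = 120, sd = 0.3, seed = 40)
  cfg <- network_config("lstm", recurrent_units = 4, dense_units = 6,
                        dropout_rate = 0, window_length = 10)
  m <- build_classifier(cfg, input_dim = 2, seed = 8)
  tc <- training_config(epochs = 25, loss = "mean_squared_error", seed = 8)
  fit <- train_classifier(m, toy, config = tc)
  expect_gte(utils::tail(fit$history$accuracy, 1), 90)
})

test_that("hyperparameter sweep enumerates unique combinations", {
  toy <- toy_sequences(n = 60, sd = 0.4, seed = 50)
  val <- toy_sequences(n = 40, sd = 0.4, seed = 51)
  tab1 <- hyperparameter_sweep(list(learning_rate = 0.01), toy, val,
                               cell_kind = "lstm", epochs = 2, seed = 1)
  expect_equal(nrow(tab1), 1)

  tab <- hyperparameter_sweep(
    list(learning_rate = c(0.001, 0.01), dropout_rate = c(0.1, 0.2),
         batch_size = c(32, 32)),  # duplicates collapse
    toy, val, cell_kind = "lstm", epochs = 2, seed = 1)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$val_accuracy >= 0 & tab$val_accuracy <= 100))
  expect_error(hyperparameter_sweep(list(), toy, val), "empty")
  expect_error(hyperparameter_sweep(list(bogus = 1), toy, val), "unknown")
})
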