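PARAM_TABLE <- c(
  "LSTM" = 300609, "GRU" = 227265,
  "BiLSTM" = 732225, "BiGRU" = 552769,
  "SIMP BiLSTM" = 235073, "SIMP BiGRU" = 178113,
  "CNN-LSTM" = 3448513, "CNN-GRU" = 2605249,
  "CNN-BiLSTM" = 6959809, "CNN-BiGRU" = 5240513,
  "SIMP CNN-BiLSTM" = 3382977, "SIMP CNN-BiGRU" = 2556097
)

all_specs <- function() {
  out <- list()
  for (cell in c("lstm", "gru")) {
    for (cnn in c(FALSE, TRUE)) {
      out <- c(out, list(model_spec(cell, FALSE, cnn),
                         model_spec(cell, TRUE, cnn),
                         model_spec(cell, TRUE, cnn, simplified = TRUE)))
    }
  }
  out
}

test_that("every detector variant reports its benchmark parameter count", {
  for (spec in all_specs()) {
    mdl <- build_model(spec, seed = 1)
    expect_identical(count_parameters(mdl), as.integer(PARAM_TABLE[[spec$name]]),
                     label = spec$name)
  }
})

test_that("simplified bidirectional models are smaller than full ones", {
  expect_lt(PARAM_TABLE[["SIMP BiLSTM"]], PARAM_TABLE[["BiLSTM"]])
  expect_lt(PARAM_TABLE[["SIMP BiGRU"]], PARAM_TABLE[["BiGRU"]])
  expect_lt(PARAM_TABLE[["SIMP CNN-BiGRU"]], PARAM_TABLE[["CNN-BiGRU"]])
  m_full <- build_model(model_spec("gru", TRUE))
  m_simp <- build_model(model_spec("gru", TRUE, simplified = TRUE))
  expect_lt(count_parameters(m_simp), count_parameters(m_full))
})

test_that("invalid specifications are rejected", {
  expect_error(model_spec("gru", bidirectional = FALSE, simplified = TRUE),
               "bidirectional")
  mdl <- build_model(model_spec("gru"), input_dim = 193)
  expect_error(predict(mdl, matrix(0, 938, 100)), "193")
})

test_that("scores are sigmoid-bounded and lengths follow the model family", {
  X <- matrix(stats::runif(64 * 193), 64, 193)
  plain <- predict(build_model(model_spec("gru"), seed = 2), X)
  expect_equal(length(plain), 64L)
  expect_true(all(plain >= 0 & plain <= 1))
  cnn <- predict(build_model(model_spec("gru", cnn_front = TRUE), seed = 2), X)
  expect_equal(length(cnn), 32L)
  expect_true(all(cnn >= 0 & cnn <= 1))
})

test_that("initialization and training are seed-deterministic", {
  m1 <- build_model(model_spec("lstm"), seed = 5)
  m2 <- build_model(model_spec("lstm"), seed = 5)
  expect_identical(lungsed:::model_params(m1), lungsed:::model_params(m2))

  set.seed(8)
  X <- lapply(1:6, function(i) matrix(stats::rnorm(40 * 10), 40, 10))
  y <- lapply(1:6, function(i) rep(c(0L, 1L), each = 20))
  run <- function() {
    mdl <- build_model(model_spec("gru"), input_dim = 10, seed = 3)
    mdl <- train_model(mdl, X[1:4], y[1:4], X[5:6], y[5:6],
                       train_config(initial_lr = 1e-3, max_epochs = 3,
                                    batch_size = 2, seed = 3))
    attr(mdl, "history")$val_loss
  }
  expect_identical(run(), run())
})

test_that("training drives scores toward the target base rate", {
  set.seed(12)
  X <- lapply(1:8, function(i) matrix(stats::rnorm(30 * 8), 30, 8))
  y0 <- lapply(1:8, function(i) integer(30))
  mdl <- build_model(model_spec("gru"), input_dim = 8, seed = 4)
  mdl <- train_model(mdl, X[1:6], y0[1:6], X[7:8], y0[7:8],
                     train_config(initial_lr = 1e-2, max_epochs = 25,
                                  batch_size = 4, seed = 4))
  scores <- unlist(lapply(X[1:6], function(x) predict(mdl, x)))
  expect_lt(mean(scores), 0.1)
})

test_that("plateau decay and early stopping follow the configured patience", {
  set.seed(21)
  # train toward all-ones targets while validating against all-zeros: the
  # validation loss then worsens monotonically, so epoch 1 stays the best
  # and the schedule's behaviour is fully determined
  X <- lapply(1:6, function(i) matrix(stats::rnorm(20 * 5), 20, 5))
  y_tr <- lapply(1:4, function(i) rep(1L, 20))
  y_va <- lapply(1:2, function(i) integer(20))
  mdl <- build_model(model_spec("gru"), input_dim = 5, seed = 6)
  cfg <- train_config(initial_lr = 1e-2, lr_decay_factor = 0.2,
                      lr_patience_epochs = 2, early_stop_epochs = 5,
                      max_epochs = 100, batch_size = 4, seed = 6)
  mdl <- train_model(mdl, X[1:4], y_tr, X[5:6], y_va, cfg)
  h <- attr(mdl, "history")
  # the validation loss never improves after epoch 1, so training halts
  # after exactly early_stop_epochs further epochs
  expect_equal(nrow(h), 1 + 5)
  expect_true(all(diff(h$val_loss) > 0))
  # decay fires after every lr_patience non-improving epochs
  expect_equal(h$lr, 1e-2 * c(1, 1, 1, 0.2, 0.2, 0.04))
  # the best-validation weights (epoch 1) are restored
  scores <- unlist(lapply(X[5:6], function(x) predict(mdl, x)))
  restored_loss <- lungsed:::bce_loss(scores, unlist(y_va))
  expect_equal(restored_loss, h$val_loss[1], tolerance = 1e-12)
})

test_that("the empty training set is rejected", {
  mdl <- build_model(model_spec("gru"), input_dim = 5)
  expect_error(train_model(mdl, list(), list(), list(), list()), "empty")
})

test_that("grouped folds never split a group and balance sizes", {
  man <- data.frame(id = sprintf("r%02d", 1:20),
                    group = rep(sprintf("g%d", 1:10), each = 2))
  folds <- make_folds(man, k = 5, seed = 2)
  expect_setequal(unique(folds), 1:5)
  for (g in unique(man$group)) {
    expect_equal(length(unique(folds[man$group == g])), 1L, label = g)
  }
  expect_true(all(table(folds) == 4))
  expect_identical(folds, make_folds(man, k = 5, seed = 2))
  expect_false(identical(folds, make_folds(man, k = 5, seed = 3)))

  # exactly k groups: one group per fold
  man5 <- data.frame(id = letters[1:5], group = sprintf("g%d", 1:5))
  f5 <- make_folds(man5, k = 5, seed = 1)
  expect_setequal(f5, 1:5)

  expect_error(make_folds(data.frame(group = c("a", "b", "c")), k = 5),
               "insufficient groups")
})
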