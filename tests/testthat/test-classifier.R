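test_that("hyperparameters are validated against the design levels", {
  expect_s3_class(optimal_hyper_params(), "hyper_params")
  expect_error(hyper_params(hidden_units = 48), "design levels")
  expect_error(hyper_params(optimizer = "SGD"), "design levels")
  expect_silent(hyper_params(hidden_units = 48, allow_custom = TRUE))
  h <- optimal_hyper_params()
  expect_equal(h$activation, "LeakyReLU")
  expect_equal(h$overlap_ratio, 0.3)
  expect_equal(h$layers, 1L)
  expect_equal(h$optimizer, "Adam")
  expect_equal(h$hidden_units, 64L)
  expect_equal(h$learning_rate, 0.003)
  expect_equal(h$dropout, 0.5)
  expect_equal(h$batch_size, 7000L)
})

test_that("model shapes: concatenated recurrent output and 4-way logits", {
  h <- hyper_params(hidden_units = 64, layers = 1, dropout = 0,
                    allow_custom = TRUE)
  model <- build_model(h, n_features = 6, width = 5)
  # forward/backward concatenation doubles the recurrent width
  expect_equal(dim(model$params$dense_W1), c(128, 64))
  X <- array(rnorm(6 * 5 * 7), c(6, 5, 7))
  probs <- gaitfbf:::predict_probs(model$params, X, h)
  expect_equal(dim(probs), c(7, 4))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-12)
  expect_error(predict(model, array(0, c(5, 5, 2))), "dimensions")
})

test_that("analytic BPTT gradients agree with central finite differences", {
  ns <- asNamespace("gaitfbf")
  for (case in list(list(act = "tanh", L = 1L), list(act = "LeakyReLU", L = 2L))) {
    set.seed(42)
    F <- 3L; TT <- 4L; H <- 4L; B <- 3L; NC <- 4L
    params <- ns$init_params(F, H, case$L, NC)
    X <- array(rnorm(F * TT * B), c(F, TT, B))
    y <- ns$onehot(c(5L, 3L, 2L), NC)
    loss_fn <- function(p)
      ns$softmax_xent(ns$bilstm_forward(p, X, H, case$L, case$act)$probs, y)$loss
    fwd <- ns$bilstm_forward(params, X, H, case$L, case$act, keep_cache = TRUE)
    g <- ns$bilstm_backward(params, fwd,
                            ns$softmax_xent(fwd$probs, y)$dlogits,
                            H, case$L, case$act)
    eps <- 1e-6
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s[%d] (%s, %d layers)", nm, i,
                                     case$act, case$L))
      }
    }
  }
})

test_that("all three optimizers reduce the loss on a toy problem", {
  w <- toy_windows(n_per_class = 12, width = 4, n_features = 3)
  for (opt in c("Adam", "Nadam", "AdamW")) {
    h <- hyper_params(optimizer = opt, hidden_units = 8, layers = 1,
                      dropout = 0, learning_rate = 0.01, batch_size = 24,
                      epochs = 15, seed = 2, allow_custom = TRUE)
    model <- train_model(build_model(h, 3, 4), w)
    expect_lt(tail(model$history$train_loss, 1), model$history$train_loss[1])
  }
})

test_that("separable synthetic windows are overfit to high accuracy", {
  w <- toy_windows(n_per_class = 50, width = 6, n_features = 4)
  h <- hyper_params(hidden_units = 16, layers = 1, dropout = 0,
                    learning_rate = 0.01, batch_size = 40, epochs = 30,
                    seed = 3, allow_custom = TRUE)
  model <- train_model(build_model(h, 4, 6), w, split = 1.0)
  expect_gte(tail(model$history$train_acc, 1), 99)
})

test_that("the 6:4 split and seeded training are reproducible", {
  w <- toy_windows(n_per_class = 25, width = 4, n_features = 3)
  h <- hyper_params(hidden_units = 4, layers = 1, dropout = 0.3,
                    learning_rate = 0.003, batch_size = 20, epochs = 2,
                    seed = 11, allow_custom = TRUE)
  m1 <- train_model(build_model(h, 3, 4), w)
  expect_length(m1$split$train, 60)
  expect_length(m1$split$val, 40)
  m2 <- train_model(build_model(h, 3, 4), w)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("training refuses a split with a missing class", {
  w <- toy_windows(n_per_class = 10, width = 4, n_features = 3)
  w$labels[w$labels == 2L] <- 3L            # heel-off absent
  h <- hyper_params(hidden_units = 4, layers = 1, batch_size = 3000,
                    epochs = 1, seed = 1, allow_custom = TRUE)
  expect_error(train_model(build_model(h, 3, 4), w), "absent")
})

test_that("prediction length and label codes are as contracted", {
  w <- toy_windows(n_per_class = 10, width = 4, n_features = 3)
  h <- hyper_params(hidden_units = 4, layers = 1, dropout = 0, epochs = 2,
                    batch_size = 40, learning_rate = 0.003, seed = 5,
                    allow_custom = TRUE)
  model <- train_model(build_model(h, 3, 4), w)
  pred <- predict(model, w)
  expect_length(pred, length(w$labels))
  expect_true(all(pred %in% c(5L, 4L, 3L, 2L)))
})

test_that("evaluation matches hand counts and the identity case", {
  rep1 <- evaluate_predictions(pred = c(5, 4, 4, 3), truth = c(5, 5, 4, 3))
  expect_equal(unname(rep1$per_phase_accuracy[c("SW", "HS", "FC")]),
               c(50, 100, 100))
  expect_equal(rep1$total_accuracy, 75)
  expect_equal(rowSums(rep1$confusion), c(SW = 2, HS = 1, FC = 1, HO = 0))
  truth <- rep(c(5, 4, 3, 2), 5)
  rep2 <- evaluate_predictions(truth, truth)
  expect_equal(rep2$total_accuracy, 100)
  expect_equal(unname(rep2$per_phase_accuracy), rep(100, 4))
  expect_equal(sum(diag(rep2$confusion)) / sum(rep2$confusion) * 100,
               rep2$total_accuracy)
  expect_error(evaluate_predictions(c(5, 4), c(5)), "equal length")
  expect_error(evaluate_predictions(c(5, 7), c(5, 4)), "phase codes")
})

test_that("random prediction on balanced truth approaches 25%", {
  set.seed(123)
  n <- 1e5
  truth <- rep(c(5L, 4L, 3L, 2L), n / 4)
  pred <- sample(c(5L, 4L, 3L, 2L), n, replace = TRUE)
  rep3 <- evaluate_predictions(pred, truth)
  expect_equal(rep3$total_accuracy, 25, tolerance = 0.04)
})
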