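# Class weights, weighted loss, the learning-rate schedule and seeded
# reproducibility of the training loop.

test_that("inverse-frequency class weights follow N / (K * n_k)", {
  expect_equal(unname(compute_class_weights(c(10, 10, 10))), rep(1, 3))
  expect_equal(unname(compute_class_weights(c(100, 50))), c(0.75, 1.5))
  expect_equal(unname(compute_class_weights(c(10, 30, 60))),
               c(100 / 30, 100 / 90, 100 / 180), tolerance = 1e-12)
  expect_equal(unname(compute_class_weights(c(10, 30, 60))),
               c(3.333, 1.111, 0.556), tolerance = 1e-3)
  expect_error(compute_class_weights(c(a = 3, b = 0)), "b")
})

test_that("weighted cross-entropy matches its closed form", {
  expect_equal(weighted_cross_entropy(c(0, 1, 0), 2, c(2, 5, 1)), 0)
  expect_equal(weighted_cross_entropy(c(0.5, 0.5), 1, c(1, 1)), 0.6931,
               tolerance = 1e-4)
  probs <- c(0.2, 0.3, 0.5)
  expect_equal(weighted_cross_entropy(probs, 3),
               -log(0.5), tolerance = 1e-12)
  # all weights one reduces to the unweighted loss
  expect_equal(weighted_cross_entropy(probs, 1, c(1, 1, 1)),
               -log(probs[1]), tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(probs, 1, c(3, 1, 1)),
               -3 * log(probs[1]), tolerance = 1e-12)
  expect_error(weighted_cross_entropy(c(0.5, 0.6), 1), "sum to 1")
  expect_error(weighted_cross_entropy(c(0.5, 0.5), 3), "out of range")
})

tiny_split <- function(n_per = 3L, seed = 1L) {
  cubs <- random_cuboids(2L * n_per, t = 4L, h = 6L, w = 8L, seed = seed,
                         labels = rep(c("a", "b"), each = n_per))
  dataset_split(train = cubs, validation = cubs[c(1, n_per + 1)])
}

tiny_model <- function(K = 2L, lr = 0.05) {
  g <- graph_new()
  s <- shape_thwc(4L, 6L, 8L, 3L)
  x1 <- graph_add(g, "input", cfg = list(key = "rgb", shape = s))
  x2 <- graph_add(g, "input", cfg = list(key = "flow", shape = s))
  ad <- graph_add(g, "add", c(x1, x2))
  gp <- graph_add(g, "global_avg_pool", ad)
  d1 <- graph_add(g, "dense", gp, list(units = 8L))
  a1 <- graph_add(g, "leaky_relu", d1, list(alpha = 0.1))
  out <- graph_add(g, "dense", a1, list(units = K))
  structure(list(graph = g, output_id = out,
                 input_ids = list(rgb = x1, flow = x2), module_outputs = list(),
                 spec = list(n_classes = K, learning_rate = lr)),
            class = "hcn_model")
}

test_that("the learning rate halves on plateau and never increases", {
  split <- tiny_split()
  # min_delta so large that every epoch counts as a stall
  cfg <- training_config(epochs = 7L, batch_size = 4L, learning_rate = 1e-3,
                         plateau_patience = 2L, early_stop_patience = 100L,
                         min_delta = 100)
  fit <- train(tiny_model(), split, cfg, seed = 1L)
  lrs <- fit$history$lr
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(sapply(lrs, function(l) any(abs(l - 1e-3 * 0.5^(0:6)) < 1e-15))))
  # after two plateau events the rate is 0.001 * 0.5^2
  expect_equal(lrs[6], 1e-3 * 0.25)
  expect_equal(min(lrs), 1e-3 * 0.5^2)
})

test_that("training is reproducible given the seed", {
  split <- tiny_split()
  cfg <- training_config(epochs = 3L, batch_size = 4L, learning_rate = 0.05,
                         early_stop_patience = 50L)
  f1 <- train(tiny_model(), split, cfg, seed = 7L)
  f2 <- train(tiny_model(), split, cfg, seed = 7L)
  expect_identical(model_get_weights(f1$model), model_get_weights(f2$model))
  expect_identical(f1$history, f2$history)
  f3 <- train(tiny_model(), split, cfg, seed = 8L)
  expect_false(identical(model_get_weights(f1$model),
                         model_get_weights(f3$model)))
})

test_that("the restored checkpoint is the validation-loss minimizer", {
  split <- tiny_split(n_per = 4L)
  cfg <- training_config(epochs = 10L, batch_size = 4L, learning_rate = 0.08,
                         early_stop_patience = 50L, min_delta = 0)
  fit <- train(tiny_model(), split, cfg, seed = 2L)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  # fitted model reproduces the best epoch's validation loss
  probs <- predict_cuboids(fit, split$validation)
  y <- match(vapply(split$validation, function(cb) cb$label, character(1)),
             fit$classes)
  val_loss <- -mean(fit$class_weights[y] *
                      log(probs[cbind(seq_along(y), y)]))
  expect_equal(val_loss, fit$best_val_loss, tolerance = 1e-10)
})

test_that("weighted and unweighted losses agree when all weights are one", {
  split <- tiny_split()
  cfg1 <- training_config(epochs = 1L, batch_size = 4L, learning_rate = 0,
                          class_weights = FALSE, early_stop_patience = 10L)
  cfg2 <- training_config(epochs = 1L, batch_size = 4L, learning_rate = 0,
                          class_weights = c(1, 1), early_stop_patience = 10L)
  f1 <- train(tiny_model(), split, cfg1, seed = 3L)
  f2 <- train(tiny_model(), split, cfg2, seed = 3L)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
})

test_that("training rejects empty splits and foreign labels", {
  expect_error(train(tiny_model(), dataset_split(), training_config()),
               "empty training split")
  split <- tiny_split()
  expect_error(train(tiny_model(), split, training_config(), seed = 1L,
                     classes = c("x", "y")), "label outside")
})

test_that("an overfit run drives training accuracy to the target", {
  # 2-class desk problem, small model: memorization within a few epochs
  set.seed(30)
  cubs <- random_cuboids(16L, t = 4L, h = 6L, w = 8L, seed = 5L,
                         labels = rep(c("a", "b"), each = 8L))
  # make the classes separable: shift class b's mean
  for (i in 9:16) cubs[[i]]$data <- cubs[[i]]$data + 0.5
  split <- dataset_split(train = cubs)
  cfg <- training_config(epochs = 25L, batch_size = 4L, learning_rate = 0.1,
                         early_stop_patience = 50L, target_train_acc = 1)
  fit <- train(tiny_model(), split, cfg, seed = 6L)
  expect_gte(max(fit$history$train_acc), 0.95)
})
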