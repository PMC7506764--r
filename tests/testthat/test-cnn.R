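# CNN engine and repetition counting by binary classification.

toy_images <- function(n_per = 20, size = 48, seed = 9) {
  set.seed(seed)
  mk <- function(cls, n) lapply(seq_len(n), function(i) {
    img <- matrix(0, size, size)
    if (cls == 1) img[10:20, 10:40] <- 1 else img[30:40, 10:40] <- 1
    img + matrix(runif(size * size, 0, 0.2), size, size)
  })
  list(images = c(mk(1, n_per), mk(2, n_per)),
       y = factor(rep(c("BC", "TT"), each = n_per)))
}

test_that("the built network matches the 5-conv + 3-dense topology", {
  m <- build_cnn(cnn_config(input_size = 64, head = "multiclass",
                            n_classes = 11))
  expect_equal(m$n_trainable_layers, 8)
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "conv"), 5)
  expect_equal(sum(types == "dense"), 3)
  expect_equal(sum(types == "dropout"), 2)
  # binary head has a single output unit
  mb <- build_cnn(cnn_config(input_size = 64, head = "binary"))
  dense_layers <- Filter(function(l) l$type == "dense", mb$layers)
  expect_equal(dense_layers[[3]]$d_out, 1)
  # forward pass on a zero image: finite softmax summing to 1
  p <- predict(m, matrix(0, 64 * 64, 1), type = "prob")
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # incompatible input size names the first failing layer
  expect_error(build_cnn(cnn_config(input_size = 16)), "config error")
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  layers <- list(
    imurehab:::new_conv_layer(8, 1, 3, 3, 1, 1, "c1"),
    imurehab:::new_bn_layer(64, 3, "b1"),
    imurehab:::new_relu_layer(192, "r1"),
    imurehab:::new_pool_layer(8, 3, 3, 2, "p1"),
    imurehab:::new_dense_layer(27, 2, "d1")
  )
  x <- matrix(rnorm(64 * 4), 64, 4)
  y <- c(1L, 2L, 1L, 2L)
  loss_of <- function(ls) {
    fw <- imurehab:::nn_forward(ls, x, train = TRUE)
    imurehab:::head_loss(fw$out, y, "multiclass", "cce")$value
  }
  fw <- imurehab:::nn_forward(layers, x, train = TRUE, keep_cache = TRUE)
  hl <- imurehab:::head_loss(fw$out, y, "multiclass", "cce")
  grads <- imurehab:::nn_backward(layers, fw$caches, hl$grad, 4)
  h <- 1e-5
  for (li in c(1, 2, 5)) {
    for (nm in names(grads[[li]])) {
      g <- grads[[li]][[nm]]
      for (j in sample(length(g), min(5, length(g)))) {
        lp <- layers
        lp[[li]]$params[[nm]][j] <- lp[[li]]$params[[nm]][j] + h
        lm <- layers
        lm[[li]]$params[[nm]][j] <- lm[[li]]$params[[nm]][j] - h
        num <- (loss_of(lp) - loss_of(lm)) / (2 * h)
        expect_equal(g[j], num, tolerance = 1e-4,
                     info = paste(li, nm, j))
      }
    }
  }
})

test_that("a reduced CNN overfits a 2-class toy set deterministically", {
  toy <- toy_images()
  x <- imurehab:::images_to_batch(toy$images, 48)
  cfg <- cnn_config(input_size = 48, head = "multiclass", n_classes = 2,
                    width_multiplier = 0.125, learning_rate = 1e-3,
                    epochs = 10, batch_size = 8, seed = 3)
  out <- train_cnn(build_cnn(cfg), x, toy$y, x, toy$y)
  expect_gte(tail(out$history$train_accuracy, 1), 0.95)
  expect_equal(nrow(out$history), 10)
  # best epoch has the minimum validation loss
  expect_equal(out$best_epoch, which.min(out$history$val_loss))
  expect_lte(out$history$val_loss[out$best_epoch],
             min(out$history$val_loss) + 1e-12)
  # identical seed and config reproduce the run exactly
  out2 <- train_cnn(build_cnn(cfg), x, toy$y, x, toy$y)
  expect_equal(out$history, out2$history, tolerance = 1e-12)
  # sequence predictions equal elementwise single-image predictions
  seq_pred <- predict_sequence(out$model, toy$images[c(1, 21, 2)])
  single <- vapply(toy$images[c(1, 21, 2)], function(im)
    as.character(predict(out$model, list(im))), character(1))
  expect_equal(as.character(seq_pred), single)
  # empty and constant sequences
  expect_length(predict_sequence(out$model, list()), 0)
  same <- predict_sequence(out$model, toy$images[c(1, 1, 1)])
  expect_length(unique(as.character(same)), 1)
})

test_that("transition counting equals the runs-of-ones oracle", {
  expect_equal(count_reps_transitions(c(0, 1, 1, 0, 0, 1, 1, 0)), 2L)
  expect_equal(count_reps_transitions(rep(0, 20)), 0L)
  expect_equal(count_reps_transitions(c(1, 1, 0, 0)), 1L)
  expect_equal(count_reps_transitions(integer(0)), 0L)
  set.seed(12)
  for (i in 1:2000) {
    n <- sample(3:40, 1)
    labs <- c(0L, sample(0:1, n - 2, replace = TRUE), 0L)
    transitions <- sum(abs(diff(labs)))
    expect_equal(count_reps_transitions(labs), transitions / 2)
  }
})

test_that("the perfect-classifier limit recovers exact counts", {
  trials <- noiseless_trials()
  for (lab in names(trials)) {
    n <- count_reps_cnn(trials[[lab]]$recording, peak_labeller())
    expect_equal(n, trials[[lab]]$truth$n_reps, info = lab)
  }
  # recording shorter than one window: 0 with a warning
  short <- imu_recording("S1", "BC", "constrained", 64, (0:99) / 64,
                         matrix(0, 100, 3), matrix(0, 100, 3))
  expect_warning(n0 <- count_reps_cnn(short, peak_labeller()), "shorter")
  expect_equal(n0, 0L)
})
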