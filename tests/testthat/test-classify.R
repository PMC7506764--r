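# Grid-searched classifier harness and confusion-matrix evaluation.

two_blobs <- function(n_per = 30, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  list(x = x, y = factor(rep(c("BC", "TT"), each = n_per)))
}

test_that("default grids include the reference optima", {
  svm_grid <- default_grid("svm")
  expect_true(any(svm_grid$kernel == "rbf" & svm_grid$cost == 100 &
                    svm_grid$gamma == 0.01))
  expect_true(1 %in% default_grid("knn")$k)
  expect_true(10 %in% default_grid("rf")$n_estimators)
  expect_true(1 %in% default_grid("mlp")$alpha)
})

test_that("separable blobs reach CV accuracy 1 for some SVM cell", {
  d <- two_blobs()
  spec <- classifier_spec("svm", folds = 5, seed = 3)
  fit <- grid_search_train(d$x, d$y, spec)
  expect_equal(max(fit$cv_table$mean_accuracy), 1)
  expect_equal(as.character(predict(fit$model, d$x)), as.character(d$y))
})

test_that("1-NN memorizes its training set", {
  d <- two_blobs(n_per = 25, sep = 3, seed = 5)
  spec <- classifier_spec("knn", grid = data.frame(k = c(1, 3, 5)),
                          folds = 5, seed = 2)
  fit <- grid_search_train(d$x, d$y, spec)
  model1 <- imurehab:::fit_one("knn", d$x, d$y, list(k = 1), spec)
  expect_equal(mean(predict(model1, d$x) == d$y), 1)
})

test_that("rf and mlp train deterministically through the harness", {
  d <- two_blobs(n_per = 20, sep = 5, seed = 8)
  for (alg in c("rf", "mlp")) {
    spec <- classifier_spec(alg, folds = 4, seed = 6,
                            grid = default_grid(alg)[1:2, , drop = FALSE])
    f1 <- grid_search_train(d$x, d$y, spec)
    f2 <- grid_search_train(d$x, d$y, spec)
    expect_equal(f1$cv_table, f2$cv_table, info = alg)
    expect_gte(max(f1$cv_table$mean_accuracy), 0.9)
  }
})

test_that("a class with fewer samples than folds is a stratification error", {
  x <- matrix(rnorm(24), 12, 2)
  y <- factor(c(rep("BC", 9), rep("TT", 3)))
  expect_error(grid_search_train(x, y, classifier_spec("knn", folds = 5)),
               "stratification error")
})

test_that("evaluation metrics match direct substitution and the F1 oracle", {
  # perfect predictions
  y <- factor(rep(exercise_labels(), each = 3))
  rep_perfect <- evaluate(NULL, labels = y, predictions = y)
  expect_equal(rep_perfect$accuracy, 1)
  expect_true(all(rep_perfect$per_class$precision == 1))
  expect_true(all(rep_perfect$per_class$f1 == 1))

  # two-class toy with TP = 8, FP = 2, FN = 2 for class BC
  truth <- c(rep("BC", 10), rep("TT", 10))
  pred <- c(rep("BC", 8), "TT", "TT", "BC", "BC", rep("TT", 8))
  r <- evaluate(NULL, labels = truth, predictions = pred)
  bc <- r$per_class[r$per_class$class == "BC", ]
  expect_equal(bc$tp, 8L)
  expect_equal(bc$fp, 2L)
  expect_equal(bc$fn, 2L)
  expect_equal(bc$precision, 0.8)
  expect_equal(bc$recall, 0.8)
  expect_equal(bc$f1, 0.8)

  # F1 equals the harmonic-mean oracle on random label vectors
  set.seed(10)
  labs <- exercise_labels()[1:4]
  for (i in 1:100) {
    truth <- sample(labs, 60, replace = TRUE)
    pred <- sample(labs, 60, replace = TRUE)
    r <- suppressWarnings(evaluate(NULL, labels = truth, predictions = pred,
                                   levels = labs))
    for (j in seq_len(nrow(r$per_class))) {
      cls <- r$per_class$class[j]
      tp <- sum(truth == cls & pred == cls)
      fp <- sum(truth != cls & pred == cls)
      fn <- sum(truth == cls & pred != cls)
      p_o <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r_o <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f_o <- if (p_o + r_o == 0) 0 else 2 * p_o * r_o / (p_o + r_o)
      expect_equal(r$per_class$f1[j], f_o)
    }
    expect_equal(r$accuracy, mean(truth == pred))
  }
})

test_that("row-normalized confusion has unit rows and recall diagonal", {
  expect_equal(normalize_confusion(diag(5)), diag(5), ignore_attr = TRUE)
  set.seed(11)
  for (i in 1:100) {
    cm <- matrix(rpois(25, 4), 5, 5)
    cm[cm < 0] <- 0
    if (any(rowSums(cm) == 0)) cm <- cm + 1
    norm <- normalize_confusion(cm)
    expect_equal(rowSums(norm), rep(1, 5), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  truth <- sample(c("BC", "TT", "SQ"), 50, replace = TRUE)
  pred <- sample(c("BC", "TT", "SQ"), 50, replace = TRUE)
  r <- suppressWarnings(evaluate(NULL, labels = truth, predictions = pred))
  expect_equal(unname(diag(normalize_confusion(r))),
               r$per_class$recall)
  # zero-support row: zeros with warning
  cm0 <- rbind(c(3, 1), c(0, 0))
  expect_warning(n0 <- normalize_confusion(cm0), "zero-support")
  expect_equal(n0[2, ], c(0, 0), ignore_attr = TRUE)
})

test_that("model comparison selects by validation score with documented ties", {
  one <- data.frame(algorithm = "rf", window_length_s = 4, pca = FALSE,
                    train_accuracy = 1, validation_accuracy = 0.8,
                    test_accuracy = 0.75)
  expect_true(compare_models(one)$selected[1])
  two <- rbind(one, data.frame(algorithm = "svm", window_length_s = 2,
                               pca = TRUE, train_accuracy = 0.99,
                               validation_accuracy = 0.9,
                               test_accuracy = 0.88))
  ranked <- compare_models(two)
  expect_equal(ranked$algorithm[1], "svm")
  expect_true(ranked$selected[1])
  # tie on validation: svm > mlp > knn > rf
  tie <- data.frame(algorithm = c("rf", "mlp"), window_length_s = 4,
                    pca = FALSE, train_accuracy = 1,
                    validation_accuracy = 0.9, test_accuracy = 0.8)
  expect_equal(compare_models(tie)$algorithm[1], "mlp")
})
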