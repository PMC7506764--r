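# Supervised-ML comparison harness: grid-searched SVM / kNN / random forest /
# MLP with stratified 10-fold cross-validation, and confusion-matrix
# evaluation (per-class precision, recall, F1; macro averages).

#' Default hyperparameter grid for one algorithm
#'
#' The defaults cover the regions where such models are usually tuned for
#' windowed inertial features and include C = 100 / gamma = 0.01 with an RBF
#' kernel for the SVM, k = 1 for kNN, 10 trees for the random forest, and
#' regularization step alpha = 1 (on a log scale from 1e-5 to 1e3) for the MLP.
#'
#' @param algorithm one of `"svm"`, `"knn"`, `"rf"`, `"mlp"`.
#' @return data.frame of grid cells.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    svm = expand.grid(kernel = c("rbf", "linear"), cost = c(1, 10, 100),
                      gamma = c(0.01, 0.1), stringsAsFactors = FALSE),
    knn = data.frame(k = c(1, 3, 5, 7)),
    rf = data.frame(n_estimators = c(10, 50, 100)),
    mlp = data.frame(alpha = 10^c(-5, -3, -1, 0, 1, 3)),
    stop("unknown algorithm: ", algorithm)
  )
}

#' Specify a classifier and its search grid
#'
#' @param algorithm `"svm"`, `"knn"`, `"rf"` or `"mlp"`.
#' @param grid data.frame of hyperparameter combinations (default
#'   [default_grid()]).
#' @param folds number of stratified cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment and stochastic fits.
#' @param mlp_size hidden-layer width used by the MLP (nnet) fits.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("svm", "knn", "rf", "mlp"),
                            grid = NULL, folds = 10, seed = 1, mlp_size = 16) {
  algorithm <- match.arg(algorithm)
  grid <- grid %||% default_grid(algorithm)
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("grid must be non-empty")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(algorithm = algorithm, grid = grid, folds = as.integer(folds),
                 seed = as.integer(seed), mlp_size = as.integer(mlp_size)),
            class = "classifier_spec")
}

# Stratified fold ids: within each class, a seeded shuffle is dealt
# round-robin over folds so every fold sees every class.
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < folds) {
        stop("stratification error: class '", cls, "' has ", length(idx),
             " samples, fewer than ", folds, " folds")
      }
      fold_id[idx] <- (seq_along(idx) - 1L) %% folds + 1L
      fold_id[idx] <- fold_id[idx][sample.int(length(idx))]
    }
  })
  fold_id
}

# -- single-model fit/predict backends ---------------------------------------

fit_one <- function(algorithm, x, y, params, spec) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  fit <- switch(algorithm,
    svm = fit_svm_ovr(x, y, kernel = params$kernel, cost = params$cost,
                      gamma = params$gamma),
    knn = list(train_x = x, train_y = y, k = params$k),
    rf = with_seed(spec$seed, randomForest::randomForest(
      x = x, y = y, ntree = params$n_estimators)),
    mlp = with_seed(spec$seed, nnet::nnet(
      x = x, y = nnet::class.ind(y), size = spec$mlp_size,
      decay = params$alpha, softmax = TRUE, maxit = 200,
      MaxNWts = 100000, trace = FALSE))
  )
  structure(list(algorithm = algorithm, fit = fit, levels = levels(y),
                 params = params, seed = spec$seed),
            class = "rehab_classifier")
}

# One-vs-rest SVM: one binary margin per class, predicted class = largest
# decision value. e1071's native multiclass is one-vs-one, so the OvR scheme
# is assembled from binary machines; decision-value orientation is checked on
# the training data and flipped if needed.
fit_svm_ovr <- function(x, y, kernel, cost, gamma) {
  kern <- c(rbf = "radial", linear = "linear")[[as.character(kernel)]]
  classes <- levels(y)
  machines <- lapply(classes, function(cls) {
    yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x, yy, kernel = kern, cost = cost, gamma = gamma,
                    scale = TRUE, decision.values = TRUE)
    dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1]
    flip <- mean(dv[yy == "pos"]) < mean(dv[yy == "neg"])
    list(svm = m, flip = flip)
  })
  list(classes = classes, machines = machines)
}

predict_svm_ovr <- function(fit, x) {
  scores <- vapply(fit$machines, function(m) {
    dv <- attr(stats::predict(m$svm, x, decision.values = TRUE),
               "decision.values")[, 1]
    if (m$flip) -dv else dv
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' @export
predict.rehab_classifier <- function(object, newdata, ...) {
  x <- as.matrix(drop_label(newdata))
  pred <- switch(object$algorithm,
    svm = predict_svm_ovr(object$fit, x),
    knn = as.character(with_seed(object$seed, class::knn(
      object$fit$train_x, x, object$fit$train_y, k = object$fit$k))),
    rf = as.character(stats::predict(object$fit, x)),
    mlp = {
      p <- stats::predict(object$fit, x)
      colnames(p)[max.col(p, ties.method = "first")]
    }
  )
  factor(pred, levels = object$levels)
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Every grid cell is scored by mean held-out accuracy over seeded stratified
#' folds; the best cell (ties broken by grid order) is refit on all training
#' data. The SVM uses a one-vs-rest multiclass scheme. Deterministic for a
#' fixed seed.
#'
#' @param features feature matrix or data.frame (a `label` column is ignored).
#' @param labels class labels (coerced to factor).
#' @param spec a [classifier_spec()].
#' @return list with `model` (a `rehab_classifier`), `cv_table` (grid plus
#'   `mean_accuracy`) and `best` (the selected row index).
#' @export
grid_search_train <- function(features, labels, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(drop_label(features))
  if (!all(is.finite(x))) stop("feature matrix must be finite")
  y <- droplevels(factor(labels))
  fold_id <- stratified_folds(as.character(y), spec$folds, spec$seed)
  grid <- spec$grid
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fold_acc <- vapply(seq_len(spec$folds), function(f) {
      tr <- fold_id != f
      model <- fit_one(spec$algorithm, x[tr, , drop = FALSE], y[tr], params, spec)
      mean(stats::predict(model, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc[g] <- mean(fold_acc)
  }
  best <- which.max(acc)  # ties -> first (grid order)
  cv_table <- cbind(grid, mean_accuracy = acc)
  model <- fit_one(spec$algorithm, x, y, as.list(grid[best, , drop = FALSE]), spec)
  list(model = model, cv_table = cv_table, best = best)
}

#' Evaluate predictions into a confusion matrix and per-class metrics
#'
#' Builds the true-by-predicted count matrix over the label set and derives
#' per-class TP/FP/FN, precision TP/(TP+FP), recall TP/(TP+FN), and
#' F1 = 2PR/(P+R), plus overall accuracy (trace/total) and macro averages.
#' A class never predicted has precision defined as 0 (with a warning when it
#' has support); an undefined F1 (P + R = 0) is 0.
#'
#' @param model a fitted `rehab_classifier` (or any object with a `predict`
#'   method returning labels), or `NULL` if `predictions` are supplied.
#' @param features feature rows for prediction (ignored when `predictions`
#'   given).
#' @param labels true labels.
#' @param predictions optional precomputed predicted labels.
#' @param levels label universe for the confusion matrix (default: the 11
#'   exercise labels restricted to those present in truth or predictions).
#' @return an object of class `eval_report`: `confusion`, `per_class`
#'   (data.frame), `accuracy`, `macro` (precision/recall/f1).
#' @export
evaluate <- function(model, features = NULL, labels, predictions = NULL,
                     levels = NULL) {
  if (length(labels) == 0) stop("argument error: empty input")
  if (is.null(predictions)) {
    if (is.null(model)) stop("argument error: need a model or predictions")
    predictions <- stats::predict(model, features)
  }
  if (is.null(levels)) {
    levels <- intersect(exercise_labels(),
                        union(unique(as.character(labels)),
                              unique(as.character(predictions))))
  }
  truth <- factor(as.character(labels), levels = levels)
  pred <- factor(as.character(predictions), levels = levels)
  if (any(is.na(truth)) || any(is.na(pred))) {
    stop("labels outside the declared label set")
  }
  confusion <- table(truth = truth, predicted = pred)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  support <- rowSums(confusion)
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  if (any(tp + fp == 0 & support > 0)) {
    warning("class(es) never predicted; precision defined as 0: ",
            paste(levels[tp + fp == 0 & support > 0], collapse = ", "))
  }
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  structure(
    list(
      confusion = confusion,
      per_class = data.frame(class = levels, support = as.integer(support),
                             tp = as.integer(tp), fp = as.integer(fp),
                             fn = as.integer(fn), precision = precision,
                             recall = recall, f1 = f1, row.names = NULL),
      accuracy = sum(tp) / sum(confusion),
      macro = list(precision = mean(precision), recall = mean(recall),
                   f1 = mean(f1))
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Row-normalize a confusion matrix
#'
#' Each row (true class) is divided by its support so rows sum to 1 and the
#' diagonal equals per-class recall. Zero-support rows become all-zero rows
#' with a warning.
#'
#' @param report an `eval_report` or a raw confusion matrix (true x predicted).
#' @return matrix of row-normalized rates.
#' @export
normalize_confusion <- function(report) {
  cm <- if (inherits(report, "eval_report")) unclass(report$confusion) else
    as.matrix(report)
  rs <- rowSums(cm)
  if (any(rs == 0)) warning("zero-support row(s) normalized to zeros")
  out <- cm / ifelse(rs == 0, 1, rs)
  out[rs == 0, ] <- 0
  out
}

#' Rank model evaluations and select the best by validation score
#'
#' Builds a comparison grid over (algorithm, window length, PCA flag) with
#' train/validation/test accuracies and flags the row with the highest
#' validation accuracy. Ties are broken by the documented algorithm order
#' svm > mlp > knn > rf, then by grid order.
#'
#' @param results data.frame with columns `algorithm`, `window_length_s`,
#'   `pca`, `train_accuracy`, `validation_accuracy`, `test_accuracy` (the
#'   accuracy columns may also be `eval_report` objects in list columns).
#' @return the data.frame sorted by validation accuracy with a logical
#'   `selected` column.
#' @export
compare_models <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  for (col in c("train_accuracy", "validation_accuracy", "test_accuracy")) {
    if (col %in% names(results) && is.list(results[[col]])) {
      results[[col]] <- vapply(results[[col]],
                               function(r) r$accuracy, numeric(1))
    }
  }
  stopifnot("validation_accuracy" %in% names(results))
  alg_rank <- match(results$algorithm, c("svm", "mlp", "knn", "rf"))
  ord <- order(-results$validation_accuracy, alg_rank, seq_len(nrow(results)))
  results <- results[ord, , drop = FALSE]
  results$selected <- seq_len(nrow(results)) == 1
  rownames(results) <- NULL
  results
}
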