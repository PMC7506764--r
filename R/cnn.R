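# AlexNet-style CNN models for 11-class exercise recognition and binary
# Peak/NoPeak classification, plus the transition-halving repetition counter.

#' Configuration of an AlexNet-style CNN
#'
#' The topology is always 5 convolutional layers followed by 3 fully
#' connected layers, with batch normalization after every convolutional and
#' hidden dense layer, ReLU activations, and dropout (default 0.4) in the
#' fully connected layers. At `input_size = 227` and `width_multiplier = 1`
#' the layer widths and kernels are the canonical AlexNet values
#' (96/256/384/384/256 filters, 4096-unit dense layers); smaller inputs use
#' a 7x7 stride-2 stem with the same 5+3 topology and widths scaled by the
#' multiplier. The desk-scale default (64x64 input, multiplier 0.25) trains
#' in minutes on one CPU.
#'
#' @param input_size square input size in pixels (default 64; 227 gives the
#'   full-scale network).
#' @param head `"multiclass"` (softmax over `n_classes`) or `"binary"`
#'   (single sigmoid output).
#' @param n_classes number of classes for the multiclass head (default 11).
#' @param width_multiplier scale on all layer widths (default 0.25).
#' @param dropout dropout rate in the fully connected layers (default 0.4).
#' @param optimizer `"adam"`, `"sgd"` or `"rmsprop"`.
#' @param learning_rate step size, in the swept range `[1e-6, 1e-3]`.
#' @param loss `"cce"`, `"kld"` (multiclass) or `"bce"` (binary). With
#'   one-hot targets KLD and CCE coincide.
#' @param epochs training epochs (default 20).
#' @param batch_size mini-batch size (default 32).
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 64, head = c("multiclass", "binary"),
                       n_classes = 11, width_multiplier = 0.25,
                       dropout = 0.4, optimizer = c("adam", "sgd", "rmsprop"),
                       learning_rate = NULL, loss = NULL, epochs = 20,
                       batch_size = 32, seed = 1) {
  head <- match.arg(head)
  optimizer <- match.arg(optimizer)
  loss <- loss %||% if (head == "binary") "bce" else "kld"
  loss <- match.arg(loss, c("cce", "kld", "bce"))
  if (head == "binary" && loss != "bce") stop("binary head requires bce loss")
  if (head == "multiclass" && loss == "bce") stop("multiclass head requires cce or kld")
  learning_rate <- learning_rate %||% if (head == "binary") 1e-5 else 1e-4
  if (learning_rate < 1e-6 || learning_rate > 1e-3) {
    stop("learning_rate outside the swept range [1e-6, 1e-3]")
  }
  structure(list(input_size = as.integer(input_size), head = head,
                 n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier, dropout = dropout,
                 optimizer = optimizer, learning_rate = learning_rate,
                 loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an AlexNet-style CNN
#'
#' Assembles the 5-conv + 3-dense stack for the configured input size and
#' width multiplier, with seeded He-normal weight initialization. An input
#' size incompatible with the convolution/pooling chain is a config error
#' naming the first failing layer.
#'
#' @param config a [cnn_config()].
#' @return an object of class `imurehab_cnn` with elements `layers`,
#'   `config`, `n_params`, `n_trainable_layers`.
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  m <- config$width_multiplier
  widths <- pmax(4L, round(c(96, 256, 384, 384, 256) * m))
  fc_width <- max(8L, round(4096 * m))
  if (config$input_size >= 227) {
    kernels <- c(11, 5, 3, 3, 3)
    strides <- c(4, 1, 1, 1, 1)
  } else {
    kernels <- c(7, 5, 3, 3, 3)
    strides <- c(2, 1, 1, 1, 1)
  }
  pads <- c(0, 2, 1, 1, 1)
  pool_after <- c(1, 2, 5)
  n_out <- if (config$head == "binary") 1L else config$n_classes
  layers <- list()
  with_seed(config$seed, {
    h <- config$input_size
    cin <- 1L
    for (i in 1:5) {
      nm <- paste0("conv", i)
      l <- new_conv_layer(h, cin, widths[i], kernels[i], strides[i], pads[i], nm)
      layers[[length(layers) + 1L]] <- l
      h <- l$h_out
      cin <- widths[i]
      layers[[length(layers) + 1L]] <- new_bn_layer(h * h, cin, paste0("bn", i))
      layers[[length(layers) + 1L]] <- new_relu_layer(h * h * cin,
                                                      paste0("relu", i))
      if (i %in% pool_after) {
        pl <- new_pool_layer(h, cin, 3, 2, paste0("pool", i))
        layers[[length(layers) + 1L]] <- pl
        h <- pl$h_out
      }
    }
    d <- h * h * cin
    for (i in 1:2) {
      nm <- paste0("fc", i)
      layers[[length(layers) + 1L]] <- new_dense_layer(d, fc_width, nm)
      layers[[length(layers) + 1L]] <- new_bn_layer(1L, fc_width,
                                                    paste0("bn_fc", i))
      layers[[length(layers) + 1L]] <- new_relu_layer(fc_width,
                                                      paste0("relu_fc", i))
      layers[[length(layers) + 1L]] <- new_dropout_layer(fc_width,
                                                         config$dropout,
                                                         paste0("drop", i))
      d <- fc_width
    }
    layers[[length(layers) + 1L]] <- new_dense_layer(d, n_out, "fc3")
  })
  n_params <- sum(vapply(layers, function(l) {
    sum(vapply(l$params, length, integer(1)))
  }, numeric(1)))
  structure(list(layers = layers, config = config, n_params = n_params,
                 n_trainable_layers = sum(vapply(layers, function(l)
                   l$type %in% c("conv", "dense"), logical(1))),
                 levels = NULL),
            class = "imurehab_cnn")
}

#' @export
print.imurehab_cnn <- function(x, ...) {
  cat(sprintf("<imurehab_cnn> %s head, input %dx%d, %d trainable layers, %s parameters\n",
              x$config$head, x$config$input_size, x$config$input_size,
              x$n_trainable_layers, format(x$n_params, big.mark = ",")))
  invisible(x)
}

# Stack a list of square image matrices into the engine's D x B layout,
# area-average resizing to `size` when needed.
images_to_batch <- function(images, size) {
  if (length(images) == 0) return(matrix(numeric(0), size * size, 0))
  mats <- lapply(images, function(img) {
    img <- as.matrix(img)
    if (nrow(img) != size || ncol(img) != size) {
      ar <- area_average_operator(nrow(img), size)
      ac <- area_average_operator(ncol(img), size)
      img <- ar %*% img %*% t(ac)
    }
    as.vector(img)
  })
  do.call(cbind, mats)
}

#' Load an image-dataset manifest into memory
#'
#' Reads the PNGs listed in a [build_image_dataset()] manifest, resizes them
#' to the model input size, and returns the pixel batch plus both label sets.
#'
#' @param dir directory holding the image tree and manifest.
#' @param input_size model input size in pixels.
#' @param manifest optional manifest data.frame (default: read
#'   `manifest.csv` under `dir`).
#' @return list with `x` (D x N matrix), `label` (factor), `binary`
#'   (integer 0/1 vector), `manifest`.
#' @export
load_image_manifest <- function(dir, input_size, manifest = NULL) {
  manifest <- manifest %||% utils::read.csv(file.path(dir, "manifest.csv"),
                                            stringsAsFactors = FALSE)
  imgs <- lapply(file.path(dir, manifest$image), function(p) png::readPNG(p))
  list(x = images_to_batch(imgs, input_size),
       label = factor(manifest$label, levels = exercise_labels()),
       binary = as.integer(manifest$binary),
       manifest = manifest)
}

encode_targets <- function(model, y) {
  if (model$config$head == "binary") {
    y <- as.integer(y)
    stopifnot(all(y %in% c(0L, 1L)))
    list(y = y, levels = NULL)
  } else {
    f <- droplevels(factor(y))
    list(y = as.integer(f), levels = levels(f))
  }
}

model_eval <- function(model, x, y_enc, batch_size = 64) {
  n <- ncol(x)
  losses <- numeric(0)
  correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    fw <- nn_forward(model$layers, x[, sel, drop = FALSE], train = FALSE)
    hl <- head_loss(fw$out, y_enc[sel], model$config$head, model$config$loss)
    losses <- c(losses, hl$value * length(sel))
    pred <- if (model$config$head == "binary") as.integer(hl$prob >= 0.5) else
      max.col(t(hl$prob), ties.method = "first")
    correct <- correct + sum(pred == y_enc[sel])
  }
  list(loss = sum(losses) / n, accuracy = correct / n)
}

#' Train a CNN with validation-loss checkpointing
#'
#' Mini-batch training with seeded shuffling (shuffle and resize are the only
#' augmentations; shear/flip/rotation are deliberately excluded because the
#' images encode time series). After every epoch, training and validation
#' loss/accuracy are recorded and the weights achieving the minimum
#' validation loss so far are kept; the returned model carries those best
#' weights. Two runs with identical data, config and seed are identical.
#'
#' @param model an untrained [build_cnn()] model.
#' @param x_train,y_train training pixels (D x N, from [images_to_batch()] or
#'   [load_image_manifest()]) and labels (factor for multiclass, 0/1 for
#'   binary). Every class must be present.
#' @param x_val,y_val validation pixels and labels.
#' @param epochs,batch_size,seed override the corresponding config values.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation-loss weights), `history`
#'   (data.frame: epoch, train_loss, train_accuracy, val_loss,
#'   val_accuracy), `best_epoch`.
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      epochs = NULL, batch_size = NULL, seed = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "imurehab_cnn"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  seed <- seed %||% cfg$seed
  tr <- encode_targets(model, y_train)
  if (cfg$head == "multiclass") {
    if (length(tr$levels) < 2) stop("data error: need at least 2 classes")
    model$levels <- tr$levels
  }
  va <- encode_targets(model, y_val)
  if (cfg$head == "multiclass") {
    va$y <- as.integer(factor(as.character(y_val), levels = tr$levels))
    if (any(is.na(va$y))) stop("data error: validation labels outside training classes")
  }
  n <- ncol(x_train)
  if (cfg$head == "multiclass" && length(unique(tr$y)) < length(tr$levels)) {
    stop("data error: empty class in training data")
  }
  opt <- new_optimizer(cfg$optimizer, cfg$learning_rate)
  history <- data.frame()
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        sel <- perm[start:min(start + batch_size - 1, n)]
        xb <- x_train[, sel, drop = FALSE]
        fw <- nn_forward(model$layers, xb, train = TRUE, keep_cache = TRUE)
        hl <- head_loss(fw$out, tr$y[sel], cfg$head, cfg$loss)
        grads <- nn_backward(model$layers, fw$caches, hl$grad, length(sel))
        model$layers <- nn_update_running(model$layers, fw$caches)
        stepped <- optimizer_step(opt, model$layers, grads)
        opt <- stepped$opt
        model$layers <- stepped$layers
      }
      ev_tr <- model_eval(model, x_train, tr$y)
      ev_va <- model_eval(model, x_val, va$y)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ev_tr$loss, train_accuracy = ev_tr$accuracy,
        val_loss = ev_va$loss, val_accuracy = ev_va$accuracy))
      if (ev_va$loss < best$loss) {
        best <- list(loss = ev_va$loss, layers = model$layers, epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        ep, ev_tr$loss, ev_tr$accuracy, ev_va$loss,
                        ev_va$accuracy))
      }
    }
  })
  model$layers <- best$layers
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Predict labels for a batch of images
#'
#' @param object a trained `imurehab_cnn`.
#' @param images list of image matrices, or a D x B pixel matrix at the model
#'   input size.
#' @param type `"label"` (hard labels; 0.5 threshold for the binary head) or
#'   `"prob"`.
#' @param ... unused.
#' @return labels (factor / integer 0-1 vector) or probabilities.
#' @export
predict.imurehab_cnn <- function(object, images, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.list(images)) {
    images_to_batch(images, object$config$input_size)
  } else as.matrix(images)
  if (nrow(x) != object$config$input_size^2) {
    stop("shape error: pixel rows ", nrow(x), " do not match input size ",
         object$config$input_size)
  }
  if (ncol(x) == 0) {
    return(if (object$config$head == "binary") integer(0) else
      factor(character(), levels = object$levels))
  }
  out <- matrix(NA_real_, if (object$config$head == "binary") 1 else
    object$config$n_classes, ncol(x))
  for (start in seq(1, ncol(x), by = 64)) {
    sel <- start:min(start + 63, ncol(x))
    fw <- nn_forward(object$layers, x[, sel, drop = FALSE], train = FALSE)
    z <- fw$out
    out[, sel] <- if (object$config$head == "binary") 1 / (1 + exp(-z)) else
      softmax_cols(z)
  }
  if (type == "prob") return(out)
  if (object$config$head == "binary") {
    as.integer(out[1, ] >= 0.5)
  } else {
    lv <- object$levels %||% as.character(seq_len(nrow(out)))
    factor(lv[max.col(t(out), ties.method = "first")], levels = lv)
  }
}

#' Predict a label sequence for time-ordered images
#'
#' One hard label per image, order preserved; elementwise identical to
#' predicting each image alone (the network is applied image-by-image, with
#' batch statistics frozen).
#'
#' @param model a trained `imurehab_cnn` or a [peak_labeller()].
#' @param images time-ordered list of image matrices (may be empty). For a
#'   `peak_labeller`, time-ordered `imu_window` objects instead.
#' @return vector of labels in input order.
#' @export
predict_sequence <- function(model, images) {
  if (length(images) == 0) {
    return(if (inherits(model, "peak_labeller")) integer(0) else
      predict(model, list()))
  }
  if (inherits(model, "peak_labeller")) {
    vapply(images, function(w) as.integer(label_peak_window(w, model$channel)),
           integer(1))
  } else {
    predict(model, images)
  }
}

#' Analytic left-half Peak/NoPeak labeller
#'
#' The perfect-classifier limit of the binary CNN: labels each window
#' directly with [label_peak_window()] instead of a trained model. Used to
#' isolate the correctness of the transition counter from model quality.
#'
#' @param channel dominant channel name (e.g. `"acc_x"`); when `NULL` it is
#'   determined per recording via [dominant_axis()].
#' @return an object of class `peak_labeller`.
#' @export
peak_labeller <- function(channel = NULL) {
  structure(list(channel = channel), class = "peak_labeller")
}

#' Count repetitions from a binary Peak/NoPeak label sequence
#'
#' Counts maximal runs of label 1. On a sequence that starts and ends at 0
#' this equals half the number of 0-1 transitions; a leading or trailing
#' run of 1s also counts as one repetition (the boundary rule that makes the
#' transition-halving counter well defined for odd transition counts).
#'
#' @param labels vector of 0/1 labels.
#' @return integer repetition count (>= 0).
#' @export
count_reps_transitions <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(labels) == 0) return(0L)
  r <- rle(labels)
  as.integer(sum(r$values == 1L))
}

#' Count repetitions with the CNN (or perfect-labeller) pipeline
#'
#' Windows of `length_s` seconds at `stride_s` stride are rasterized and
#' classified Peak/NoPeak by a single binary model shared across all
#' exercise classes; repetitions are the transition-halved count of the
#' label sequence. Substituting [peak_labeller()] for the model bypasses the
#' network and labels windows analytically.
#'
#' @param rec an `imu_recording`.
#' @param model a trained binary `imurehab_cnn`, or a [peak_labeller()].
#' @param image_cfg an [image_config()] (used only for a CNN model).
#' @param length_s window length in seconds (default 4).
#' @param stride_s stride in seconds (default 0.5).
#' @return integer repetition count; 0 with a warning when the recording is
#'   shorter than one window.
#' @export
count_reps_cnn <- function(rec, model, image_cfg = image_config(),
                           length_s = 4, stride_s = 0.5) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length(rec$t) < round(length_s * rec$fs)) {
    warning("recording shorter than one window; repetition count is 0")
    return(0L)
  }
  wins <- sliding_windows(rec, length_s, stride_s)
  if (inherits(model, "peak_labeller")) {
    mdl <- model
    if (is.null(mdl$channel)) mdl$channel <- dominant_axis(rec)$channel
    labels <- predict_sequence(mdl, wins)
  } else {
    stopifnot(inherits(model, "imurehab_cnn"), model$config$head == "binary")
    images <- lapply(wins, window_to_image, config = image_cfg)
    labels <- predict_sequence(model, images)
  }
  count_reps_transitions(labels)
}
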