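# Compact CNN engine: convolution via im2col + BLAS GEMM, batch
# normalization, ReLU, max pooling, dropout, dense layers, softmax/sigmoid
# heads, and SGD/Adam/RMSprop optimizers. Activations are stored as D x B
# matrices, one column per image, with pixel layout (row, column, channel)
# in column-major order.
#
# The engine is deliberately small: it exists to train desk-scale
# AlexNet-style models reproducibly on one CPU, not to compete with a
# deep-learning framework.

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

# ---- convolution -----------------------------------------------------------

new_conv_layer <- function(h_in, c_in, c_out, k, stride, pad, name) {
  h_out <- floor((h_in + 2 * pad - k) / stride) + 1
  if (h_out < 1) stop("config error: ", name, ": input ", h_in,
                      " incompatible with kernel ", k, " stride ", stride)
  hp <- h_in + 2 * pad
  # index of each unpadded pixel inside the padded vector
  g <- expand.grid(h = seq_len(h_in), w = seq_len(h_in), c = seq_len(c_in))
  pad_idx <- (g$h + pad) + hp * (g$w + pad - 1) + hp * hp * (g$c - 1)
  # gather matrix: one column per output position, rows ordered (kh, kw, c)
  kk <- expand.grid(kh = seq_len(k), kw = seq_len(k), c = seq_len(c_in))
  oo <- expand.grid(oh = seq_len(h_out), ow = seq_len(h_out))
  p_n <- nrow(oo)
  kkc <- nrow(kk)
  base_h <- (oo$oh - 1) * stride  # top-left (0-based) of each patch
  base_w <- (oo$ow - 1) * stride
  idx <- matrix(0L, kkc, p_n)
  for (p in seq_len(p_n)) {
    idx[, p] <- (base_h[p] + kk$kh) + hp * (base_w[p] + kk$kw - 1) +
      hp * hp * (kk$c - 1)
  }
  idx_vec <- as.vector(idx)
  ug <- sort(unique(idx_vec))
  row_sel <- match(pad_idx, ug)
  list(type = "conv", name = name,
       h_in = h_in, c_in = c_in, h_out = h_out, c_out = c_out,
       k = k, stride = stride, pad = pad, kkc = kkc, p_n = p_n,
       pad_idx = pad_idx, idx_vec = idx_vec, row_sel = row_sel,
       d_in = h_in * h_in * c_in, d_out = h_out * h_out * c_out,
       hp = hp,
       params = list(W = he_init(c_out, kkc), b = numeric(c_out)))
}

forward_conv <- function(layer, x, cache) {
  b_n <- ncol(x)
  if (layer$pad > 0) {
    xp <- matrix(0, layer$hp^2 * layer$c_in, b_n)
    xp[layer$pad_idx, ] <- x
  } else {
    xp <- x
  }
  cols <- xp[layer$idx_vec, , drop = FALSE]
  dim(cols) <- c(layer$kkc, layer$p_n * b_n)
  out <- layer$params$W %*% cols + layer$params$b
  dim(out) <- c(layer$c_out, layer$p_n, b_n)
  out <- aperm(out, c(2, 1, 3))
  dim(out) <- c(layer$p_n * layer$c_out, b_n)
  if (cache) attr(out, "cache") <- cols
  out
}

backward_conv <- function(layer, d_out, cols, b_n) {
  dim(d_out) <- c(layer$p_n, layer$c_out, b_n)
  dm <- aperm(d_out, c(2, 1, 3))
  dim(dm) <- c(layer$c_out, layer$p_n * b_n)
  d_w <- dm %*% t(cols)
  d_b <- rowSums(dm)
  dcols <- crossprod(layer$params$W, dm)
  dim(dcols) <- c(layer$kkc * layer$p_n, b_n)
  dpad_u <- rowsum(dcols, group = layer$idx_vec)
  d_x <- matrix(0, layer$d_in, b_n)
  ok <- !is.na(layer$row_sel)
  d_x[ok, ] <- dpad_u[layer$row_sel[ok], , drop = FALSE]
  list(d_x = d_x, grads = list(W = d_w, b = d_b))
}

# ---- max pooling ------------------------------------------------------------

new_pool_layer <- function(h_in, c_in, k, stride, name) {
  h_out <- floor((h_in - k) / stride) + 1
  if (h_out < 1) stop("config error: ", name, ": input ", h_in,
                      " incompatible with pool ", k, " stride ", stride)
  oo <- expand.grid(oh = seq_len(h_out), ow = seq_len(h_out))
  kk <- expand.grid(kh = seq_len(k), kw = seq_len(k))
  idx <- matrix(0L, nrow(kk), nrow(oo))
  for (p in seq_len(nrow(oo))) {
    idx[, p] <- ((oo$oh[p] - 1) * stride + kk$kh) +
      h_in * ((oo$ow[p] - 1) * stride + kk$kw - 1)
  }
  list(type = "pool", name = name, h_in = h_in, c_in = c_in, h_out = h_out,
       c_out = c_in, k = k, stride = stride, idx = idx, p_n = nrow(oo),
       d_in = h_in * h_in * c_in, d_out = h_out * h_out * c_in,
       params = list())
}

forward_pool <- function(layer, x, cache) {
  b_n <- ncol(x)
  dim(x) <- c(layer$h_in^2, layer$c_in * b_n)
  cur <- x[layer$idx[1, ], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (j in 2:nrow(layer$idx)) {
    v <- x[layer$idx[j, ], , drop = FALSE]
    m <- v > cur
    cur[m] <- v[m]
    arg[m] <- j
  }
  out <- cur
  dim(out) <- c(layer$p_n * layer$c_in, b_n)
  if (cache) attr(out, "cache") <- arg
  out
}

backward_pool <- function(layer, d_out, arg, b_n) {
  dim(d_out) <- c(layer$p_n, layer$c_in * b_n)
  d_x <- matrix(0, layer$h_in^2, layer$c_in * b_n)
  for (j in seq_len(nrow(layer$idx))) {
    m <- arg == j
    if (any(m)) {
      contrib <- d_out * m
      d_x[layer$idx[j, ], ] <- d_x[layer$idx[j, ], , drop = FALSE] + contrib
    }
  }
  dim(d_x) <- c(layer$d_in, b_n)
  list(d_x = d_x, grads = list())
}

# ---- batch normalization ----------------------------------------------------

new_bn_layer <- function(p_n, c_n, name) {
  list(type = "bn", name = name, p_n = p_n, c_n = c_n,
       d_in = p_n * c_n, d_out = p_n * c_n,
       momentum = 0.9, eps = 1e-5,
       running_mean = numeric(c_n), running_var = rep(1, c_n),
       params = list(gamma = rep(1, c_n), beta = numeric(c_n)))
}

bn_to_cmat <- function(layer, x, b_n) {
  dim(x) <- c(layer$p_n, layer$c_n, b_n)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(layer$p_n * b_n, layer$c_n)
  x
}

bn_from_cmat <- function(layer, xm, b_n) {
  dim(xm) <- c(layer$p_n, b_n, layer$c_n)
  xm <- aperm(xm, c(1, 3, 2))
  dim(xm) <- c(layer$p_n * layer$c_n, b_n)
  xm
}

forward_bn <- function(layer, x, train, cache) {
  b_n <- ncol(x)
  xm <- bn_to_cmat(layer, x, b_n)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  invstd <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
               layer$params$beta, "+")
  out <- bn_from_cmat(layer, out, b_n)
  if (cache) {
    attr(out, "cache") <- list(xhat = xhat, invstd = invstd, mu = mu, va = va)
  }
  out
}

backward_bn <- function(layer, d_out, cache, b_n) {
  dy <- bn_to_cmat(layer, d_out, b_n)
  xhat <- cache$xhat
  n <- nrow(dy)
  d_gamma <- colSums(dy * xhat)
  d_beta <- colSums(dy)
  dxhat <- sweep(dy, 2, layer$params$gamma, "*")
  t1 <- sweep(dxhat * n, 2, colSums(dxhat), "-")
  t2 <- xhat * matrix(colSums(dxhat * xhat), n, ncol(dy), byrow = TRUE)
  d_x <- sweep(t1 - t2, 2, cache$invstd / n, "*")
  list(d_x = bn_from_cmat(layer, d_x, b_n),
       grads = list(gamma = d_gamma, beta = d_beta))
}

# ---- relu / dropout / dense -------------------------------------------------

new_relu_layer <- function(d, name) {
  list(type = "relu", name = name, d_in = d, d_out = d, params = list())
}

new_dropout_layer <- function(d, rate, name) {
  list(type = "dropout", name = name, d_in = d, d_out = d, rate = rate,
       params = list())
}

new_dense_layer <- function(d_in, d_out, name) {
  list(type = "dense", name = name, d_in = d_in, d_out = d_out,
       params = list(W = he_init(d_out, d_in), b = numeric(d_out)))
}

# ---- whole-network forward / backward --------------------------------------

nn_forward <- function(layers, x, train = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    out <- switch(l$type,
      conv = forward_conv(l, x, keep_cache),
      pool = forward_pool(l, x, keep_cache),
      bn = forward_bn(l, x, train, keep_cache),
      relu = {
        o <- pmax(x, 0)
        if (keep_cache) attr(o, "cache") <- x > 0
        o
      },
      dropout = {
        if (train) {
          mask <- matrix(stats::runif(length(x)) >= l$rate, nrow(x), ncol(x))
          o <- x * mask / (1 - l$rate)
          if (keep_cache) attr(o, "cache") <- mask
          o
        } else x
      },
      dense = {
        o <- l$params$W %*% x + l$params$b
        if (keep_cache) attr(o, "cache") <- x
        o
      },
      stop("unknown layer type ", l$type)
    )
    if (keep_cache) {
      caches[[i]] <- attr(out, "cache")
      attr(out, "cache") <- NULL
    }
    x <- out
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, d_out, b_n) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = backward_conv(l, d_out, caches[[i]], b_n),
      pool = backward_pool(l, d_out, caches[[i]], b_n),
      bn = backward_bn(l, d_out, caches[[i]], b_n),
      relu = list(d_x = d_out * caches[[i]], grads = list()),
      dropout = list(d_x = d_out * caches[[i]] / (1 - l$rate), grads = list()),
      dense = list(d_x = crossprod(l$params$W, d_out),
                   grads = list(W = d_out %*% t(caches[[i]]),
                                b = rowSums(d_out)))
    )
    grads[[i]] <- res$grads
    d_out <- res$d_x
  }
  grads
}

# Update batchnorm running statistics from one training batch's cache.
nn_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(caches[[i]])) {
      m <- layers[[i]]$momentum
      layers[[i]]$running_mean <- m * layers[[i]]$running_mean +
        (1 - m) * caches[[i]]$mu
      layers[[i]]$running_var <- m * layers[[i]]$running_var +
        (1 - m) * caches[[i]]$va
    }
  }
  layers
}

# ---- heads and losses -------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# loss value and gradient at the pre-activation of the final dense layer
head_loss <- function(z, y, head, loss) {
  b_n <- ncol(z)
  if (head == "binary") {
    p <- 1 / (1 + exp(-z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    value <- -mean(y * log(p) + (1 - y) * log(1 - p))
    grad <- matrix(p - y, 1, b_n) / b_n
    list(value = value, grad = grad, prob = as.vector(p))
  } else {
    p <- softmax_cols(z)
    onehot <- matrix(0, nrow(z), b_n)
    onehot[cbind(y, seq_len(b_n))] <- 1
    pc <- pmax(p[cbind(y, seq_len(b_n))], 1e-12)
    # with one-hot targets the KL divergence to the prediction equals the
    # cross-entropy (the target entropy term is zero)
    value <- -mean(log(pc))
    grad <- (p - onehot) / b_n
    list(value = value, grad = grad, prob = p)
  }
}

# ---- optimizers -------------------------------------------------------------

new_optimizer <- function(kind = c("adam", "sgd", "rmsprop"), lr) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, t = 0L, state = list()),
            class = "nn_optimizer")
}

optimizer_step <- function(opt, layers, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (length(g) == 0) next
    for (nm in names(g)) {
      key <- paste0(i, ".", nm)
      p <- layers[[i]]$params[[nm]]
      gr <- g[[nm]]
      st <- opt$state[[key]]
      if (opt$kind == "sgd") {
        v <- if (is.null(st)) 0 else st$v
        v <- 0.9 * v - opt$lr * gr
        p <- p + v
        opt$state[[key]] <- list(v = v)
      } else if (opt$kind == "rmsprop") {
        s <- if (is.null(st)) 0 else st$s
        s <- 0.9 * s + 0.1 * gr^2
        p <- p - opt$lr * gr / (sqrt(s) + 1e-8)
        opt$state[[key]] <- list(s = s)
      } else {
        m <- if (is.null(st)) 0 else st$m
        v <- if (is.null(st)) 0 else st$v
        m <- 0.9 * m + 0.1 * gr
        v <- 0.999 * v + 0.001 * gr^2
        mh <- m / (1 - 0.9^opt$t)
        vh <- v / (1 - 0.999^opt$t)
        p <- p - opt$lr * mh / (sqrt(vh) + 1e-8)
        opt$state[[key]] <- list(m = m, v = v)
      }
      layers[[i]]$params[[nm]] <- p
    }
  }
  list(opt = opt, layers = layers)
}
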