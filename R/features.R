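# Sliding-window segmentation, the 48-dimensional time/frequency feature
# extractor, and PCA retention at >99% accumulated variance.

#' Segment a recording into overlapping sliding windows
#'
#' Window and stride are converted to samples (`W = round(length_s * fs)`,
#' `S = round(stride_s * fs)`); the window count is
#' `floor((N - W) / S) + 1`. A 50% overlap corresponds to
#' `stride_s = length_s / 2`; the image pipeline default of 0.5 s stride on
#' 4 s windows yields 43 windows from a 25 s recording.
#'
#' @param rec an `imu_recording`.
#' @param length_s window length in seconds (> 0).
#' @param stride_s hop between window starts in seconds (> 0).
#' @return list of `imu_window` objects ordered by start index, each holding
#'   `samples` (W x 6 matrix), `start_index` (1-based sample offset),
#'   `length_s`, `fs`, `label` and `source`. A recording shorter than one
#'   window gives an empty list with a warning.
#' @export
sliding_windows <- function(rec, length_s, stride_s = length_s / 2) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length_s <= 0 || stride_s <= 0) stop("length_s and stride_s must be > 0")
  n <- length(rec$t)
  w <- round(length_s * rec$fs)
  s <- round(stride_s * rec$fs)
  if (s < 1) stop("stride_s shorter than one sample")
  if (n < w) {
    warning("recording shorter than one window; no windows produced")
    return(list())
  }
  k <- floor((n - w) / s) + 1
  chans <- recording_channels(rec)
  lapply(seq_len(k), function(i) {
    start <- (i - 1) * s + 1
    structure(
      list(samples = chans[start:(start + w - 1), , drop = FALSE],
           start_index = start, length_s = length_s, fs = rec$fs,
           label = rec$exercise_label,
           source = paste(rec$subject_id, rec$exercise_label, rec$session,
                          sep = "/")),
      class = "imu_window"
    )
  })
}

#' Shannon entropy of an equal-width amplitude histogram
#'
#' Bins span `[min(values), max(values)]` with `n_bins` equal-width bins;
#' entropy is `-sum(p * log2(p))` over the normalized bin occupancies, with
#' `0 * log(0)` taken as 0. A constant series occupies a single bin and has
#' entropy 0; values uniformly filling all bins give `log2(n_bins)` bits.
#'
#' @param values numeric vector (length >= 1).
#' @param n_bins number of histogram bins (default 16).
#' @return entropy in bits (>= 0).
#' @export
shannon_entropy <- function(values, n_bins = 16) {
  stopifnot(length(values) >= 1, n_bins >= 1)
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Spectral energy of a window (DC excluded)
#'
#' The mean is removed, and the energy is `sum(|X_k|^2) / W^2` over the
#' discrete Fourier coefficients, which by Parseval's theorem equals the
#' (population) time-domain variance of the window. The feature is therefore
#' offset-invariant: a constant series has energy 0 and a unit-amplitude
#' sinusoid with an integer number of cycles has energy 0.5.
#'
#' @param values numeric vector (length >= 2).
#' @return non-negative scalar.
#' @export
fft_energy <- function(values) {
  stopifnot(length(values) >= 2)
  x <- values - mean(values)
  xf <- stats::fft(x)
  sum(Mod(xf[-1])^2) / length(x)^2
}

# Pearson correlation with a zero-variance policy: any degenerate pair is 0.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Names of the 48 features in their frozen order
#'
#' Block order: min, max, mean, sd, rms, entropy, fft_energy — each over the
#' six channels acc_x..gyro_z — followed by the six within-sensor Pearson
#' correlations (acc xy, xz, yz; gyro xy, xz, yz). The order is frozen so
#' serialized feature tables and PCA models stay portable.
#'
#' @return character vector of length 48.
#' @export
feature_names <- function() {
  stats_blocks <- c("min", "max", "mean", "sd", "rms", "entropy", "energy")
  c(as.vector(outer(stats_blocks, CHANNELS, paste, sep = ".")),
    paste0("cor.", c("acc_xy", "acc_xz", "acc_yz",
                     "gyro_xy", "gyro_xz", "gyro_yz")))
}

#' Extract the 48-dimensional feature vector of one window
#'
#' Per channel: minimum, maximum, mean, standard deviation, RMS, histogram
#' entropy ([shannon_entropy()]) and spectral energy ([fft_energy()]); plus
#' the six within-sensor Pearson correlations. A zero-variance pair has
#' correlation defined as 0. Output order is [feature_names()].
#'
#' @param window an `imu_window` (or a W x 6 matrix in channel order).
#' @param n_bins histogram bins for the entropy feature.
#' @return named numeric vector of length 48, with the class label (if known)
#'   attached as attribute `"label"`.
#' @export
extract_features <- function(window, n_bins = 16) {
  m <- if (inherits(window, "imu_window")) window$samples else as.matrix(window)
  stopifnot(ncol(m) == 6, nrow(m) >= 2)
  per_channel <- vapply(seq_len(6), function(j) {
    x <- m[, j]
    c(min(x), max(x), mean(x), stats::sd(x), sqrt(mean(x^2)),
      shannon_entropy(x, n_bins), fft_energy(x))
  }, numeric(7))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  cors <- vapply(pairs, function(p) safe_cor(m[, p[1]], m[, p[2]]), numeric(1))
  fv <- c(as.vector(per_channel), cors)
  names(fv) <- feature_names()
  if (inherits(window, "imu_window")) attr(fv, "label") <- window$label
  fv
}

#' Featurize a set of recordings into a labelled feature table
#'
#' @param recordings list of `imu_recording` objects.
#' @param length_s sliding window length in seconds.
#' @param stride_s stride in seconds (default 50% overlap).
#' @return data.frame with the 48 feature columns plus a `label` factor over
#'   the 11 classes.
#' @export
featurize_recordings <- function(recordings, length_s, stride_s = length_s / 2) {
  rows <- list()
  labels <- character()
  for (rec in recordings) {
    wins <- sliding_windows(rec, length_s, stride_s)
    for (w in wins) {
      rows[[length(rows) + 1L]] <- extract_features(w)
      labels <- c(labels, rec$exercise_label)
    }
  }
  if (length(rows) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 48,
                                dimnames = list(NULL, feature_names())))
    out$label <- factor(character(), levels = exercise_labels())
    return(out)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- factor(labels, levels = exercise_labels())
  out
}

#' Featurize every recording indexed by a dataset split
#'
#' @param split a `dataset_split` from [scan_dataset()].
#' @inheritParams featurize_recordings
#' @return labelled feature data.frame as in [featurize_recordings()].
#' @export
featurize_split <- function(split, length_s, stride_s = length_s / 2) {
  stopifnot(inherits(split, "dataset_split"))
  recs <- lapply(split$index$path, read_recording)
  featurize_recordings(recs, length_s, stride_s)
}

#' Fit a PCA model retaining components above an accumulated-variance threshold
#'
#' Features are standardized by their training mean and standard deviation
#' (zero-variance columns get scale 1 with a warning), decomposed by SVD, and
#' the smallest number of leading components whose accumulated explained-
#' variance fraction exceeds `variance_threshold` is retained. If no prefix
#' exceeds the threshold (e.g. threshold 1), all non-degenerate components —
#' the rank of the standardized matrix — are retained.
#'
#' @param x numeric matrix or data.frame of feature rows (a `label` column is
#'   dropped if present); >= 2 rows.
#' @param variance_threshold accumulated-variance cut (default 0.99).
#' @return an object of class `imu_pca`: `center`, `scale`, `rotation`,
#'   `var_fraction`, `n_retained`, `threshold`.
#' @export
fit_pca <- function(x, variance_threshold = 0.99) {
  x <- as.matrix(drop_label(x))
  stopifnot(nrow(x) >= 2)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature column(s); scale set to 1")
    scl[zero] <- 1
  }
  xs <- scale(x, center = ctr, scale = scl)
  sv <- svd(xs)
  ev <- sv$d^2
  tol <- max(ev) * max(dim(xs)) * .Machine$double.eps
  rank <- sum(ev > tol)
  vf <- ev / sum(ev)
  cum <- cumsum(vf)
  above <- which(cum > variance_threshold)
  n_retained <- if (length(above) > 0) min(above) else rank
  n_retained <- min(n_retained, rank)
  structure(
    list(center = ctr, scale = scl, rotation = sv$v,
         var_fraction = vf, n_retained = as.integer(n_retained),
         threshold = variance_threshold),
    class = "imu_pca"
  )
}

drop_label <- function(x) {
  if (is.data.frame(x) && "label" %in% names(x)) x[names(x) != "label"] else x
}

#' Project feature rows onto the retained principal components
#'
#' Uses the training mean/scale and loadings only, so validation and test
#' rows are transformed without leakage.
#'
#' @param model an `imu_pca` from [fit_pca()].
#' @param x feature matrix or data.frame with the same columns the model was
#'   fitted on.
#' @return matrix with `n_retained` columns of principal-component scores.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "imu_pca"))
  x <- as.matrix(drop_label(x))
  if (ncol(x) != length(model$center)) {
    stop("shape error: expected ", length(model$center), " feature columns, got ",
         ncol(x))
  }
  xs <- scale(x, center = model$center, scale = model$scale)
  xs %*% model$rotation[, seq_len(model$n_retained), drop = FALSE]
}

#' @export
print.imu_pca <- function(x, ...) {
  cat(sprintf(
    "<imu_pca> %d/%d components retained (accumulated variance %.4f > %.2f)\n",
    x$n_retained, length(x$var_fraction),
    sum(x$var_fraction[seq_len(x$n_retained)]), x$threshold))
  invisible(x)
}
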