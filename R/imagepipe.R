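# Deterministic rasterization of six-channel windows into fixed-size
# grayscale images, and the left-half Peak/NoPeak binary labelling used by
# the CNN repetition counter.

#' Configuration of the signal-image rasterizer
#'
#' Six traces are drawn into one square canvas with fixed per-sensor vertical
#' limits (by default the calibration ranges, +/- 16 g and +/- 2000 deg/s) so
#' amplitude information is preserved across windows; per-window autoscaling
#' is deliberately not performed. Rendering is a pure function of the window
#' and the config: no plotting device, no anti-aliasing. Optional
#' downsampling is by exact area averaging.
#'
#' @param native_size square canvas size in pixels (default 576).
#' @param target_size output size after area-average downsampling (default
#'   227; `NULL` keeps the native canvas).
#' @param acc_limit_g vertical half-range for accelerometer traces (g).
#' @param gyro_limit_dps vertical half-range for gyroscope traces (deg/s).
#' @return an object of class `image_config`.
#' @export
image_config <- function(native_size = 576, target_size = 227,
                         acc_limit_g = ACC_RANGE_G,
                         gyro_limit_dps = GYRO_RANGE_DPS) {
  stopifnot(native_size >= 8, is.null(target_size) || target_size >= 4)
  structure(list(native_size = as.integer(native_size),
                 target_size = if (is.null(target_size)) NULL else
                   as.integer(target_size),
                 acc_limit_g = acc_limit_g, gyro_limit_dps = gyro_limit_dps),
            class = "image_config")
}

# Exact area-average 1D operator from `from` pixels to `to` pixels;
# deterministic for any integer pair.
area_average_operator <- function(from, to) {
  a <- matrix(0, to, from)
  ratio <- from / to
  for (i in seq_len(to)) {
    lo <- (i - 1) * ratio
    hi <- i * ratio
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, from)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) a[i, j] <- overlap / ratio
    }
  }
  a
}

# Draw one polyline (values in [-1, 1], left to right) into the canvas with
# value 1; vertical spans connect adjacent columns so the trace is unbroken.
draw_trace <- function(canvas, y_norm) {
  n <- nrow(canvas)
  w <- length(y_norm)
  y_norm <- pmin(pmax(y_norm, -1), 1)
  xs <- if (w == 1) 1 else seq(1, n, length.out = w)
  rows_at_col <- stats::approx(xs, y_norm, xout = seq_len(n), rule = 2)$y
  r <- round((1 - (rows_at_col + 1) / 2) * (n - 1)) + 1
  nxt <- c(r[-1], r[n])
  lo <- pmin(r, nxt)
  hi <- pmax(r, nxt)
  lens <- hi - lo + 1
  rows <- sequence(lens, from = lo)
  cols <- rep(seq_len(n), times = lens)
  canvas[cbind(rows, cols)] <- 1
  canvas
}

#' Rasterize a six-channel window into a grayscale image
#'
#' All six traces are overlaid on one canvas (trace = 1 on background 0),
#' accelerometer channels scaled by `acc_limit_g` and gyroscope channels by
#' `gyro_limit_dps`. Output is bit-identical for identical input and config.
#'
#' @param window an `imu_window` (or W x 6 matrix in channel order).
#' @param config an [image_config()].
#' @return numeric matrix in `[0, 1]`, `target_size` square (or `native_size`
#'   when no downsampling is configured).
#' @export
window_to_image <- function(window, config = image_config()) {
  m <- if (inherits(window, "imu_window")) window$samples else as.matrix(window)
  stopifnot(ncol(m) == 6, nrow(m) >= 2)
  if (any(!is.finite(m))) stop("validation error: non-finite sample in window")
  n <- config$native_size
  canvas <- matrix(0, n, n)
  lims <- c(rep(config$acc_limit_g, 3), rep(config$gyro_limit_dps, 3))
  for (j in 1:6) {
    canvas <- draw_trace(canvas, m[, j] / lims[j])
  }
  if (!is.null(config$target_size) && config$target_size != n) {
    a <- area_average_operator(n, config$target_size)
    canvas <- a %*% canvas %*% t(a)
  }
  canvas
}

#' Binary Peak/NoPeak label of a window
#'
#' The window's dominant-axis segment is Savitzky-Golay smoothed, its global
#' extremum located as the sample with the largest absolute deviation from
#' the segment median, and the window labelled 1 ("Peak") when that extremum
#' falls strictly in the left half of the window's time span, 0 ("NoPeak")
#' otherwise (an extremum exactly at the midpoint is NoPeak). A constant
#' segment is labelled 0 with attribute `degenerate`.
#'
#' @param window an `imu_window`.
#' @param dominant_channel channel name (e.g. `"acc_x"`), typically from
#'   [dominant_axis()] on the source recording.
#' @return integer 0 or 1.
#' @export
label_peak_window <- function(window, dominant_channel) {
  m <- if (inherits(window, "imu_window")) window$samples else as.matrix(window)
  stopifnot(dominant_channel %in% CHANNELS)
  x <- m[, dominant_channel]
  w <- length(x)
  if (max(x) == min(x)) {
    out <- 0L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fs <- if (inherits(window, "imu_window")) window$fs else w / 4
  xs <- suppressWarnings(smooth_signal(x, peak_config(fs = fs)))
  dev <- abs(xs - stats::median(xs))
  peak_i <- which.max(dev)
  as.integer((peak_i - 1) < w / 2)
}

#' Build an image dataset with multiclass and binary labels
#'
#' For every recording of a split: windows of `length_s` at `stride_s` are
#' rasterized and written as grayscale PNGs under per-class folders, and a
#' manifest records the image path, the multiclass label, the binary
#' Peak/NoPeak label (computed on the recording's dominant axis), the source
#' recording and the window start index. Unreadable recordings are skipped
#' with a warning.
#'
#' @param split a `dataset_split` from [scan_dataset()].
#' @param out_dir output directory for the image tree and `manifest.csv`.
#' @param config an [image_config()].
#' @param length_s window length in seconds (default 4).
#' @param stride_s stride in seconds (default 0.5, which yields 43 images per
#'   25 s of signal).
#' @return the manifest as a data.frame, invisibly.
#' @export
build_image_dataset <- function(split, out_dir, config = image_config(),
                                length_s = 4, stride_s = 0.5) {
  stopifnot(inherits(split, "dataset_split"))
  rows <- list()
  for (i in seq_len(nrow(split$index))) {
    path <- split$index$path[i]
    rec <- tryCatch(read_recording(path), error = function(e) {
      warning("skipping unreadable recording ", path)
      NULL
    })
    if (is.null(rec)) next
    dom <- dominant_axis(rec)
    wins <- if (length(rec$t) >= round(length_s * rec$fs)) {
      sliding_windows(rec, length_s, stride_s)
    } else list()
    label <- rec$exercise_label
    dir.create(file.path(out_dir, label), recursive = TRUE, showWarnings = FALSE)
    rec_id <- sub("\\.csv$", "", basename(path))
    for (w in wins) {
      img <- window_to_image(w, config)
      img_name <- sprintf("%s_w%06d.png", rec_id, w$start_index)
      img_path <- file.path(out_dir, label, img_name)
      png::writePNG(img, img_path)
      rows[[length(rows) + 1L]] <- data.frame(
        image = file.path(label, img_name), label = label,
        binary = label_peak_window(w, dom$channel),
        source = path, start_index = w$start_index,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = character(), label = character(), binary = integer(),
               source = character(), start_index = integer())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
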