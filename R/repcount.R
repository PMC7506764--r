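# Peak-detection repetition counting: dominant-axis selection by mean-square,
# Savitzky-Golay smoothing, quantile-based threshold cut-offs, and
# alternating max-min pair counting.

#' Configuration of the peak-detection counter
#'
#' The Savitzky-Golay window defaults to about 2 s of samples (1023 samples
#' at 512 Hz), forced odd; order defaults to 4. Thresholds are placed at
#' `median +/- k * A` where `A` is half the 5th-95th percentile span of the
#' filtered signal and `k` is `threshold_fraction`.
#'
#' @param fs sampling rate the window scaling refers to (Hz).
#' @param sg_window_samples odd Savitzky-Golay window length; default the
#'   nearest odd integer to `2 * fs` (1023 at 512 Hz).
#' @param sg_order polynomial order (default 4).
#' @param threshold_fraction k in (0, 1) (default 0.3).
#' @param quantiles lower/upper amplitude quantiles (default 5th/95th).
#' @return an object of class `peak_config`.
#' @export
peak_config <- function(fs = 512, sg_window_samples = NULL, sg_order = 4,
                        threshold_fraction = 0.3, quantiles = c(0.05, 0.95)) {
  if (is.null(sg_window_samples)) {
    w <- round(2 * fs)
    if (w %% 2 == 0) w <- w - 1
    sg_window_samples <- w
  }
  if (sg_window_samples %% 2 == 0 || sg_window_samples <= sg_order) {
    stop("sg_window_samples must be odd and greater than sg_order")
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)")
  }
  structure(list(fs = fs, sg_window_samples = as.integer(sg_window_samples),
                 sg_order = as.integer(sg_order),
                 threshold_fraction = threshold_fraction,
                 quantiles = quantiles),
            class = "peak_config")
}

#' Identify the dominant sensor channel of a recording
#'
#' Each channel is mean-removed (so the accelerometer's gravity offset does
#' not mask motion) and scaled by its sensor's calibration range (16 g,
#' 2000 deg/s) to make accelerometer and gyroscope mean squares commensurable;
#' the channel with the largest mean square wins. Ties break deterministically
#' in the order acc X, Y, Z, gyro X, Y, Z.
#'
#' @param rec an `imu_recording` (N >= 2).
#' @return list with `sensor` ("accelerometer"/"gyroscope"), `axis`
#'   ("X"/"Y"/"Z"), `channel` (e.g. "acc_x"), `mean_squares` (all six scaled
#'   values) and `degenerate` (TRUE when all channels are constant).
#' @export
dominant_axis <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"), length(rec$t) >= 2)
  m <- recording_channels(rec)
  m <- sweep(m, 2, c(rep(ACC_RANGE_G, 3), rep(GYRO_RANGE_DPS, 3)), "/")
  m <- sweep(m, 2, colMeans(m), "-")
  ms <- colMeans(m^2)
  degenerate <- all(ms < .Machine$double.eps * 100)
  j <- unname(which.max(ms))  # first maximum wins: documented tie-break
  list(
    sensor = if (j <= 3) "accelerometer" else "gyroscope",
    axis = toupper(substr(CHANNELS[j], nchar(CHANNELS[j]), nchar(CHANNELS[j]))),
    channel = CHANNELS[j],
    mean_squares = ms,
    degenerate = degenerate
  )
}

#' Savitzky-Golay smoothing of one channel
#'
#' Least-squares local polynomial smoothing at the configured window and
#' order; output length equals input length and polynomials up to the filter
#' order pass through unchanged (away from the edges). A signal shorter than
#' the configured window shrinks the window to the largest valid odd length
#' with a warning.
#'
#' @param x numeric signal.
#' @param config a [peak_config()].
#' @return filtered signal of the same length.
#' @export
smooth_signal <- function(x, config = peak_config()) {
  n <- length(x)
  w <- config$sg_window_samples
  if (n <= w) {
    w <- n - 1 - (n %% 2)  # largest odd length < n
    if (w <= config$sg_order) {
      warning("signal too short to smooth; returned unchanged")
      return(x)
    }
    warning("Savitzky-Golay window shrunk to ", w, " samples")
  }
  signal::sgolayfilt(x, p = config$sg_order, n = w)
}

#' Upper and lower threshold cut-offs of a filtered signal
#'
#' With `m` the median and `A = (q_hi - q_lo) / 2` half the quantile span of
#' the filtered signal, the cut-offs are `m + k A` and `m - k A`. The
#' quantile-based amplitude makes the thresholds robust to outliers and
#' translation-equivariant. A zero amplitude span flags the signal as
#' degenerate (no repetitions detectable).
#'
#' @param x filtered signal (>= 2 samples).
#' @param config a [peak_config()].
#' @return list with `upper`, `lower`, `degenerate`.
#' @export
compute_thresholds <- function(x, config = peak_config()) {
  stopifnot(length(x) >= 2)
  m <- stats::median(x)
  q <- stats::quantile(x, config$quantiles, names = FALSE)
  a <- (q[2] - q[1]) / 2
  if (!is.finite(a) || a <= .Machine$double.eps * max(1, abs(m))) {
    return(list(upper = m, lower = m, degenerate = TRUE))
  }
  k <- config$threshold_fraction
  list(upper = m + k * a, lower = m - k * a, degenerate = FALSE)
}

#' Detect alternating peaks and valleys using two threshold cut-offs
#'
#' A state machine seeks a maximum above the upper cut-off, then a minimum
#' below the lower cut-off, alternating; within one state the most extreme
#' value wins. A cycle whose excursion stays inside the cut-offs is skipped;
#' a monotone signal yields nothing.
#'
#' @param x filtered signal.
#' @param thresholds list with `upper`, `lower` (and optional `degenerate`)
#'   from [compute_thresholds()].
#' @return list with `peaks` and `valleys` (strictly increasing sample
#'   indices), and `extrema` (data.frame `index`, `type` in detection order,
#'   strictly alternating).
#' @export
detect_peaks <- function(x, thresholds) {
  if (isTRUE(thresholds$degenerate)) {
    return(list(peaks = integer(0), valleys = integer(0),
                extrema = data.frame(index = integer(0), type = character(0))))
  }
  upper <- thresholds$upper
  lower <- thresholds$lower
  idx <- integer(0)
  typ <- character(0)
  seeking_max <- TRUE
  cand_val <- -Inf
  cand_idx <- NA_integer_
  # A candidate maximum is confirmed once it has exceeded the upper cut-off
  # and the signal falls back below it (and symmetrically for minima): the
  # cut-off pair acts as a hysteresis band, so excursions that never leave
  # the band trigger nothing.
  for (i in seq_along(x)) {
    v <- x[i]
    if (seeking_max) {
      if (v > cand_val) {
        cand_val <- v
        cand_idx <- i
      }
      if (cand_val >= upper && v < upper) {
        idx <- c(idx, cand_idx)
        typ <- c(typ, "max")
        seeking_max <- FALSE
        cand_val <- v
        cand_idx <- i
      }
    } else {
      if (v < cand_val) {
        cand_val <- v
        cand_idx <- i
      }
      if (cand_val <= lower && v > lower) {
        idx <- c(idx, cand_idx)
        typ <- c(typ, "min")
        seeking_max <- TRUE
        cand_val <- v
        cand_idx <- i
      }
    }
  }
  list(peaks = idx[typ == "max"], valleys = idx[typ == "min"],
       extrema = data.frame(index = idx, type = typ))
}

#' Count repetitions by peak detection on the dominant axis
#'
#' Pipeline: [dominant_axis()] -> [smooth_signal()] -> [compute_thresholds()]
#' -> [detect_peaks()]; each completed max-min pair increments the repetition
#' count. Per-exercise configurations may be supplied via `config_table`
#' keyed by class label, defaulting to the global `config`.
#'
#' @param rec an `imu_recording`.
#' @param config a [peak_config()]; defaults to one scaled to the recording's
#'   sampling rate.
#' @param config_table optional named list of per-label [peak_config()]s.
#' @return an object of class `rep_result`: `dominant`, `filtered`,
#'   `thresholds`, `peaks`, `valleys`, `rep_count`, `degenerate`.
#' @export
count_reps_peaks <- function(rec, config = NULL, config_table = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  config <- config_table[[rec$exercise_label]] %||% config %||%
    peak_config(fs = rec$fs)
  dom <- dominant_axis(rec)
  if (dom$degenerate) {
    return(structure(list(dominant = dom, filtered = NULL,
                          thresholds = NULL, peaks = integer(0),
                          valleys = integer(0), rep_count = 0L,
                          degenerate = TRUE),
                     class = "rep_result"))
  }
  x <- recording_channels(rec)[, dom$channel]
  xf <- smooth_signal(x, config)
  th <- compute_thresholds(xf, config)
  det <- detect_peaks(xf, th)
  typ <- det$extrema$type
  n_pairs <- if (length(typ) >= 2) {
    sum(typ[-length(typ)] == "max" & typ[-1] == "min")
  } else 0L
  structure(
    list(dominant = dom, filtered = xf, thresholds = th,
         peaks = det$peaks, valleys = det$valleys,
         rep_count = as.integer(n_pairs),
         degenerate = isTRUE(th$degenerate)),
    class = "rep_result"
  )
}

#' @export
print.rep_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<rep_result> degenerate signal: 0 repetitions\n")
  } else {
    cat(sprintf("<rep_result> %s %s-axis: %d repetitions (%d peaks, %d valleys)\n",
                x$dominant$sensor, x$dominant$axis, x$rep_count,
                length(x$peaks), length(x$valleys)))
  }
  invisible(x)
}
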