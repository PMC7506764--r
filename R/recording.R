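# Core domain types: one subject-exercise trial from a wrist-worn 6-axis IMU,
# its on-disk CSV form, and the class-folder dataset layout.

ACC_RANGE_G <- 16      # accelerometer calibration range, +/- g
GYRO_RANGE_DPS <- 2000 # gyroscope calibration range, +/- deg/s

CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")

#' The closed set of exercise labels
#'
#' Ten local-muscular-endurance exercises plus the "others" (OTH) class for
#' non-exercise movement: bicep curls (BC), frontal raises (FR), lateral
#' raises (LR), triceps extension right (TER), pec dec (PD), trunk twist (TT),
#' standing bicycle crunch (SBC), squats (SQ), leg lateral raise (LLR) and
#' lunges (L).
#'
#' @return character vector of the 11 labels.
#' @export
exercise_labels <- function() {
  c("BC", "FR", "LR", "TER", "PD", "TT", "SBC", "SQ", "LLR", "L", "OTH")
}

#' Construct and validate an IMU recording
#'
#' A recording is one trial: a time axis plus six synchronized channels
#' (3D accelerometer in g, 3D gyroscope in deg/s) at a fixed sampling rate.
#'
#' @param subject_id opaque subject identifier.
#' @param exercise_label one of [exercise_labels()].
#' @param session `"constrained"` (video-paced, low variability) or
#'   `"unconstrained"` (from memory, jittered tempo/plane/rest position).
#' @param fs sampling rate in Hz (> 0).
#' @param t time stamps in seconds, strictly increasing with spacing 1/fs.
#' @param acc N x 3 matrix of accelerometer samples in g (columns X, Y, Z),
#'   within +/- 16 g.
#' @param gyro N x 3 matrix of gyroscope samples in deg/s, within +/- 2000.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, exercise_label, session, fs, t, acc, gyro) {
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      exercise_label = as.character(exercise_label),
      session = as.character(session),
      fs = as.numeric(fs),
      t = as.numeric(t),
      acc = as.matrix(acc),
      gyro = as.matrix(gyro)
    ),
    class = "imu_recording"
  )
  colnames(rec$acc) <- c("x", "y", "z")
  colnames(rec$gyro) <- c("x", "y", "z")
  validate_recording(rec)
  rec
}

#' Validate an IMU recording against its type invariants
#'
#' Checks the closed label set, positive sampling rate, equal channel lengths,
#' a strictly increasing time axis with spacing 1/fs, and the sensor
#' calibration ranges (+/- 16 g, +/- 2000 deg/s).
#'
#' @param rec an `imu_recording`.
#' @param tol_fraction allowed fractional deviation of sample spacing from 1/fs.
#' @return `rec`, invisibly; stops with a validation error otherwise.
#' @export
validate_recording <- function(rec, tol_fraction = 0.01) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!rec$exercise_label %in% exercise_labels()) {
    stop("validation error: unknown exercise label '", rec$exercise_label, "'")
  }
  if (!rec$session %in% c("constrained", "unconstrained")) {
    stop("validation error: session must be 'constrained' or 'unconstrained'")
  }
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    stop("validation error: fs must be a positive scalar")
  }
  n <- length(rec$t)
  if (n < 1) stop("validation error: empty recording")
  if (nrow(rec$acc) != n || nrow(rec$gyro) != n ||
      ncol(rec$acc) != 3 || ncol(rec$gyro) != 3) {
    stop("validation error: all 7 series must have identical length N (acc/gyro N x 3)")
  }
  if (n > 1) {
    dt <- diff(rec$t)
    if (any(dt <= 0)) stop("validation error: time axis not strictly increasing")
    if (any(abs(dt - 1 / rec$fs) > tol_fraction / rec$fs)) {
      stop("validation error: sample spacing inconsistent with fs (dropped samples?)")
    }
  }
  if (any(!is.finite(rec$acc)) || any(!is.finite(rec$gyro))) {
    stop("validation error: non-finite sensor values")
  }
  if (any(abs(rec$acc) > ACC_RANGE_G)) {
    stop("validation error: accelerometer values outside +/-", ACC_RANGE_G, " g")
  }
  if (any(abs(rec$gyro) > GYRO_RANGE_DPS)) {
    stop("validation error: gyroscope values outside +/-", GYRO_RANGE_DPS, " deg/s")
  }
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %s subject=%s session=%s fs=%g Hz N=%d (%.2f s)\n",
    x$exercise_label, x$subject_id, x$session, x$fs, length(x$t),
    length(x$t) / x$fs
  ))
  invisible(x)
}

# Six channels as an N x 6 matrix in the fixed channel order.
recording_channels <- function(rec) {
  m <- cbind(rec$acc, rec$gyro)
  colnames(m) <- CHANNELS
  m
}

#' Write a recording to a self-describing CSV file
#'
#' The dialect is comma-separated, '.' decimal, UTF-8, with metadata stored as
#' `#key=value` header lines (subject, label, session, fs) followed by a
#' 7-column header row `t,acc_x,...,gyro_z`. Output bytes are deterministic
#' for identical input.
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- c(
    sprintf("#subject=%s", rec$subject_id),
    sprintf("#label=%s", rec$exercise_label),
    sprintf("#session=%s", rec$session),
    sprintf("#fs=%s", format(rec$fs, digits = 12))
  )
  m <- cbind(rec$t, recording_channels(rec))
  body <- apply(m, 1L, function(row) paste(sprintf("%.9g", row), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, paste(c("t", CHANNELS), collapse = ","), body),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a recording from its CSV file
#'
#' Inverse of [write_recording()]: parses the `#key=value` metadata block, the
#' column header and the sample rows, and validates the result.
#'
#' @param path CSV file written in the package's trial dialect.
#' @return an `imu_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  for (key in c("subject", "label", "session", "fs")) {
    if (is.null(meta[[key]])) stop("format error: missing metadata '#", key, "='")
  }
  header_i <- which(!grepl("^#", lines))[1]
  if (is.na(header_i)) stop("format error: no column header")
  cols <- strsplit(lines[header_i], ",", fixed = TRUE)[[1]]
  expected <- c("t", CHANNELS)
  missing <- setdiff(expected, cols)
  if (length(missing) > 0) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  dat <- utils::read.csv(
    text = paste(lines[-seq_len(header_i)], collapse = "\n"),
    header = FALSE, col.names = cols, colClasses = "numeric"
  )
  if (nrow(dat) < 1) stop("format error: no data rows")
  imu_recording(
    subject_id = meta$subject,
    exercise_label = meta$label,
    session = meta$session,
    fs = as.numeric(meta$fs),
    t = dat$t,
    acc = as.matrix(dat[, c("acc_x", "acc_y", "acc_z")]),
    gyro = as.matrix(dat[, c("gyro_x", "gyro_y", "gyro_z")])
  )
}

# Parse "<subject>_<session>_<k>.csv" file names; NA fields when they do not fit.
parse_trial_filename <- function(fname) {
  base <- sub("\\.csv$", "", basename(fname))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 3) {
    list(subject = parts[1], session = parts[2],
         k = suppressWarnings(as.integer(parts[length(parts)])))
  } else {
    list(subject = NA_character_, session = NA_character_, k = NA_integer_)
  }
}

#' Index one split of a class-folder dataset
#'
#' Expects the layout `<root>/<split>/<LABEL>/<subject>_<session>_<k>.csv`
#' with one sub-folder per exercise class. Files that fail to parse are
#' skipped with one warning each; empty class folders warn. When subject ids
#' are recoverable from file names, subject-disjointness against the sibling
#' splits under `root` is enforced (an overlapping subject is a validation
#' error), mirroring a subject-disjoint train/validation/test design.
#'
#' @param root dataset root directory.
#' @param split one of the split folder names under `root` (e.g. "train").
#' @param check_subject_overlap verify subject-disjointness across splits.
#' @return a `dataset_split`: list with `root`, `split` and `index`
#'   (data.frame: path, label, subject, session).
#' @export
scan_dataset <- function(root, split, check_subject_overlap = TRUE) {
  split_dir <- file.path(root, split)
  if (!dir.exists(split_dir)) stop("no such split directory: ", split_dir)
  class_dirs <- sort(list.dirs(split_dir, recursive = FALSE))
  rows <- list()
  for (cd in class_dirs) {
    label <- basename(cd)
    if (!label %in% exercise_labels()) {
      warning("skipping non-class folder: ", label)
      next
    }
    files <- sort(list.files(cd, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) {
      warning("empty class folder: ", file.path(split, label))
      next
    }
    for (f in files) {
      rec <- tryCatch(read_recording(f), error = function(e) {
        warning("skipping unparseable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(rec)) next
      if (rec$exercise_label != label) {
        warning("skipping ", f, ": label '", rec$exercise_label,
                "' does not match folder '", label, "'")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = f, label = label, subject = rec$subject_id,
        session = rec$session, stringsAsFactors = FALSE
      )
    }
  }
  index <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), label = character(),
               subject = character(), session = character())
  if (check_subject_overlap && nrow(index) > 0) {
    other_splits <- setdiff(basename(sort(list.dirs(root, recursive = FALSE))), split)
    for (os in other_splits) {
      other_files <- list.files(file.path(root, os), pattern = "\\.csv$",
                                recursive = TRUE)
      other_subjects <- unique(vapply(other_files,
        function(f) parse_trial_filename(f)$subject, character(1)))
      clash <- intersect(unique(index$subject), other_subjects)
      clash <- clash[!is.na(clash)]
      if (length(clash) > 0) {
        stop("validation error: subject(s) ", paste(clash, collapse = ", "),
             " appear in both '", split, "' and '", os, "' splits")
      }
    }
  }
  structure(list(root = root, split = split, index = index),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s: %d recordings\n", x$split, nrow(x$index)))
  if (nrow(x$index) > 0) print(table(x$index$label))
  invisible(x)
}
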