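# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_profiles <- function() default_profiles()

exercise_only_labels <- function() setdiff(exercise_labels(), "OTH")

# one constrained noiseless trial per exercise class (n_reps = 6, fs = 64)
noiseless_trials <- function() {
  cached("noiseless_trials", {
    p <- test_profiles()
    lapply(stats::setNames(nm = exercise_only_labels()), function(lab) {
      pr <- p[[lab]]
      pr$noise_sd <- 0
      simulate_exercise(pr, 6, fs = 64, mode = "constrained", seed = 2)
    })
  })
}

# desk-scale dataset tree: 2 train / 1 validation / 1 test subjects,
# one trial per class, fs 64
desk_dataset_root <- function() {
  cached("desk_dataset_root", {
    root <- file.path(tempdir(), "imurehab-fixture-ds")
    unlink(root, recursive = TRUE)
    make_dataset(list(
      root = root, fs = 64, trials_per_class = 1,
      splits = list(train = list(subjects = 2),
                    validation = list(subjects = 1),
                    test = list(subjects = 1))
    ), seed = 42)
    root
  })
}

desk_features <- function(split) {
  cached(paste0("desk_features_", split), {
    featurize_split(scan_dataset(desk_dataset_root(), split), 4, 2)
  })
}

# binary Peak/NoPeak image set rendered from constrained synthetic trials;
# vertical limits matched to the generator's amplitude regime (about 1 g /
# 200 deg/s) so the traces keep usable vertical resolution at 64 px
desk_image_config <- function() {
  image_config(native_size = 576, target_size = 64,
               acc_limit_g = 2, gyro_limit_dps = 250)
}

binary_image_set <- function(labels, seeds, n_reps = 6) {
  p <- test_profiles()
  icfg <- desk_image_config()
  imgs <- list()
  ys <- integer(0)
  for (lab in labels) {
    for (s in seeds) {
      sim <- simulate_exercise(p[[lab]], n_reps, fs = 64,
                               mode = "constrained", seed = s)
      dom <- dominant_axis(sim$recording)
      for (w in sliding_windows(sim$recording, 4, 0.5)) {
        imgs[[length(imgs) + 1L]] <- window_to_image(w, icfg)
        ys <- c(ys, label_peak_window(w, dom$channel))
      }
    }
  }
  list(images = imgs, y = ys)
}

random_window <- function(seed, w = 128) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(w * 3), w, 3),
             matrix(rnorm(w * 3, sd = 50), w, 3))
  colnames(m) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  m
}
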