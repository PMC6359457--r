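#' Gait simulation configuration
#'
#' A stated world for testing the pipeline: 3-channel quasi-periodic signals
#' at 100 Hz (vertical hip position, thigh angle, thigh moment) whose stride
#' cadence and amplitude differ across gait modes. Standing (ST) is
#' near-constant plus noise. The default schedule mimics a ~60 s walking
#' trial cycling ST/SW/NW/FW with multi-second dwells; default cadences rise
#' with walking speed (slow 0.7, normal 0.9, fast 1.1 strides/s).
#'
#' @param fs sampling rate in Hz (default 100).
#' @param schedule data.frame with columns `mode`, `duration` (seconds).
#' @param cadence named vector of per-mode stride cadences in Hz (0 = ST).
#' @param amplitude named list: per-mode length-3 channel amplitude vectors.
#' @param hip_offset constant offset of the hip-position channel (m); keeps
#'   the channel strictly positive, as a vertical position is.
#' @param noise_sd per-channel measurement noise standard deviations.
#' @param seed integer seed.
#' @return an object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(fs = 100,
                            schedule = default_gait_schedule(),
                            cadence = c(ST = 0, SW = 0.7, NW = 0.9, FW = 1.1),
                            amplitude = list(ST = c(0.002, 0.5, 0.5),
                                             SW = c(0.015, 15, 20),
                                             NW = c(0.020, 20, 30),
                                             FW = c(0.025, 25, 40)),
                            hip_offset = 0.9,
                            noise_sd = c(0.002, 0.8, 1.5),
                            seed = 1L) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("mode", "duration") %in% names(schedule)))
  if (any(schedule$duration <= 0)) stop_config("durations must be positive")
  walking <- setdiff(unique(schedule$mode), "ST")
  if (anyDuplicated(cadence[walking]))
    stop_config("walking-mode cadences must be distinct")
  structure(list(fs = fs, schedule = schedule, cadence = cadence,
                 amplitude = amplitude, hip_offset = hip_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gait_sim_config")
}

#' @rdname gait_sim_config
#' @export
default_gait_schedule <- function() {
  data.frame(mode = c("ST", "SW", "NW", "FW", "ST", "SW", "NW", "FW"),
             duration = c(6, 8, 8, 8, 6, 8, 8, 8))
}

#' Simulate a labeled gait recording
#'
#' Emulates the statistical structure the recognition pipeline assumes, not
#' gait physiology: within each scheduled mode segment the thigh angle is a
#' sinusoid at the mode's cadence, the hip position is an offset plus a
#' small oscillation at twice the cadence (two vertical excursions per
#' stride), and the thigh moment is a phase-shifted sinusoid plus a
#' stance-impulse harmonic; ST is near-constant. White Gaussian measurement
#' noise is added per channel and per-sample labels follow the schedule
#' exactly. Fully reproducible by seed.
#'
#' @param config a [gait_sim_config()].
#' @return a [raw_recording()] with channels `hip_pos`, `thigh_angle`,
#'   `thigh_moment`.
#' @export
simulate_gait_recording <- function(config = gait_sim_config()) {
  fs <- config$fs
  with_seed(config$seed, {
    segs <- lapply(seq_len(nrow(config$schedule)), function(k) {
      mode <- config$schedule$mode[k]
      n <- round(config$schedule$duration[k] * fs)
      t <- (seq_len(n) - 1) / fs
      cad <- config$cadence[[mode]]
      amp <- config$amplitude[[mode]]
      phase0 <- stats::runif(1, 0, 2 * pi)
      if (cad > 0) {
        ph <- 2 * pi * cad * t + phase0
        hip <- config$hip_offset + amp[1] * sin(2 * ph)
        ang <- amp[2] * sin(ph)
        mom <- amp[3] * (sin(ph - pi / 3) + 0.3 * sin(2 * ph))
      } else {
        hip <- rep(config$hip_offset, n)
        ang <- amp[2] * sin(2 * pi * 0.05 * t + phase0)  # slow postural sway
        mom <- rep(0, n)
      }
      list(x = cbind(hip_pos = hip, thigh_angle = ang, thigh_moment = mom),
           labels = rep(mode, n))
    })
    x <- do.call(rbind, lapply(segs, `[[`, "x"))
    noise <- sapply(config$noise_sd, function(s) stats::rnorm(nrow(x), 0, s))
    raw_recording(x + noise, fs = fs,
                  labels = unlist(lapply(segs, `[[`, "labels")))
  })
}

#' Planted feature-table configuration
#'
#' A labeled feature table with a known informative subset: informative
#' columns have class-dependent means separated by `effect_size` noise
#' standard deviations, the rest are standard Gaussian noise, and optional
#' redundant columns are noisy copies of a source column at a configured
#' correlation. Exercises the selection machinery with known ground truth.
#'
#' @param m number of patterns (balanced across classes).
#' @param n number of features.
#' @param informative indices of the planted informative set.
#' @param classes number of classes K.
#' @param effect_size class-mean separation in noise-sd units (>= 0).
#' @param redundancy optional data.frame with columns `copy`, `source`,
#'   `correlation`.
#' @param seed integer seed.
#' @return an object of class `planted_table_config`.
#' @export
planted_table_config <- function(m = 200L, n = 30L, informative = 1:5,
                                 classes = 3L, effect_size = 3,
                                 redundancy = NULL, seed = 1L) {
  if (any(informative < 1 | informative > n))
    stop_config("informative indices must lie in 1..n")
  if (effect_size < 0) stop_config("effect_size must be >= 0")
  if (!is.null(redundancy)) {
    redundancy <- as.data.frame(redundancy)
    stopifnot(all(c("copy", "source", "correlation") %in% names(redundancy)))
    if (any(redundancy$copy %in% informative))
      stop_config("redundant copies must overwrite non-informative columns")
  }
  structure(list(m = as.integer(m), n = as.integer(n),
                 informative = as.integer(informative),
                 classes = as.integer(classes), effect_size = effect_size,
                 redundancy = redundancy, seed = as.integer(seed)),
            class = "planted_table_config")
}

#' Generate a planted feature table
#'
#' @param config a [planted_table_config()].
#' @return a [feature_table()] with attribute `informative` (ground truth,
#'   for tests).
#' @export
generate_planted_table <- function(config = planted_table_config()) {
  with_seed(config$seed, {
    m <- config$m; n <- config$n; K <- config$classes
    labels <- rep_len(paste0("C", seq_len(K)), m)
    X <- matrix(stats::rnorm(m * n), m, n)
    # informative feature j elevates the mean of one class (cyclically
    # assigned) by the effect size: class-dependent means as stated, and no
    # single feature can separate every class, so with K > #informative the
    # planted set is jointly necessary for minimal error
    for (j in seq_along(config$informative)) {
      col <- config$informative[j]
      cls <- paste0("C", ((j - 1) %% K) + 1)
      X[labels == cls, col] <- X[labels == cls, col] + config$effect_size
    }
    if (!is.null(config$redundancy)) {
      for (r in seq_len(nrow(config$redundancy))) {
        src <- config$redundancy$source[r]
        rho <- config$redundancy$correlation[r]
        s <- scale(X[, src])[, 1]
        X[, config$redundancy$copy[r]] <-
          rho * s + sqrt(1 - rho^2) * stats::rnorm(m)
      }
    }
    colnames(X) <- paste0("f", seq_len(n))
    out <- feature_table(X, labels)
    attr(out, "informative") <- config$informative
    out
  })
}
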