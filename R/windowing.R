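#' Labeled multichannel gait recording
#'
#' Container for a uniformly sampled multichannel biomechanical time series
#' (e.g. vertical hip position, thigh angle, thigh moment) with a per-sample
#' gait-mode label.
#'
#' @param samples numeric matrix, time in rows, channels in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character or factor vector of per-sample mode identifiers,
#'   length `nrow(samples)`.
#' @param channel_names optional channel identifiers; defaults to the matrix
#'   column names or `ch1..chk`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, labels, channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_config("fs must be a single positive number, got %s", format(fs))
  labels <- as.character(labels)
  if (length(labels) != nrow(samples))
    stop_config("labels length (%d) must equal the sample count (%d)",
                length(labels), nrow(samples))
  channel_names <- channel_names %||% colnames(samples) %||%
    paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop_config("channel_names length must equal the channel count")
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, labels = labels,
                 channel_names = channel_names),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("modes:", paste(names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Windowing configuration
#'
#' Frame length `Lf`, increment `I` and processing budget `tau`, all in
#' milliseconds. Real-time feasibility requires `tau <= Lf` for disjoint
#' windowing and `tau <= I <= Lf` for overlapped windowing. `tau` is a
#' declared budget checked against the configuration, not a measured time.
#'
#' @param frame_ms frame length Lf in ms.
#' @param increment_ms increment I in ms; defaults to `frame_ms` (disjoint).
#' @param mode "disjoint" or "overlapped".
#' @param processing_budget_ms declared processing time tau in ms.
#' @return an object of class `windowing_config`.
#' @export
windowing_config <- function(frame_ms, increment_ms = frame_ms,
                             mode = c("disjoint", "overlapped"),
                             processing_budget_ms = 0) {
  mode <- match.arg(mode)
  if (frame_ms <= 0) stop_config("frame_ms must be positive")
  if (mode == "disjoint") {
    increment_ms <- frame_ms
    if (processing_budget_ms > frame_ms)
      stop_config("disjoint windowing requires tau <= Lf (tau = %g, Lf = %g)",
                  processing_budget_ms, frame_ms)
  } else {
    if (increment_ms > frame_ms)
      stop_config("overlapped windowing requires I <= Lf (I = %g, Lf = %g)",
                  increment_ms, frame_ms)
    if (processing_budget_ms > increment_ms)
      stop_config("overlapped windowing requires tau <= I (tau = %g, I = %g)",
                  processing_budget_ms, increment_ms)
  }
  if (increment_ms <= 0) stop_config("increment_ms must be positive")
  structure(list(frame_ms = frame_ms, increment_ms = increment_ms,
                 mode = mode, processing_budget_ms = processing_budget_ms),
            class = "windowing_config")
}

frame_samples <- function(config, fs) {
  n <- config$frame_ms * fs / 1000
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    stop_config("frame_ms * fs / 1000 must be a positive integer (got %g)", n)
  as.integer(round(n))
}

increment_samples <- function(config, fs) {
  n <- config$increment_ms * fs / 1000
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    stop_config("increment_ms * fs / 1000 must be a positive integer (got %g)", n)
  as.integer(round(n))
}

#' Segment a recording into frames
#'
#' Slides a frame of length `Lf` ms over the recording with increment `I` ms
#' (disjoint windowing is the special case `I = Lf`). Frame `k` (0-based)
#' starts at sample `k * I * fs / 1000`; trailing partial frames are dropped.
#' The frame count equals `floor((T - Lf) / I) + 1` for a recording of
#' duration `T` ms (0 when no complete frame fits).
#'
#' @param recording a [raw_recording()].
#' @param config a [windowing_config()].
#' @return list of frames, each of class `gait_frame` with fields `data`
#'   (frame-samples x channels), `start_index` (1-based sample offset) and
#'   `label` (majority per-sample label, see [assign_frame_label()]).
#' @export
segment_frames <- function(recording, config) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(config, "windowing_config"))
  nf <- frame_samples(config, recording$fs)
  ni <- increment_samples(config, recording$fs)
  n <- nrow(recording$samples)
  if (n < nf) return(list())
  starts <- seq.int(1L, n - nf + 1L, by = ni)
  lapply(starts, function(s) {
    idx <- s:(s + nf - 1L)
    structure(list(data = recording$samples[idx, , drop = FALSE],
                   start_index = s,
                   label = assign_frame_label(recording$labels[idx])),
              class = "gait_frame")
  })
}

#' Majority label of a frame
#'
#' Frames spanning a mode transition contain more than one per-sample label;
#' the frame is labeled with the majority label. Ties are broken in favor of
#' the label of the last sample in the frame (the latest sample best reflects
#' current intent); if the last sample's label is not among the tied leaders,
#' the tied label occurring latest in the frame wins.
#'
#' @param frame_sample_labels non-empty vector of per-sample labels.
#' @return a single mode identifier.
#' @export
assign_frame_label <- function(frame_sample_labels) {
  labs <- as.character(frame_sample_labels)
  if (length(labs) == 0L) stop_config("empty label sequence")
  tab <- table(labs)
  leaders <- names(tab)[tab == max(tab)]
  if (length(leaders) == 1L) return(leaders)
  last <- labs[length(labs)]
  if (last %in% leaders) return(last)
  # latest occurrence among tied leaders
  leaders[which.max(vapply(leaders, function(l) max(which(labs == l)), 0))]
}

#' Read a labeled recording from CSV
#'
#' Expects the header `time,<ch1>,<ch2>,...,label` with time in seconds.
#' Uniform sampling is inferred from the time column and validated against
#' the declared sampling rate.
#'
#' @param path CSV file path.
#' @param fs declared sampling rate in Hz.
#' @param tol relative tolerance on the inferred sampling period.
#' @return a [raw_recording()].
#' @export
read_recording_csv <- function(path, fs, tol = 1e-6) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "time") || !identical(names(df)[ncol(df)], "label"))
    stop_config("recording CSV must have columns time,<channels...>,label")
  t <- df$time
  if (length(t) > 1) {
    dt <- diff(t)
    if (max(abs(dt - 1 / fs)) > tol * (1 / fs) + 1e-12)
      stop_config("time column is not uniform at the declared fs = %g Hz", fs)
  }
  ch <- setdiff(names(df), c("time", "label"))
  raw_recording(as.matrix(df[ch]), fs = fs, labels = df$label,
                channel_names = ch)
}

#' Write a labeled recording to CSV
#'
#' @param recording a [raw_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  df <- data.frame(time = (seq_len(nrow(recording$samples)) - 1) / recording$fs,
                   recording$samples, check.names = FALSE)
  df$label <- recording$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
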