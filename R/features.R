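TD_TYPES <- c("SSC", "ZC", "WL", "VAR", "MAV", "MAV1", "MAV2", "RMS",
              "WAMP", "SK", "KU")
FD_TYPES <- c("MDF", "MNF", "MAXF", "AR4")
PAIR_TYPES <- c("COR", "ANG")
ALL_TYPES <- c(TD_TYPES, FD_TYPES, PAIR_TYPES)

#' Feature extraction configuration
#'
#' Thresholds are in the amplitude units of the (typically normalized)
#' signal. The defaults follow the convention that detection thresholds for
#' ZC/SSC/WAMP scale with the signal: when `NULL` they are resolved at table
#' build time to `0.01 *` the per-channel standard deviation of the frames.
#'
#' @param zc_threshold amplitude threshold for zero crossings (>= 0).
#' @param ssc_threshold slope-sign-change threshold (>= 0).
#' @param wamp_threshold Willison-amplitude threshold (>= 0).
#' @param ar_order autoregressive model order (default 4).
#' @param ar_method "yule-walker" (default, periodogram-consistent) or "burg".
#' @param psd_window periodogram taper: "rectangular" or "hamming".
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(zc_threshold = NULL, ssc_threshold = NULL,
                           wamp_threshold = NULL, ar_order = 4L,
                           ar_method = c("yule-walker", "burg"),
                           psd_window = c("rectangular", "hamming")) {
  for (th in list(zc_threshold, ssc_threshold, wamp_threshold))
    if (!is.null(th) && th < 0) stop_config("thresholds must be >= 0")
  if (ar_order < 1) stop_config("ar_order must be >= 1")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
                 wamp_threshold = wamp_threshold, ar_order = as.integer(ar_order),
                 ar_method = match.arg(ar_method),
                 psd_window = match.arg(psd_window)),
            class = "feature_config")
}

resolve_thresholds <- function(config, channel_sd) {
  config$zc_threshold <- config$zc_threshold %||% (0.01 * channel_sd)
  config$ssc_threshold <- config$ssc_threshold %||% (0.01 * channel_sd)
  config$wamp_threshold <- config$wamp_threshold %||% (0.01 * channel_sd)
  config
}

pop_var <- function(x) mean((x - mean(x))^2)

td_one <- function(x, type, cfg) {
  L <- length(x)
  switch(type,
    MAV = mean(abs(x)),
    MAV1 = {
      i <- seq_len(L)
      w <- ifelse(i >= 0.25 * L & i <= 0.75 * L, 1, 0.5)
      mean(w * abs(x))
    },
    MAV2 = {
      i <- seq_len(L)
      w <- ifelse(i < 0.25 * L, 4 * i / L,
                  ifelse(i > 0.75 * L, 4 * (L - i) / L, 1))
      mean(w * abs(x))
    },
    VAR = pop_var(x),
    RMS = sqrt(mean(x^2)),
    WL = sum(abs(diff(x))),
    ZC = {
      if (L < 2) stop_config("ZC needs frame length >= 2")
      d <- x[-L] * x[-1]
      sum(d < 0 & abs(x[-L] - x[-1]) >= cfg$zc_threshold)
    },
    SSC = {
      if (L < 3) stop_config("SSC needs frame length >= 3")
      xm <- x[2:(L - 1)]
      dl <- xm - x[1:(L - 2)]
      dr <- xm - x[3:L]
      sum(dl * dr > 0 & pmax(abs(dl), abs(dr)) >= cfg$ssc_threshold)
    },
    WAMP = sum(abs(diff(x)) > cfg$wamp_threshold),
    SK = {
      m2 <- pop_var(x)
      if (m2 <= 0) 0 else mean((x - mean(x))^3) / m2^1.5
    },
    KU = {
      m2 <- pop_var(x)
      if (m2 <= 0) 0 else mean((x - mean(x))^4) / m2^2
    },
    stop_config("unknown TD feature type '%s'", type)
  )
}

#' Time-domain features of one frame channel
#'
#' Canonical surface-EMG time-domain summaries of a single-channel frame:
#' slope sign change (SSC), zero crossing (ZC), waveform length (WL),
#' variance (VAR, population convention), mean absolute value (MAV) and its
#' piecewise-weighted variants (MAV1, MAV2), root mean square (RMS), Willison
#' amplitude (WAMP), skewness (SK) and kurtosis (KU). SSC/ZC/WAMP count
#' events whose amplitude exceeds the corresponding threshold in `config`.
#' A zero-variance frame yields SK = KU = 0 under the zero-variance
#' convention (with a message) rather than an error.
#'
#' @param frame_channel numeric vector (one channel of one frame).
#' @param types subset of the TD type names.
#' @param config a [feature_config()]; `NULL` thresholds resolve to 0 here.
#' @return named numeric vector, one value per requested type.
#' @export
compute_td_features <- function(frame_channel, types = TD_TYPES,
                                config = feature_config()) {
  types <- match.arg(types, TD_TYPES, several.ok = TRUE)
  cfg <- resolve_thresholds(config, 0)
  if (any(types %in% c("SK", "KU")) && pop_var(frame_channel) <= 0)
    message("zero-variance frame: SK/KU returned as 0")
  vapply(stats::setNames(types, types), function(tp) td_one(frame_channel, tp, cfg),
         numeric(1))
}

#' Correlation and angle between two frames
#'
#' COR is the Pearson correlation of the two equal-length frame vectors; ANG
#' is the angle in radians (`[0, pi]`) between the raw (un-centered) frame
#' vectors, i.e. `acos` of their normalized inner product.
#'
#' @param frame_a,frame_b numeric vectors of equal length >= 2.
#' @return named numeric vector `c(COR = ..., ANG = ...)`.
#' @export
compute_pair_features <- function(frame_a, frame_b) {
  if (length(frame_a) != length(frame_b) || length(frame_a) < 2)
    stop_config("pair features need two equal-length frames of length >= 2")
  na <- sqrt(sum(frame_a^2)); nb <- sqrt(sum(frame_b^2))
  if (na == 0 || nb == 0) stop_config("ANG undefined for a zero-norm frame")
  if (pop_var(frame_a) == 0 || pop_var(frame_b) == 0)
    stop_config("COR undefined for a zero-variance frame")
  c(COR = stats::cor(frame_a, frame_b),
    ANG = acos(max(-1, min(1, sum(frame_a * frame_b) / (na * nb)))))
}

# one-sided periodogram of the mean-removed frame; DC bin excluded so a
# signal offset (e.g. vertical hip position) cannot dominate the spectrum
periodogram <- function(x, fs, taper = "rectangular") {
  x <- x - mean(x)
  L <- length(x)
  if (taper == "hamming")
    x <- x * (0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  p <- Mod(stats::fft(x))^2 / L
  k <- seq_len(floor(L / 2))           # bins 1 .. L/2 (skip DC)
  list(freq = k * fs / L, power = p[k + 1])
}

#' Frequency-domain features of one frame channel
#'
#' Power-spectrum summaries from the periodogram of the mean-removed frame:
#' mean frequency (MNF, power-weighted mean), median frequency (MDF, first
#' bin where cumulative power reaches half the total), maximum frequency
#' (MAXF, bin of the periodogram maximum), and order-`ar_order`
#' autoregressive coefficients (AR4 by default, Yule-Walker on the
#' mean-removed frame). All frequencies are in Hz, in `[0, fs/2]`.
#'
#' @param frame_channel numeric vector.
#' @param fs sampling rate in Hz.
#' @param types subset of `MDF`, `MNF`, `MAXF`, `AR4`.
#' @param config a [feature_config()].
#' @return named numeric vector; AR coefficients are named `AR4.1..AR4.k`.
#' @export
compute_fd_features <- function(frame_channel, fs, types = FD_TYPES,
                                config = feature_config()) {
  types <- match.arg(types, FD_TYPES, several.ok = TRUE)
  out <- numeric(0)
  spec_types <- intersect(types, c("MDF", "MNF", "MAXF"))
  if (length(spec_types)) {
    if (all(frame_channel == frame_channel[1]))
      stop_config("MNF/MDF/MAXF undefined for a constant frame")
    pg <- periodogram(frame_channel, fs, config$psd_window)
    tot <- sum(pg$power)
    if (tot <= 0) stop_config("MNF/MDF/MAXF undefined: zero spectral power")
    for (tp in spec_types) {
      out[tp] <- switch(tp,
        MNF = sum(pg$freq * pg$power) / tot,
        MDF = pg$freq[which(cumsum(pg$power) >= tot / 2)[1]],
        MAXF = pg$freq[which.max(pg$power)])
    }
  }
  if ("AR4" %in% types) {
    ord <- config$ar_order
    if (length(frame_channel) < 2 * ord)
      stop_config("AR needs frame length >= 2 * ar_order")
    fit <- if (config$ar_method == "burg")
      stats::ar.burg(frame_channel, aic = FALSE, order.max = ord, demean = TRUE)
    else
      stats::ar.yw(frame_channel, aic = FALSE, order.max = ord, demean = TRUE)
    a <- fit$ar
    length(a) <- ord                      # pad in the degenerate all-zero case
    a[is.na(a)] <- 0
    out[paste0("AR4.", seq_len(ord))] <- a
  }
  # preserve requested order (AR block last if requested last, etc.)
  want <- unlist(lapply(types, function(tp)
    if (tp == "AR4") paste0("AR4.", seq_len(config$ar_order)) else tp))
  out[want]
}

#' Feature layout
#'
#' An ordered list of (feature type, target) entries describing the columns
#' of a feature table. Single-channel types target one channel; COR/ANG
#' target an unordered channel pair; AR4 expands to `ar_order` columns.
#'
#' @param entries data.frame with columns `type` and `target` (`"2"` for a
#'   channel, `"1-3"` for a pair).
#' @return an object of class `feature_layout`.
#' @export
feature_layout <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "target") %in% names(entries)))
  bad <- setdiff(entries$type, ALL_TYPES)
  if (length(bad)) stop_config("unknown feature types: %s", paste(bad, collapse = ", "))
  # canonicalize pair targets so {1,3} == {3,1}
  is_pair <- entries$type %in% PAIR_TYPES
  entries$target <- as.character(entries$target)
  entries$target[is_pair] <- vapply(entries$target[is_pair], function(t) {
    p <- sort(as.integer(strsplit(t, "-", fixed = TRUE)[[1]]))
    if (length(p) != 2 || any(is.na(p))) stop_config("pair target must be 'a-b'")
    paste(p, collapse = "-")
  }, character(1))
  if (anyDuplicated(entries[c("type", "target")]))
    stop_config("duplicate (type, target) layout entry")
  structure(list(entries = entries), class = "feature_layout")
}

layout_column_names <- function(layout, ar_order = 4L) {
  unlist(mapply(function(tp, tg) {
    if (tp == "AR4") paste0("AR4.", seq_len(ar_order), "@", tg)
    else paste0(tp, "@", tg)
  }, layout$entries$type, layout$entries$target, SIMPLIFY = FALSE),
  use.names = FALSE)
}

#' Number of table columns a layout expands to
#'
#' Scalar entries contribute one column each; each AR4 entry contributes
#' `ar_order` columns.
#'
#' @param layout a [feature_layout()].
#' @param ar_order AR model order (default 4).
#' @return integer column count.
#' @export
layout_width <- function(layout, ar_order = 4L) {
  sum(ifelse(layout$entries$type == "AR4", ar_order, 1L))
}

#' @export
print.feature_layout <- function(x, ...) {
  cat(sprintf("feature_layout: %d entries -> %d columns\n",
              nrow(x$entries), layout_width(x)))
  invisible(x)
}

expand_types_layout <- function(types, n_channels) {
  rows <- list()
  for (tp in types) {
    if (tp %in% PAIR_TYPES) {
      prs <- utils::combn(n_channels, 2)
      for (j in seq_len(ncol(prs)))
        rows[[length(rows) + 1L]] <- data.frame(
          type = tp, target = paste(prs[, j], collapse = "-"))
    } else {
      for (ch in seq_len(n_channels))
        rows[[length(rows) + 1L]] <- data.frame(type = tp, target = as.character(ch))
    }
  }
  feature_layout(do.call(rbind, rows))
}

#' Standard layouts for a 3-channel gait recording
#'
#' `full_layout()` holds all 17 feature types (F1-F17) on every channel and
#' channel pair: 14 scalar types x 3 channels + COR/ANG x 3 pairs + AR4 x 3
#' channels = 60 columns. `preselected_layout()` drops the five weak types
#' (MAV1, MAV2, MDF, MNF, MAXF), giving 45 columns, and with
#' `drop_hip_zc = TRUE` also removes ZC of channel 1 (vertical hip position
#' never crosses zero), giving the 44-column training layout.
#'
#' @param n_channels number of channels (default 3).
#' @return a [feature_layout()].
#' @export
full_layout <- function(n_channels = 3L) {
  expand_types_layout(c(TD_TYPES, "MDF", "MNF", "MAXF", "COR", "ANG", "AR4"),
                      n_channels)
}

#' @rdname full_layout
#' @param drop_hip_zc drop the ZC entry of channel 1 (44-column layout)?
#' @export
preselected_layout <- function(n_channels = 3L, drop_hip_zc = FALSE) {
  keep <- c("SSC", "ZC", "WL", "VAR", "MAV", "RMS", "WAMP", "SK", "KU",
            "COR", "ANG", "AR4")
  lay <- expand_types_layout(keep, n_channels)
  if (drop_hip_zc) {
    e <- lay$entries
    lay <- feature_layout(e[!(e$type == "ZC" & e$target == "1"), ])
  }
  lay
}

#' Build a labeled feature table from frames
#'
#' Row `k` is the concatenation, in layout order, of the features of frame
#' `k`; labels are carried over from the frames. `NULL` thresholds in
#' `config` are resolved to `0.01 *` the per-channel standard deviation over
#' all frames.
#'
#' @param frames list of frames from [segment_frames()].
#' @param layout a [feature_layout()].
#' @param config a [feature_config()].
#' @param fs sampling rate in Hz (needed for FD entries; defaults to 100).
#' @return an object of class `feature_table` with fields `values` (m x n
#'   matrix), `labels`, `layout`, `normalized`.
#' @export
build_feature_table <- function(frames, layout, config = feature_config(),
                                fs = 100) {
  if (!length(frames)) stop_config("no frames to build a table from")
  n_ch <- ncol(frames[[1]]$data)
  tgt_idx <- lapply(strsplit(layout$entries$target, "-", fixed = TRUE), as.integer)
  if (max(unlist(tgt_idx)) > n_ch)
    stop_config("layout references channel %d but frames have %d channels",
                max(unlist(tgt_idx)), n_ch)
  ch_sd <- apply(do.call(rbind, lapply(frames, `[[`, "data")), 2, stats::sd)
  rows <- lapply(frames, function(fr) {
    unlist(lapply(seq_len(nrow(layout$entries)), function(j) {
      tp <- layout$entries$type[j]
      tg <- tgt_idx[[j]]
      if (tp %in% PAIR_TYPES) {
        compute_pair_features(fr$data[, tg[1]], fr$data[, tg[2]])[tp]
      } else {
        cfg <- resolve_thresholds(config, ch_sd[tg])
        if (tp %in% TD_TYPES) compute_td_features(fr$data[, tg], tp, cfg)
        else compute_fd_features(fr$data[, tg], fs, tp, cfg)
      }
    }), use.names = FALSE)
  })
  values <- do.call(rbind, rows)
  colnames(values) <- layout_column_names(layout, config$ar_order)
  feature_table(values, vapply(frames, `[[`, "", "label"), layout)
}

#' Labeled feature table
#'
#' @param values m x n numeric matrix of feature values.
#' @param labels length-m vector of mode identifiers.
#' @param layout the [feature_layout()] describing the columns (optional).
#' @param normalized has the table been column-standardized?
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, layout = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop_config("labels length must equal the row count")
  if (!is.null(layout) && layout_width(layout) != ncol(values))
    stop_config("layout expands to %d columns but values has %d",
                layout_width(layout), ncol(values))
  structure(list(values = values, labels = as.character(labels),
                 layout = layout, normalized = normalized),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d patterns x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  cat("classes:", paste(names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Standardize feature-table columns
#'
#' Centers and scales every column to mean 0 and unit variance (population
#' convention: divide by the length-n standard deviation). The fitted
#' centers/scales are stored as attributes so the identical transform can be
#' applied to held-out rows with [apply_normalization()].
#'
#' @param table a [feature_table()].
#' @return the normalized `feature_table` with attributes `center`, `scale`.
#' @export
normalize_table <- function(table) {
  v <- table$values
  ctr <- colMeans(v)
  scl <- sqrt(colMeans(sweep(v, 2, ctr)^2))
  if (any(scl == 0)) {
    offending <- colnames(v)[scl == 0] %||% which(scl == 0)
    stop_config("zero-variance column(s): %s", paste(offending, collapse = ", "))
  }
  out <- feature_table(sweep(sweep(v, 2, ctr), 2, scl, "/"), table$labels,
                       table$layout, normalized = TRUE)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' @rdname normalize_table
#' @param fitted a table returned by [normalize_table()] (carries the
#'   center/scale to reuse).
#' @param newdata a raw `feature_table` of held-out rows.
#' @export
apply_normalization <- function(fitted, newdata) {
  ctr <- attr(fitted, "center"); scl <- attr(fitted, "scale")
  if (is.null(ctr)) stop_config("`fitted` carries no normalization parameters")
  out <- feature_table(sweep(sweep(newdata$values, 2, ctr), 2, scl, "/"),
                       newdata$labels, newdata$layout, normalized = TRUE)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Read / write feature tables as CSV
#'
#' The header encodes layout entries as `TYPE@channel`, `TYPE@chA-chB` for
#' pairs, and `AR4.k@channel` for the AR coefficients; the final column is
#' `label`.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_table_csv` returns a `feature_table`;
#'   `write_feature_table_csv` returns `path` invisibly.
#' @export
write_feature_table_csv <- function(table, path) {
  df <- as.data.frame(table$values, check.names = FALSE)
  df$label <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table_csv
#' @export
read_feature_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop_config("feature CSV must have a label column")
  vals <- as.matrix(df[setdiff(names(df), "label")])
  lay <- tryCatch(layout_from_column_names(colnames(vals)), error = function(e) NULL)
  feature_table(vals, df$label, lay)
}

layout_from_column_names <- function(nms) {
  parts <- strsplit(nms, "@", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop_config("column names must be TYPE@target")
  tp <- sub("^AR4\\.[0-9]+$", "AR4", vapply(parts, `[[`, "", 1))
  tg <- vapply(parts, `[[`, "", 2)
  ent <- unique(data.frame(type = tp, target = tg, stringsAsFactors = FALSE))
  feature_layout(ent)
}
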