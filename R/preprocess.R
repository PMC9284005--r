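# Filtering, movement-segment extraction and sliding-window segmentation.
#
# Conventions: sample indices are 0-based in configuration arithmetic and
# all sample ranges are half-open [start, end); sample i corresponds to
# t = i / fs. Filters are applied per channel, forward-backward
# (zero-phase), so feature windows carry no group delay.

#' Preprocessing configuration
#'
#' @param notch_hz mains frequency to remove (Hz).
#' @param notch_q notch quality factor; bandwidth = notch_hz / notch_q.
#' @param band_hz length-2 numeric band-pass edges (Hz).
#' @param filter_order overall band-pass Butterworth order (even).
#' @param onset_s movement onset used for segment extraction: the cue
#'   time (seconds from trial start), not a detected EMG onset.
#' @param keep_duration_s length of movement data kept for modelling (s);
#'   only the first second of each movement is used by default.
#' @param window_len sliding-window length in samples.
#' @param window_step sliding-window step in samples.
#' @param channels_used integer indices of channels to keep
#'   (`NULL` = all, in recorded order).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_hz = 50, notch_q = 30,
                              band_hz = c(10, 450), filter_order = 4L,
                              onset_s = 4.0, keep_duration_s = 1.0,
                              window_len = 300L, window_step = 150L,
                              channels_used = NULL) {
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stopf("band_hz must be increasing positive edges")
  if (window_step > window_len) stopf("window_step must be <= window_len")
  if (filter_order %% 2L != 0L) stopf("filter_order must be even")
  structure(list(notch_hz = notch_hz, notch_q = notch_q, band_hz = band_hz,
                 filter_order = as.integer(filter_order), onset_s = onset_s,
                 keep_duration_s = keep_duration_s,
                 window_len = as.integer(window_len),
                 window_step = as.integer(window_step),
                 channels_used = channels_used),
            class = "preprocess_config")
}

# second-order IIR notch (constrained biquad) at f0 with quality q
#' @noRd
notch_coefficients <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' @noRd
apply_filtfilt_rows <- function(sig, b, a) {
  out <- sig
  for (c in seq_len(nrow(sig)))
    out[c, ] <- signal::filtfilt(filt = b, a = a, x = sig[c, ])
  out
}

#' Zero-phase 50 Hz notch filter
#'
#' Removes mains interference with a second-order IIR notch applied
#' forward-backward per channel (zero phase, squared magnitude response).
#'
#' @param rec a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return filtered [raw_recording()] of identical shape.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs_hz <= 2 * cfg$notch_hz)
    stopf("sampling rate %d Hz too low for a %g Hz notch", rec$fs_hz, cfg$notch_hz)
  co <- notch_coefficients(cfg$notch_hz, cfg$notch_q, rec$fs_hz)
  rec$signal <- apply_filtfilt_rows(rec$signal, co$b, co$a)
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Restricts the signal to the informative sEMG band (default 10-450 Hz)
#' with a Butterworth band-pass applied forward-backward per channel.
#'
#' @inheritParams notch_filter
#' @return filtered [raw_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs_hz <= 2 * cfg$band_hz[2])
    stopf("sampling rate %d Hz too low for band edge %g Hz",
          rec$fs_hz, cfg$band_hz[2])
  bf <- signal::butter(cfg$filter_order / 2L, cfg$band_hz * 2 / rec$fs_hz,
                       type = "pass")
  rec$signal <- apply_filtfilt_rows(rec$signal, bf$b, bf$a)
  rec
}

#' Extract the modelled movement segment
#'
#' Keeps samples in `[round(onset_s * fs), round((onset_s +
#' keep_duration_s) * fs))` — by default the first second of movement
#' after the go-cue, which is the portion used for prediction.
#'
#' @inheritParams notch_filter
#' @return a [raw_recording()] containing only the kept segment.
#' @export
extract_movement_segment <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs_hz
  from <- round(cfg$onset_s * fs)            # 0-based, inclusive
  to <- round((cfg$onset_s + cfg$keep_duration_s) * fs)  # exclusive
  if (to > ncol(rec$signal))
    stopf("trial of %d samples too short for segment [%d, %d)",
          ncol(rec$signal), from, to)
  rec$signal <- rec$signal[, (from + 1L):to, drop = FALSE]
  rec
}

#' Select a subset of channels
#'
#' @inheritParams notch_filter
#' @return a [raw_recording()] with channels `cfg$channels_used`, in the
#'   configured order (`NULL` selects all).
#' @export
select_channels <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  idx <- cfg$channels_used
  if (is.null(idx)) return(rec)
  if (any(idx < 1L | idx > nrow(rec$signal)))
    stopf("channel index out of range 1..%d", nrow(rec$signal))
  rec$signal <- rec$signal[idx, , drop = FALSE]
  rec$channel_names <- rec$channel_names[idx]
  rec
}

#' Sliding-window segmentation of a trial segment
#'
#' Cuts the segment into overlapping analysis windows: window k covers
#' samples `[k*step, k*step + window_len)`, giving
#' `floor((T - len)/step) + 1` windows, each inheriting the trial's
#' label. Windows never straddle trial boundaries.
#'
#' @param segment a [raw_recording()] (typically the output of
#'   [extract_movement_segment()]).
#' @param cfg a [preprocess_config()].
#' @return a `window_set`: list with `windows` (C x W x N array), `meta`
#'   (data.frame: subject_id, label, source_trial, start_sample),
#'   `fs_hz`, `channel_names`.
#' @export
sliding_windows <- function(segment, cfg = preprocess_config()) {
  stopifnot(inherits(segment, "raw_recording"))
  T <- ncol(segment$signal); W <- cfg$window_len; step <- cfg$window_step
  if (T < W) stopf("segment of %d samples shorter than window length %d", T, W)
  starts <- seq(0L, T - W, by = step)
  arr <- array(0, dim = c(nrow(segment$signal), W, length(starts)))
  for (k in seq_along(starts))
    arr[, , k] <- segment$signal[, (starts[k] + 1L):(starts[k] + W)]
  window_set(arr,
             meta = data.frame(subject_id = segment$subject_id,
                               label = segment$label,
                               source_trial = segment$trial_index,
                               start_sample = starts,
                               stringsAsFactors = FALSE),
             fs_hz = segment$fs_hz, channel_names = segment$channel_names)
}

#' Window-set container
#'
#' Holds N analysis windows as a C x W x N array plus per-window
#' metadata. All downstream feature extraction and modelling consumes
#' this container.
#'
#' @param windows numeric array, channels x window length x windows.
#' @param meta data.frame with one row per window (columns `subject_id`,
#'   `label`, `source_trial`, `start_sample`).
#' @param fs_hz sampling rate (Hz).
#' @param channel_names channel names.
#' @return object of class `window_set`.
#' @export
window_set <- function(windows, meta, fs_hz, channel_names) {
  stopifnot(is.array(windows), length(dim(windows)) == 3L,
            nrow(meta) == dim(windows)[3])
  structure(list(windows = windows, meta = meta, fs_hz = as.integer(fs_hz),
                 channel_names = channel_names),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of %d channels x %d samples @ %d Hz\n",
              d[3], d[1], d[2], x$fs_hz))
  print(table(x$meta$label))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @export
n_windows <- function(ws) dim(ws$windows)[3]

#' Subset a window set by window index
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[, , idx, drop = FALSE],
             ws$meta[idx, , drop = FALSE], ws$fs_hz, ws$channel_names)
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical C, W and fs.
#' @export
combine_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  d1 <- dim(sets[[1]]$windows)[1:2]
  for (s in sets)
    if (!identical(dim(s$windows)[1:2], d1) || s$fs_hz != sets[[1]]$fs_hz)
      stopf("window sets differ in shape or sampling rate")
  arr <- array(unlist(lapply(sets, function(s) s$windows)),
               dim = c(d1, sum(vapply(sets, n_windows, 0L))))
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  rownames(meta) <- NULL
  window_set(arr, meta, sets[[1]]$fs_hz, sets[[1]]$channel_names)
}

#' Full preprocessing of one trial
#'
#' Channel selection, zero-phase notch and band-pass filtering of the
#' whole trial (so filter edge effects stay outside the kept segment),
#' movement-segment extraction, and sliding-window segmentation.
#'
#' @inheritParams notch_filter
#' @return a `window_set` for the trial.
#' @export
preprocess_trial <- function(rec, cfg = preprocess_config()) {
  rec <- select_channels(rec, cfg)
  rec <- notch_filter(rec, cfg)
  rec <- bandpass_filter(rec, cfg)
  seg <- extract_movement_segment(rec, cfg)
  sliding_windows(seg, cfg)
}

#' Preprocess a list of recordings into one window set
#'
#' @param recordings list of [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return a combined `window_set` over all trials.
#' @export
preprocess_dataset <- function(recordings, cfg = preprocess_config()) {
  combine_window_sets(lapply(recordings, preprocess_trial, cfg = cfg))
}
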