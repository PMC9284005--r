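#' Construct a raw sEMG recording
#'
#' A `raw_recording` holds one trial's multi-channel signal matrix
#' (channels x time samples, arbitrary signal units) together with its
#' sampling rate and acquisition metadata. This is the container every
#' preprocessing and feature-extraction step operates on.
#'
#' @param signal numeric matrix, channels x samples (C x T).
#' @param fs_hz sampling rate in Hz (positive integer-valued scalar).
#' @param subject_id subject identifier string.
#' @param label movement class, one of `"standing"`, `"sitting"`, `"walking"`.
#' @param channel_names character vector of C muscle names. Defaults to
#'   `ch1..chC`.
#' @param trial_index integer trial number within the subject's session.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs_hz, subject_id, label,
                          channel_names = NULL, trial_index = 1L) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("'signal' must be a numeric matrix (channels x samples)")
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    stopf("'signal' must have at least one channel and one sample")
  assert_scalar_number(fs_hz, "fs_hz", min = 1)
  label <- match_movement_label(label)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stopf("channel_names length (%d) != channel count (%d)",
          length(channel_names), nrow(signal))
  structure(
    list(signal = signal, fs_hz = as.integer(fs_hz),
         subject_id = as.character(subject_id), label = label,
         channel_names = as.character(channel_names),
         trial_index = as.integer(trial_index)),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s, trial %d, label '%s'\n",
              x$subject_id, x$trial_index, x$label))
  cat(sprintf("  %d channels x %d samples @ %d Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs_hz,
              ncol(x$signal) / x$fs_hz))
  invisible(x)
}

#' @export
dim.raw_recording <- function(x) dim(x$signal)

#' Write / read one recording as CSV + JSON sidecar
#'
#' The signal is stored as a headered CSV with columns `t_s, ch1..chC`
#' (one row per sample, times in seconds from trial start); all metadata
#' lives in a JSON sidecar at `<path>.json`. Numeric values round-trip
#' exactly (shortest round-trippable decimal representation).
#'
#' @param rec a [raw_recording()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [raw_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  C <- nrow(rec$signal); T <- ncol(rec$signal)
  df <- data.table::data.table(t_s = (seq_len(T) - 1L) / rec$fs_hz)
  for (c in seq_len(C)) df[[paste0("ch", c)]] <- rec$signal[c, ]
  data.table::fwrite(df, path)
  meta <- list(fs_hz = rec$fs_hz, subject_id = rec$subject_id,
               label = rec$label, channel_names = rec$channel_names,
               trial_index = rec$trial_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stopf("signal file not found: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing metadata sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs_hz", "subject_id", "label", "channel_names", "trial_index"))
    if (is.null(meta[[f]])) stopf("sidecar %s lacks field '%s'", sidecar, f)
  df <- tryCatch(data.table::fread(path),
                 error = function(e) stopf("malformed signal file %s: %s",
                                           path, conditionMessage(e)))
  if (nrow(df) == 0L) stopf("empty signal file: %s", path)
  if (!identical(names(df)[1L], "t_s"))
    stopf("malformed header in %s: first column must be 't_s'", path)
  ndata <- ncol(df) - 1L
  C <- length(meta$channel_names)
  if (ndata != C)
    stopf("channel-count mismatch in %s: %d data columns, sidecar declares %d channels",
          path, ndata, C)
  sig <- t(as.matrix(df[, -1L, with = FALSE]))
  dimnames(sig) <- NULL
  raw_recording(sig, meta$fs_hz, meta$subject_id, meta$label,
                meta$channel_names, meta$trial_index)
}

#' Write / read a dataset manifest (TSV)
#'
#' A manifest lists the recordings of a dataset, one row per trial:
#' `path  subject  label  trial  fs_hz`. Paths are interpreted relative to
#' the manifest's directory.
#'
#' @param manifest data.frame with columns `path, subject_id, label,
#'   trial_index, fs_hz`.
#' @param path TSV file path.
#' @export
write_manifest <- function(manifest, path) {
  req <- c("path", "subject_id", "label", "trial_index", "fs_hz")
  if (!all(req %in% names(manifest)))
    stopf("manifest must have columns: %s", paste(req, collapse = ", "))
  out <- manifest[, req]
  names(out) <- c("path", "subject", "label", "trial", "fs_hz")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("path", "subject", "label", "trial", "fs_hz")
  if (!all(req %in% names(df)))
    stopf("malformed manifest %s: need columns %s", path, paste(req, collapse = ", "))
  names(df) <- c("path", "subject_id", "label", "trial_index", "fs_hz")[match(names(df), req)]
  if (anyDuplicated(df$path)) stopf("manifest %s has duplicate paths", path)
  if (length(unique(df$fs_hz)) > 1L)
    stopf("manifest %s mixes sampling rates: %s", path,
          paste(unique(df$fs_hz), collapse = ", "))
  df
}

#' Load every recording listed in a manifest
#'
#' @param manifest_path path to a manifest TSV written by [write_manifest()].
#' @return list of [raw_recording()] in manifest order.
#' @export
load_dataset <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    full <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(full))
      stopf("manifest entry %d references missing file: %s", i, p)
    read_recording(full)
  })
}
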