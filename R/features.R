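# Hand-crafted sEMG features: 7 time-domain quantities (MAV, SSI, WL,
# RMS, ZC, SSC, 6th-order AR coefficients) and 3 frequency-domain
# quantities (MNP, PKF, MDF), following the standard Phinyomark-style
# definitions used throughout the myoelectric-control literature.

#' Feature-extraction configuration
#'
#' @param zc_threshold dead-band threshold for zero crossings (signal
#'   units); a crossing counts only if the step `|x_i - x_{i+1}|` is at
#'   least this large. Default 0 (no dead band).
#' @param ssc_threshold dead-band threshold for slope-sign changes.
#' @param ar_order autoregressive model order (default 6).
#' @param fs_hz sampling rate used to label frequency bins (Hz).
#' @param ar_scalar_mode if `TRUE`, only the first AR coefficient enters
#'   the feature vector, giving the 7-per-channel time-domain layout; the
#'   default `FALSE` keeps all `ar_order` coefficients (12 per channel).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(zc_threshold = 0, ssc_threshold = 0,
                           ar_order = 6L, fs_hz = 1500L,
                           ar_scalar_mode = FALSE) {
  assert_scalar_number(zc_threshold, "zc_threshold", min = 0)
  assert_scalar_number(ssc_threshold, "ssc_threshold", min = 0)
  if (ar_order < 1L) stopf("ar_order must be >= 1")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
                 ar_order = as.integer(ar_order), fs_hz = as.integer(fs_hz),
                 ar_scalar_mode = isTRUE(ar_scalar_mode)),
            class = "feature_config")
}

#' Amplitude/time-domain features of one channel window
#'
#' For a window `x` of length N:
#' \itemize{
#'   \item MAV: mean absolute value, `mean(|x|)`;
#'   \item SSI: simple square integral, `sum(x^2)`;
#'   \item WL: waveform length, `sum(|x[i+1] - x[i]|)`;
#'   \item RMS: `sqrt(SSI / N)`;
#'   \item ZC: sign-change count, gated by `zc_threshold`;
#'   \item SSC: slope-sign-change count, gated by `ssc_threshold`.
#' }
#'
#' @param x numeric vector (one channel, one window), length >= 2.
#' @param cfg a [feature_config()].
#' @return named numeric vector `c(MAV, SSI, WL, RMS, ZC, SSC)`.
#' @export
time_domain_features <- function(x, cfg = feature_config()) {
  N <- length(x)
  if (N < 2L) stopf("time-domain features need at least 2 samples (got %d)", N)
  d <- diff(x)
  ssi <- sum(x^2)
  zc <- sum(x[-N] * x[-1L] < 0 & abs(d) >= cfg$zc_threshold)
  ssc <- 0L
  if (N >= 3L) {
    d1 <- x[2:(N - 1L)] - x[1:(N - 2L)]
    d2 <- x[2:(N - 1L)] - x[3:N]
    ssc <- sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= cfg$ssc_threshold)
  }
  c(MAV = mean(abs(x)), SSI = ssi, WL = sum(abs(d)),
    RMS = sqrt(ssi / N), ZC = zc, SSC = ssc)
}

#' Autoregressive coefficients by Yule-Walker (Levinson-Durbin)
#'
#' Fits an order-p AR model `x_t = sum_k a_k x_{t-k} + e_t` from the
#' biased sample autocovariances via the Levinson-Durbin recursion (no
#' demeaning; band-passed sEMG is zero-mean). A zero-variance window
#' returns all-zero coefficients by convention.
#'
#' @param x numeric vector, length > `ar_order`.
#' @param cfg a [feature_config()].
#' @return named numeric vector `AR1..ARp` in the predictive convention
#'   above.
#' @export
ar_coefficients <- function(x, cfg = feature_config()) {
  p <- cfg$ar_order
  N <- length(x)
  if (N <= p) stopf("AR order %d needs more than %d samples (got %d)", p, p, N)
  # biased autocovariances r_0..r_p (divide by N, no demeaning)
  r <- vapply(0:p, function(k) sum(x[1:(N - k)] * x[(1 + k):N]) / N, 0)
  out <- numeric(p)
  if (r[1] > 0) {
    a <- numeric(0); e <- r[1]
    for (k in 1:p) {
      acc <- r[k + 1]
      if (k > 1) acc <- acc - sum(a * r[k:2])
      kappa <- acc / e
      a <- if (k == 1) kappa else c(a - kappa * rev(a), kappa)
      e <- e * (1 - kappa^2)
      if (e <= 0) { out[1:k] <- a; break }
      out[1:k] <- a
    }
  }
  names(out) <- paste0("AR", 1:p)
  out
}

#' Spectral features of one channel window
#'
#' Computes a one-sided rectangular-window periodogram
#' `P_j = |X_j|^2 / N` at frequencies `f_j = j * fs / N`,
#' `j = 0..floor(N/2)` (DC bin included), and derives:
#' \itemize{
#'   \item MNP: mean power over the bins;
#'   \item PKF: frequency of the maximum-power bin (ties toward the
#'     lowest frequency);
#'   \item MDF: smallest `f_j` at which cumulative power reaches half the
#'     total power.
#' }
#'
#' @param x numeric vector, length >= 4.
#' @param cfg a [feature_config()] supplying `fs_hz`.
#' @return named numeric vector `c(MNP, PKF, MDF)` (frequencies in Hz).
#' @export
frequency_domain_features <- function(x, cfg = feature_config()) {
  N <- length(x)
  if (N < 4L) stopf("spectral features need at least 4 samples (got %d)", N)
  nb <- floor(N / 2) + 1L
  P <- abs(fft(x)[1:nb])^2 / N
  f <- (seq_len(nb) - 1L) * cfg$fs_hz / N
  tot <- sum(P)
  if (tot == 0) return(c(MNP = 0, PKF = 0, MDF = 0))
  mdf <- f[which(cumsum(P) >= tot / 2)[1L]]
  c(MNP = mean(P), PKF = f[which.max(P)], MDF = mdf)
}

#' @noRd
td_feature_names <- function(cfg) {
  base <- c("MAV", "SSI", "WL", "RMS", "ZC", "SSC")
  ar <- if (cfg$ar_scalar_mode) "AR1" else paste0("AR", seq_len(cfg$ar_order))
  c(base, ar)
}

#' Extract the hand-crafted feature vector of one window
#'
#' Assembles the time-domain block `F_td` (per-channel MAV, SSI, WL, RMS,
#' ZC, SSC, AR coefficients; channels concatenated in channel order) and
#' the frequency-domain block `F_fd` (per-channel MNP, PKF, MDF).
#' With the default 6-coefficient AR block and C channels, `f_td` has
#' length 12 C and `f_fd` length 3 C; `ar_scalar_mode` gives 7 C.
#'
#' @param window numeric matrix, channels x samples (one window), or a
#'   `window_set` element.
#' @param cfg a [feature_config()].
#' @return list with named numeric vectors `f_td` and `f_fd`
#'   (names `ch{i}_{feature}`).
#' @export
extract_handcrafted <- function(window, cfg = feature_config()) {
  stopifnot(is.matrix(window))
  C <- nrow(window)
  td <- lapply(seq_len(C), function(c) {
    x <- window[c, ]
    res <- tryCatch({
      ar <- ar_coefficients(x, cfg)
      if (cfg$ar_scalar_mode) ar <- ar[1L]
      c(time_domain_features(x, cfg), ar)
    }, error = function(e) stopf("channel %d: %s", c, conditionMessage(e)))
    names(res) <- paste0("ch", c, "_", td_feature_names(cfg))
    res
  })
  fd <- lapply(seq_len(C), function(c) {
    res <- tryCatch(frequency_domain_features(window[c, ], cfg),
                    error = function(e) stopf("channel %d: %s", c,
                                              conditionMessage(e)))
    names(res) <- paste0("ch", c, "_", names(res))
    res
  })
  list(f_td = unlist(td), f_fd = unlist(fd))
}

#' Hand-crafted feature matrix of a window set
#'
#' Applies [extract_handcrafted()] to every window and stacks the
#' concatenated `[F_td, F_fd]` vectors row-wise.
#'
#' @param ws a `window_set`.
#' @param cfg a [feature_config()]; its `fs_hz` is overridden by the
#'   window set's sampling rate.
#' @return numeric matrix, windows x features, with feature column names
#'   and the window metadata attached as attribute `"meta"`.
#' @export
handcrafted_features <- function(ws, cfg = feature_config()) {
  stopifnot(inherits(ws, "window_set"))
  cfg$fs_hz <- ws$fs_hz
  N <- n_windows(ws)
  rows <- lapply(seq_len(N), function(i) {
    hv <- extract_handcrafted(ws$windows[, , i], cfg)
    c(hv$f_td, hv$f_fd)
  })
  X <- do.call(rbind, rows)
  attr(X, "n_td") <- length(extract_handcrafted(ws$windows[, , 1], cfg)$f_td)
  attr(X, "meta") <- ws$meta
  X
}

#' Write a feature table to CSV
#'
#' One row per window with metadata columns
#' `subject,trial,start_sample,label` followed by the feature columns.
#'
#' @param X feature matrix from [handcrafted_features()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(X, path) {
  meta <- attr(X, "meta")
  df <- data.frame(subject = meta$subject_id, trial = meta$source_trial,
                   start_sample = meta$start_sample, label = meta$label,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X))
  data.table::fwrite(df, path)
  invisible(path)
}
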