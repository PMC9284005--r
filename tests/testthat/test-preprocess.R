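sine_rec <- function(f, fs = 1500, dur = 2, C = 1, amp = 1) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  sig <- matrix(rep(amp * sin(2 * pi * f * t), C), nrow = C, byrow = TRUE)
  raw_recording(sig, fs, "S1", "standing")
}

rms_interior <- function(x, fs = 1500, edge_s = 0.1) {
  n <- length(x); k <- round(edge_s * fs)
  sqrt(mean(x[(k + 1):(n - k)]^2))
}

test_that("notch filter removes 50 Hz and passes 100 Hz", {
  cfg <- preprocess_config()
  r50 <- sine_rec(50)
  y50 <- notch_filter(r50, cfg)
  expect_lt(rms_interior(y50$signal[1, ]), 0.1 * rms_interior(r50$signal[1, ]))

  r100 <- sine_rec(100)
  y100 <- notch_filter(r100, cfg)
  expect_gt(rms_interior(y100$signal[1, ]), 0.89 * rms_interior(r100$signal[1, ]))

  rz <- raw_recording(matrix(0, 2, 3000), 1500, "S1", "standing")
  expect_equal(notch_filter(rz, cfg)$signal, rz$signal)

  low <- raw_recording(matrix(rnorm(200), 1, 200), 90, "S1", "standing")
  expect_error(notch_filter(low, cfg), "too low")
})

test_that("bandpass filter rejects DC/low frequencies and passes 100 Hz", {
  cfg <- preprocess_config()
  rdc <- raw_recording(matrix(5, 1, 3000), 1500, "S1", "standing")
  ydc <- bandpass_filter(rdc, cfg)
  n <- ncol(ydc$signal)
  expect_lt(max(abs(ydc$signal[1, 151:(n - 150)])), 0.05)

  r2 <- sine_rec(2)
  y2 <- bandpass_filter(r2, cfg)
  expect_lt(rms_interior(y2$signal[1, ]), 0.1 * rms_interior(r2$signal[1, ]))

  r100 <- sine_rec(100)
  y100 <- bandpass_filter(r100, cfg)
  expect_gt(rms_interior(y100$signal[1, ]), 0.89 * rms_interior(r100$signal[1, ]))
})

test_that("filters are linear and commute with channel permutation", {
  cfg <- preprocess_config()
  set.seed(4)
  a <- matrix(rnorm(3 * 1500), 3, 1500)
  b <- matrix(rnorm(3 * 1500), 3, 1500)
  mk <- function(m) raw_recording(m, 1500, "S1", "standing")
  fab <- bandpass_filter(mk(a + b), cfg)$signal
  fa <- bandpass_filter(mk(a), cfg)$signal
  fb <- bandpass_filter(mk(b), cfg)$signal
  expect_equal(fab, fa + fb, tolerance = 1e-9)

  perm <- c(3, 1, 2)
  expect_equal(notch_filter(mk(a[perm, ]), cfg)$signal,
               notch_filter(mk(a), cfg)$signal[perm, ])
})

test_that("zero-phase filtering preserves the peak of a symmetric pulse", {
  cfg <- preprocess_config()
  n <- 3000; centre <- 1500
  pulse <- exp(-((seq_len(n) - centre) / 20)^2)
  rec <- raw_recording(matrix(pulse, 1), 1500, "S1", "standing")
  for (f in list(notch_filter, bandpass_filter)) {
    y <- f(rec, cfg)$signal[1, ]
    expect_lte(abs(which.max(abs(y)) - centre), 1)
  }
})

test_that("movement segment extraction follows the half-open convention", {
  cfg <- preprocess_config()   # onset 4 s, keep 1 s
  sig <- matrix(seq_len(18000), 1)  # encode the sample index as the value
  rec <- raw_recording(sig, 1500, "S1", "sitting")
  seg <- extract_movement_segment(rec, cfg)
  expect_equal(ncol(seg$signal), 1500L)
  expect_equal(seg$signal[1, 1], 6001)       # 0-based sample 6000
  expect_equal(seg$signal[1, 1500], 7500)    # 0-based sample 7499
  expect_identical(seg$label, "sitting")

  short <- raw_recording(matrix(0, 1, round(4.5 * 1500)), 1500, "S1", "sitting")
  expect_error(extract_movement_segment(short, cfg), "too short")

  cfg0 <- preprocess_config(onset_s = 0, keep_duration_s = 2)
  full <- raw_recording(matrix(rnorm(3000), 1), 1500, "S1", "sitting")
  expect_identical(extract_movement_segment(full, cfg0)$signal, full$signal)
})

test_that("sliding windows have the specified count, starts and labels", {
  seg <- raw_recording(matrix(rnorm(5 * 1500), 5), 1500, "S1", "walking")
  ws <- sliding_windows(seg, preprocess_config(window_len = 300, window_step = 150))
  expect_equal(n_windows(ws), 9L)
  expect_equal(ws$meta$start_sample, seq(0L, 1200L, by = 150L))
  expect_true(all(ws$meta$label == "walking"))
  expect_equal(ws$windows[, , 2], seg$signal[, 151:450])

  one <- raw_recording(matrix(rnorm(300), 1), 1500, "S1", "walking")
  expect_equal(n_windows(sliding_windows(one, preprocess_config())), 1L)

  ws25 <- sliding_windows(seg, preprocess_config(window_len = 300, window_step = 75))
  expect_equal(n_windows(ws25), 17L)

  tiny <- raw_recording(matrix(rnorm(200), 1), 1500, "S1", "walking")
  expect_error(sliding_windows(tiny, preprocess_config()), "shorter than window")
})

test_that("non-overlapping windows tile the truncated segment exactly", {
  seg <- raw_recording(matrix(rnorm(2 * 1000), 2), 1500, "S1", "standing")
  ws <- sliding_windows(seg, preprocess_config(window_len = 300, window_step = 300))
  expect_equal(n_windows(ws), 3L)
  recon <- do.call(cbind, lapply(1:3, function(k) ws$windows[, , k]))
  expect_identical(recon, seg$signal[, 1:900])
})

test_that("channel selection subsets and reorders, and validates indices", {
  rec <- raw_recording(matrix(rnorm(10 * 100), 10), 1500, "S1", "standing",
                       channel_names = paste0("m", 1:10))
  sel <- select_channels(rec, preprocess_config(channels_used = 1:5))
  expect_equal(nrow(sel$signal), 5L)
  expect_equal(sel$channel_names, paste0("m", 1:5))

  rev5 <- select_channels(rec, preprocess_config(channels_used = 5:1))
  expect_equal(rev5$channel_names, paste0("m", 5:1))

  expect_identical(select_channels(rec, preprocess_config())$signal, rec$signal)
  expect_error(select_channels(rec, preprocess_config(channels_used = c(1, 11))),
               "out of range")
})
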