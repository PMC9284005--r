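# shared fixtures, generated in code and cached for the test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small 2-subject synthetic dataset (full paradigm, default templates)
small_dataset <- function() {
  fixture("small_dataset", simulate_dataset(2, variability = 0.1, seed = 2024))
}

small_windows <- function() {
  fixture("small_windows", preprocess_dataset(small_dataset()$recordings))
}

# one deterministic random window matrix
random_window <- function(C = 5, W = 300, seed = 1) {
  set.seed(seed)
  matrix(rnorm(C * W), C, W)
}

# a tiny high-SNR 2-class window set for training smoke tests:
# class A = low-frequency sinusoid bursts, class B = high-frequency, with noise
toy_window_set <- function(n_per_class = 50, C = 3, W = 90, fs = 300,
                           seed = 7) {
  set.seed(seed)
  t <- (seq_len(W) - 1) / fs
  arr <- array(0, c(C, W, 2 * n_per_class))
  lab <- rep(c("standing", "walking"), each = n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    f0 <- if (lab[i] == "standing") 20 else 90
    amp <- if (lab[i] == "standing") c(1, 0.2, 0.6) else c(0.2, 1, 0.4)
    for (c in seq_len(C))
      arr[c, , i] <- amp[c] * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) +
        rnorm(W, 0, 0.1)
  }
  window_set(arr,
             meta = data.frame(subject_id = "T1", label = lab,
                               source_trial = seq_len(2 * n_per_class),
                               start_sample = 0L, stringsAsFactors = FALSE),
             fs_hz = fs, channel_names = paste0("ch", seq_len(C)))
}

# split a window set by trial indices
ws_trials <- function(ws, trials) {
  subset_windows(ws, which(ws$meta$source_trial %in% trials))
}
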