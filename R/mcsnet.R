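# Learned channel-synergy feature extractor: a shared per-channel LSTM
# over framed window samples, a two-layer temporal CNN (ELU + average
# pooling), and a depthwise convolution across the sEMG-channel axis
# that combines the temporal-frequency maps of different muscles into
# synergy features, finished by a global average pool.

#' Configuration of the learned feature extractor
#'
#' The window is framed into non-overlapping `frame_len`-sample steps so
#' the LSTM sees `W / frame_len` time steps of `frame_len`-dimensional
#' input (a 300-sample window becomes a 20-step sequence), which keeps
#' CPU training practical without changing the architecture's structure.
#'
#' @param lstm_hidden LSTM hidden size (shared weights, each sEMG
#'   channel's sequence processed independently).
#' @param cnn1_filters,cnn2_filters filter counts of the two temporal
#'   convolution layers.
#' @param kernel_len temporal kernel length (in LSTM steps).
#' @param depthwise_multiplier outputs per feature map of the depthwise
#'   channel-axis convolution; the learned feature length is
#'   `cnn2_filters * depthwise_multiplier`.
#' @param pool_len length-2 integer vector, average-pool sizes after the
#'   two convolution layers.
#' @param dropout_rate dropout on the learned feature vector during
#'   training (eval mode never drops).
#' @param frame_len samples per LSTM input step.
#' @return object of class `mcsnet_config`.
#' @export
mcsnet_config <- function(lstm_hidden = 16L, cnn1_filters = 16L,
                          cnn2_filters = 32L, kernel_len = 5L,
                          depthwise_multiplier = 2L, pool_len = c(2L, 3L),
                          dropout_rate = 0.25, frame_len = 15L) {
  sizes <- c(lstm_hidden, cnn1_filters, cnn2_filters, kernel_len,
             depthwise_multiplier, frame_len, pool_len)
  if (any(sizes < 1L)) stopf("all mcsnet sizes must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  structure(list(lstm_hidden = as.integer(lstm_hidden),
                 cnn1_filters = as.integer(cnn1_filters),
                 cnn2_filters = as.integer(cnn2_filters),
                 kernel_len = as.integer(kernel_len),
                 depthwise_multiplier = as.integer(depthwise_multiplier),
                 pool_len = as.integer(pool_len),
                 dropout_rate = dropout_rate,
                 frame_len = as.integer(frame_len),
                 activation = "ELU"),
            class = "mcsnet_config")
}

#' Build the learned feature extractor
#'
#' Lays out and initializes all parameters for a given input shape and
#' reports the resulting feature dimension and parameter count. Stage
#' order: LSTM (per channel, shared weights) -> two temporal CNN layers
#' -> depthwise CNN across channels -> global average pool.
#'
#' @param cfg a [mcsnet_config()].
#' @param input_shape integer vector `c(C, W)`: channels and window
#'   length in samples.
#' @param seed initialization seed (fixed-seed uniform fan-in scheme).
#' @return object of class `mcsnet` with elements `params`, `dims`,
#'   `feature_dim`, `param_count`.
#' @export
build_mcsnet <- function(cfg = mcsnet_config(), input_shape = c(5L, 300L),
                         seed = 1L) {
  C <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  d <- cfg$frame_len
  L0 <- W %/% d
  if (L0 < 1L) stopf("window of %d samples shorter than one %d-sample frame", W, d)
  k <- cfg$kernel_len; p1 <- cfg$pool_len[1]; p2 <- cfg$pool_len[2]
  L1 <- L0 - k + 1L
  if (L1 < p1) stopf("kernel/pool too long for %d LSTM steps", L0)
  P1 <- L1 %/% p1
  L2 <- P1 - k + 1L
  if (L2 < p2) stopf("kernel (%d) longer than pooled sequence (%d)", k, P1)
  P2 <- L2 %/% p2
  h <- cfg$lstm_hidden; f1 <- cfg$cnn1_filters; f2 <- cfg$cnn2_filters
  m <- cfg$depthwise_multiplier
  params <- with_seed(seed, list(
    lstm = lstm_init(d, h),
    conv1 = list(W = init_mat(k * h, f1, fan_in = k * h), b = numeric(f1)),
    conv2 = list(W = init_mat(k * f1, f2, fan_in = k * f1), b = numeric(f2)),
    dw = list(W = array(runif(C * f2 * m, -sqrt(1 / C), sqrt(1 / C)),
                        c(C, f2, m)),
              b = numeric(f2 * m))
  ))
  n_par <- sum(vapply(rapply(params, length, how = "unlist"), identity, 0L))
  structure(list(cfg = cfg, input_shape = c(C, W), params = params,
                 dims = list(C = C, W = W, d = d, L0 = L0, L1 = L1, P1 = P1,
                             L2 = L2, P2 = P2, h = h, f1 = f1, f2 = f2, m = m),
                 feature_dim = f2 * m, param_count = n_par, seed = seed),
            class = "mcsnet")
}

#' @export
print.mcsnet <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<mcsnet> input %d x %d -> LSTM(%d, %d steps) -> CNN(%d, %d) -> depthwise(x%d) -> %d features\n",
              d$C, d$W, d$h, d$L0, d$f1, d$f2, d$m, x$feature_dim))
  cat(sprintf("  %d parameters\n", x$param_count))
  invisible(x)
}

# windows: C x W x B array -> (B*C, L0, d) framed LSTM input
#' @noRd
frame_windows <- function(arr, dims) {
  C <- dims$C; B <- dim(arr)[3]
  Wuse <- dims$L0 * dims$d
  Xp <- aperm(arr[, seq_len(Wuse), , drop = FALSE], c(3, 1, 2))  # B, C, W
  M <- array(Xp, c(B * C, Wuse))                                 # b fastest
  aperm(array(M, c(B * C, dims$d, dims$L0)), c(1, 3, 2))
}

# full forward pass with cached intermediates (for backprop)
#' @noRd
mcsnet_forward_cache <- function(model, arr, training = FALSE) {
  dims <- model$dims; p <- model$params
  B <- dim(arr)[3]; C <- dims$C
  XL <- frame_windows(arr, dims)
  ls <- lstm_forward(XL, p$lstm, dims$h)
  c1 <- conv1d_forward(ls$H, p$conv1$W, p$conv1$b, model$cfg$kernel_len)
  a1 <- elu(c1$Y)
  q1 <- avgpool_forward(a1, model$cfg$pool_len[1])
  c2 <- conv1d_forward(q1, p$conv2$W, p$conv2$b, model$cfg$kernel_len)
  a2 <- elu(c2$Y)
  q2 <- avgpool_forward(a2, model$cfg$pool_len[2])
  A <- array(q2, c(B, C, dims$P2, dims$f2))
  dwY <- depthwise_forward(A, p$dw$W, p$dw$b)
  dwA <- elu(dwY)
  Fm <- matrix(0, B, dims$f2 * dims$m)
  for (l in seq_len(dims$P2)) Fm <- Fm + matrix(dwA[, l, ], B, ncol(Fm))
  Fm <- Fm / dims$P2
  mask <- NULL
  if (training && model$cfg$dropout_rate > 0) {
    keep <- 1 - model$cfg$dropout_rate
    mask <- matrix(stats::rbinom(length(Fm), 1L, keep) / keep,
                   nrow(Fm), ncol(Fm))
    Fm <- Fm * mask
  }
  list(features = Fm,
       cache = list(lstm = ls$cache, a1 = a1, Xc1 = c1$Xc, q1 = q1,
                    a2 = a2, Xc2 = c2$Xc, q2dim = dim(q2), A = A,
                    dwA = dwA, mask = mask, B = B,
                    dim_a1 = dim(a1), dim_a2 = dim(a2), dim_H = dim(ls$H)))
}

# backward from dF (B x feature_dim) to parameter gradients
#' @noRd
mcsnet_backward <- function(model, cache, dF) {
  dims <- model$dims; p <- model$params; cf <- model$cfg
  B <- cache$B; C <- dims$C
  if (!is.null(cache$mask)) dF <- dF * cache$mask
  dDwA <- array(0, c(B, dims$P2, dims$f2 * dims$m))
  for (l in seq_len(dims$P2)) dDwA[, l, ] <- dF / dims$P2
  dDwY <- dDwA * elu_grad_from_out(cache$dwA)
  dw <- depthwise_backward(dDwY, cache$A, p$dw$W)
  dQ2 <- array(dw$dA, cache$q2dim)                       # (B*C, P2, f2)
  dA2 <- avgpool_backward(dQ2, cf$pool_len[2], cache$dim_a2)
  dC2 <- dA2 * elu_grad_from_out(cache$a2)
  bw2 <- conv1d_backward(dC2, cache$Xc2, p$conv2$W, cf$kernel_len,
                         dim(cache$q1))
  dA1 <- avgpool_backward(bw2$dX, cf$pool_len[1], cache$dim_a1)
  dC1 <- dA1 * elu_grad_from_out(cache$a1)
  bw1 <- conv1d_backward(dC1, cache$Xc1, p$conv1$W, cf$kernel_len,
                         cache$dim_H)
  dlstm <- lstm_backward(bw1$dX, cache$lstm, p$lstm, dims$h)
  list(lstm = dlstm,
       conv1 = list(W = bw1$W, b = bw1$b),
       conv2 = list(W = bw2$W, b = bw2$b),
       dw = list(W = dw$W, b = dw$b))
}

#' Extract learned features from windows
#'
#' Runs the feature extractor in evaluation mode (deterministic, dropout
#' disabled). The input is not normalized internally; standardize
#' windows upstream (the training pipeline does this with
#' training-split statistics).
#'
#' @param model a built [build_mcsnet()] extractor.
#' @param windows a `window_set` or a C x W x B array.
#' @return numeric matrix, B x feature_dim.
#' @export
mcsnet_forward <- function(model, windows) {
  stopifnot(inherits(model, "mcsnet"))
  arr <- if (inherits(windows, "window_set")) windows$windows else windows
  if (!identical(dim(arr)[1:2], as.integer(model$input_shape)))
    stopf("window shape (%d x %d) does not match model input (%d x %d)",
          dim(arr)[1], dim(arr)[2], model$input_shape[1], model$input_shape[2])
  mcsnet_forward_cache(model, arr, training = FALSE)$features
}

#' Closed-form parameter count of a configuration
#'
#' `4h(d + h + 1) + f1(k h + 1) + f2(k f1 + 1) + f2 m (C + 1)` for frame
#' size d, hidden h, kernel k, filter counts f1/f2, C channels and
#' depthwise multiplier m.
#'
#' @param cfg a [mcsnet_config()].
#' @param input_shape `c(C, W)`.
#' @return integer parameter count.
#' @export
mcsnet_param_count <- function(cfg, input_shape = c(5L, 300L)) {
  C <- input_shape[1]; d <- cfg$frame_len; h <- cfg$lstm_hidden
  k <- cfg$kernel_len; f1 <- cfg$cnn1_filters; f2 <- cfg$cnn2_filters
  m <- cfg$depthwise_multiplier
  4L * h * (d + h + 1L) + f1 * (k * h + 1L) + f2 * (k * f1 + 1L) +
    f2 * m * (C + 1L)
}
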