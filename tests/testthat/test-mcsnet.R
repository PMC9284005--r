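tiny_cfg <- function() {
  mcsnet_config(lstm_hidden = 4L, cnn1_filters = 3L, cnn2_filters = 4L,
                kernel_len = 2L, depthwise_multiplier = 2L,
                pool_len = c(2L, 1L), dropout_rate = 0, frame_len = 5L)
}

test_that("forward pass satisfies the shape contract and is deterministic", {
  net <- build_mcsnet(mcsnet_config(), input_shape = c(5, 300), seed = 1)
  set.seed(2)
  arr <- array(rnorm(5 * 300 * 8), c(5, 300, 8))
  F1 <- mcsnet_forward(net, arr)
  expect_equal(dim(F1), c(8L, net$feature_dim))
  expect_true(all(is.finite(F1)))
  expect_equal(net$feature_dim, 64L)

  # identical builds from the same seed
  net2 <- build_mcsnet(mcsnet_config(), input_shape = c(5, 300), seed = 1)
  expect_identical(net$params, net2$params)

  # eval-mode forward is bitwise reproducible
  expect_identical(F1, mcsnet_forward(net, arr))

  # batch permutation permutes rows; identical windows give identical rows
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(mcsnet_forward(net, arr[, , perm]), F1[perm, ])
  dup <- arr[, , c(1, 1, 2)]
  Fd <- mcsnet_forward(net, dup)
  expect_equal(Fd[1, ], Fd[2, ])

  expect_error(mcsnet_forward(net, array(0, c(4, 300, 2))), "does not match")
})

test_that("parameter count matches the closed-form layer formulas", {
  cfg <- mcsnet_config()
  net <- build_mcsnet(cfg, input_shape = c(5, 300), seed = 3)
  h <- cfg$lstm_hidden; d <- cfg$frame_len; k <- cfg$kernel_len
  f1 <- cfg$cnn1_filters; f2 <- cfg$cnn2_filters; m <- cfg$depthwise_multiplier
  expected <- 4 * h * (d + h + 1) +      # LSTM: input, recurrent, bias
    f1 * (k * h + 1) +                   # temporal conv 1
    f2 * (k * f1 + 1) +                  # temporal conv 2
    f2 * m * (5 + 1)                     # depthwise across 5 channels
  expect_equal(net$param_count, expected)
  expect_equal(mcsnet_param_count(cfg, c(5, 300)), expected)
})

test_that("feature dimension is invariant to batch size but output scales with input", {
  net <- build_mcsnet(mcsnet_config(), input_shape = c(5, 300), seed = 1)
  set.seed(5)
  a1 <- array(rnorm(5 * 300 * 1), c(5, 300, 1))
  a9 <- array(rnorm(5 * 300 * 9), c(5, 300, 9))
  expect_equal(ncol(mcsnet_forward(net, a1)), ncol(mcsnet_forward(net, a9)))

  # no built-in input normalization: scaling the input changes the output
  f <- mcsnet_forward(net, a1)
  f1000 <- mcsnet_forward(net, a1 * 1000)
  expect_gt(max(abs(f - f1000)), 1e-3)
})

test_that("configuration errors are caught at build time", {
  expect_error(build_mcsnet(mcsnet_config(kernel_len = 50L),
                            input_shape = c(5, 300)), "kernel")
  expect_error(mcsnet_config(dropout_rate = 1), "dropout_rate")
})

test_that("analytic gradients match finite differences through all stages", {
  cfg <- tiny_cfg()
  net <- build_mcsnet(cfg, input_shape = c(3, 30), seed = 9)
  set.seed(10)
  arr <- array(rnorm(3 * 30 * 4), c(3, 30, 4))
  y <- c(1L, 2L, 1L, 2L)
  cw <- c(1, 1)
  D <- net$feature_dim
  set.seed(11)
  head <- list(W = matrix(rnorm(D * 2, sd = 0.3), D, 2), b = rnorm(2))

  loss_fn <- function(params) {
    m <- net; m$params <- params
    fw <- hcsnet:::mcsnet_forward_cache(m, arr, training = FALSE)
    logits <- sweep(fw$features %*% head$W, 2, head$b, "+")
    hcsnet:::softmax_xent(logits, y, cw)$loss
  }
  fw <- hcsnet:::mcsnet_forward_cache(net, arr, training = FALSE)
  logits <- sweep(fw$features %*% head$W, 2, head$b, "+")
  sx <- hcsnet:::softmax_xent(logits, y, cw)
  dF <- sx$dlogits %*% t(head$W)
  grads <- hcsnet:::mcsnet_backward(net, fw$cache, dF)

  eps <- 1e-6
  check <- function(path, idx) {
    p <- net$params
    g_analytic <- grads[[path[1]]][[path[2]]][idx]
    pp <- p; pp[[path[1]]][[path[2]]][idx] <- pp[[path[1]]][[path[2]]][idx] + eps
    pm <- p; pm[[path[1]]][[path[2]]][idx] <- pm[[path[1]]][[path[2]]][idx] - eps
    g_num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    expect_equal(g_analytic, g_num, tolerance = 1e-4)
  }
  set.seed(12)
  for (path in list(c("lstm", "Wx"), c("lstm", "Wh"), c("lstm", "b"),
                    c("conv1", "W"), c("conv1", "b"),
                    c("conv2", "W"), c("conv2", "b"),
                    c("dw", "W"), c("dw", "b"))) {
    n <- length(net$params[[path[1]]][[path[2]]])
    for (idx in sample.int(n, min(4L, n))) check(path, idx)
  }
})

test_that("gradients flow: extractor plus linear head learns a 2-class toy set", {
  ws <- toy_window_set(n_per_class = 100, C = 3, W = 90)
  cfg <- mcsnet_config(lstm_hidden = 8L, cnn1_filters = 8L, cnn2_filters = 8L,
                       kernel_len = 3L, pool_len = c(2L, 2L),
                       depthwise_multiplier = 2L, dropout_rate = 0,
                       frame_len = 5L)
  # train MCSNet + head alone (flat attention keeps fusion out of the loop is
  # not available here: use the full trainer but with handcrafted disabled by
  # a direct low-level loop on the learned branch)
  net <- build_mcsnet(cfg, input_shape = c(3, 90), seed = 1)
  y <- match(ws$meta$label, c("standing", "walking"))
  arr <- ws$windows
  D <- net$feature_dim
  set.seed(2)
  head <- list(W = matrix(0, D, 2), b = numeric(2))
  params <- list(net = net$params, head = head)
  opt <- hcsnet:::adam_init(params)
  acc <- 0
  for (epoch in 1:200) {
    fw <- hcsnet:::mcsnet_forward_cache(hcsnet:::model_with(net, params$net),
                                        arr, training = FALSE)
    logits <- sweep(fw$features %*% params$head$W, 2, params$head$b, "+")
    sx <- hcsnet:::softmax_xent(logits, y, c(1, 1))
    acc <- mean(apply(sx$probs, 1, which.max) == y)
    if (acc >= 0.95 && epoch > 5) break
    dF <- sx$dlogits %*% t(params$head$W)
    grads <- list(net = hcsnet:::mcsnet_backward(net, fw$cache, dF),
                  head = list(W = crossprod(fw$features, sx$dlogits),
                              b = colSums(sx$dlogits)))
    st <- hcsnet:::adam_step(params, grads, opt, lr = 3e-3)
    params <- st$params; opt <- st$state
  }
  expect_gte(acc, 0.95)
})
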