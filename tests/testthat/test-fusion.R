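test_that("feature concatenation preserves order and validates inputs", {
  set.seed(1)
  td <- matrix(rnorm(3 * 60), 3); fd <- matrix(rnorm(3 * 15), 3)
  le <- matrix(rnorm(3 * 64), 3)
  cf <- concat_features(td, fd, le)
  expect_equal(ncol(cf$f_fusion), 139L)
  expect_equal(unname(cf$block_sizes), c(60L, 15L, 64L))
  expect_equal(cf$f_fusion[, 1:60], td)
  expect_equal(cf$f_fusion[, 76:139], le)

  expect_error(concat_features(td[, 0], fd, le), "mandatory")
  expect_error(concat_features(td[1:2, ], fd, le), "different numbers")

  # injectivity: distinct inputs give distinct outputs
  td2 <- td; td2[1, 1] <- td2[1, 1] + 1
  expect_false(identical(concat_features(td2, fd, le)$f_fusion, cf$f_fusion))
})

test_that("channel attention gates with sigmoid weights in (0,1)", {
  gidx <- attention_groups(5, 60, 15, 64)
  expect_length(gidx, 139L)
  expect_equal(attr(gidx, "n_groups"), 74L)

  set.seed(2)
  f <- matrix(rnorm(4 * 139), 4)
  # zero-initialized MLP: all weights sigmoid(0) = 0.5
  G <- 74L; H <- G %/% 4L
  zero_par <- list(W1 = matrix(0, G, H), b1 = numeric(H),
                   W2 = matrix(0, H, G), b2 = numeric(G))
  at0 <- channel_attention(f, zero_par, gidx)
  expect_true(all(at0$weights == 0.5))
  expect_equal(at0$f_final, 0.5 * f)

  # random parameters: weights strictly inside (0,1), layout preserved
  set.seed(3)
  par <- list(W1 = matrix(rnorm(G * H, sd = 0.1), G, H), b1 = rnorm(H, sd = 0.1),
              W2 = matrix(rnorm(H * G, sd = 0.1), H, G), b2 = rnorm(G, sd = 0.1))
  at <- channel_attention(f, par, gidx)
  expect_true(all(at$weights > 0 & at$weights < 1))
  expect_equal(dim(at$f_final), dim(f))

  # a group whose elements are all zero stays zero after gating
  f0 <- f; f0[, 1:12] <- 0
  expect_true(all(channel_attention(f0, par, gidx)$f_final[, 1:12] == 0))

  # grouping must cover the vector exactly
  expect_error(channel_attention(f[, 1:100], par, gidx), "grouping covers")

  # flat mode: one group per element
  gflat <- attention_groups(5, 60, 15, 64, flat = TRUE)
  expect_equal(attr(gflat, "n_groups"), 139L)
})

test_that("linear + softmax head yields proper probabilities and argmax labels", {
  D <- 10L
  f <- matrix(rnorm(5 * D), 5)
  zero_head <- list(W = matrix(0, D, 3), b = numeric(3))
  out <- classify(f, zero_head)
  expect_true(all(abs(out$probabilities - 1 / 3) < 1e-12))

  # strong logit wins; ties break toward the lowest class index
  idhead <- list(W = matrix(0, D, 3), b = c(10, 0, 0))
  out2 <- classify(f, idhead)
  expect_true(all(out2$label == MOVEMENT_CLASSES[1]))
  expect_true(all(out2$probabilities[, 1] > 0.99))

  set.seed(4)
  rh <- list(W = matrix(rnorm(D * 3), D, 3), b = rnorm(3))
  out3 <- classify(f, rh)
  expect_equal(rowSums(out3$probabilities), rep(1, 5), tolerance = 1e-6)
  expect_error(classify(f[, 1:3], rh), "expects")
})

test_that("class weights follow the inverse-proportion, majority=1 rule", {
  w <- class_weights(rep(c("walk", "sit", "stand"), c(20, 10, 10)))
  expect_equal(w[["walk"]], 1); expect_equal(w[["sit"]], 2)
  expect_equal(w[["stand"]], 2)

  wb <- class_weights(rep(c("a", "b", "c"), each = 5))
  expect_true(all(wb == 1))

  w2 <- class_weights(rep(c("a", "b", "c"), c(30, 10, 60)))
  expect_equal(unname(w2[c("a", "b", "c")]), c(2, 6, 1))

  expect_error(class_weights(c("a", "a"), classes = c("a", "b")), "absent")
})

test_that("weighted and unweighted losses coincide on balanced batches", {
  set.seed(5)
  logits <- matrix(rnorm(12), 4, 3)
  y <- c(1L, 2L, 3L, 1L)
  l1 <- hcsnet:::softmax_xent(logits, y, c(1, 1, 1))
  l2 <- hcsnet:::softmax_xent(logits, y, c(2, 2, 2))
  expect_equal(l1$loss, l2$loss)
  expect_equal(l1$dlogits, l2$dlogits)
})

test_that("training honours the validation-stopping contract deterministically", {
  ws <- toy_window_set(n_per_class = 40)
  tr <- ws_trials(ws, c(1:30, 41:70))
  va <- ws_trials(ws, c(31:35, 71:75))
  cfg <- mcsnet_config(lstm_hidden = 6L, cnn1_filters = 6L, cnn2_filters = 6L,
                       kernel_len = 3L, pool_len = c(2L, 2L), frame_len = 6L,
                       depthwise_multiplier = 2L)
  tc <- train_config(max_epochs = 12L, seed = 5L, batch_size = 32L)
  fit <- train_hcsnet(tr, va, model_cfg = cfg, train_cfg = tc)

  h <- fit$history
  expect_equal(nrow(h), 12L)
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  expect_equal(fit$best_val_loss, min(h$val_loss))
  # loss decreases over the first epochs
  expect_lt(mean(h$train_loss[9:12]), mean(h$train_loss[1:3]))

  fit2 <- train_hcsnet(tr, va, model_cfg = cfg, train_cfg = tc)
  expect_equal(fit$history, fit2$history, tolerance = 1e-6)
  expect_equal(fit$params, fit2$params)

  expect_error(train_hcsnet(subset_windows(tr, 0), va, cfg, tc), "empty")
  one_class <- ws_trials(ws, 1:10)
  expect_error(train_hcsnet(one_class, va, cfg, tc), "single class")
})

test_that("prediction is deterministic and independent of batch composition", {
  ws <- toy_window_set(n_per_class = 30)
  tr <- ws_trials(ws, c(1:20, 31:50))
  va <- ws_trials(ws, c(21:25, 51:55))
  te <- ws_trials(ws, c(26:30, 56:60))
  cfg <- mcsnet_config(lstm_hidden = 6L, cnn1_filters = 6L, cnn2_filters = 6L,
                       kernel_len = 3L, pool_len = c(2L, 2L), frame_len = 6L)
  fit <- train_hcsnet(tr, va, model_cfg = cfg,
                      train_cfg = train_config(max_epochs = 20L, seed = 1L))
  p1 <- predict_hcsnet(fit, te)
  p2 <- predict_hcsnet(fit, te)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$probabilities), rep(1, n_windows(te)), tolerance = 1e-6)

  # single-window batch equals its row in the full batch
  single <- predict_hcsnet(fit, subset_windows(te, 3))
  expect_equal(single$probabilities[1, ], p1$probabilities[3, ],
               tolerance = 1e-6)

  # the toy classes are separable: the fused model should learn them
  expect_gte(mean(p1$label == te$meta$label), 0.9)
})

test_that("fused features are at least as informative as single sources", {
  ws <- toy_window_set(n_per_class = 40, seed = 19)
  tr <- ws_trials(ws, c(1:28, 41:68))
  va <- ws_trials(ws, c(29:32, 69:72))
  te <- ws_trials(ws, c(33:40, 73:80))
  cfg <- mcsnet_config(lstm_hidden = 6L, cnn1_filters = 6L, cnn2_filters = 6L,
                       kernel_len = 3L, pool_len = c(2L, 2L), frame_len = 6L)
  tc <- train_config(max_epochs = 25L, seed = 2L)

  fused <- train_hcsnet(tr, va, model_cfg = cfg, train_cfg = tc)
  acc_fused <- mean(predict_hcsnet(fused, te)$label == te$meta$label)

  # handcrafted-only route: LDA on the same features
  fc <- feature_config(fs_hz = ws$fs_hz)
  Xtr <- rbind(handcrafted_features(tr, fc), handcrafted_features(va, fc))
  ytr <- c(tr$meta$label, va$meta$label)
  Xte <- handcrafted_features(te, fc)
  hand <- fit_baseline("rbfsvm", Xtr, ytr)
  acc_hand <- mean(predict(hand, Xte) == te$meta$label)

  # learned-only route: classifier on the untrained extractor's features
  net <- build_mcsnet(cfg, input_shape = dim(ws$windows)[1:2], seed = 2)
  Ftr <- mcsnet_forward(net, combine_window_sets(list(tr, va)))
  Fte <- mcsnet_forward(net, te)
  learned <- fit_baseline("knn", Ftr, ytr)
  acc_learned <- mean(predict(learned, Fte) == te$meta$label)

  expect_gte(acc_fused, max(acc_hand, acc_learned) - 0.05)
})
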