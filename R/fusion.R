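# Feature fusion and classification: the hand-crafted blocks F_td, F_fd
# and the learned block F_learning are concatenated, gated by a
# channel-attention module (shared two-layer MLP over per-group average
# and max pools, sigmoid output, broadcast multiplicative weighting),
# and classified by a linear + softmax head. Trained end-to-end with
# Adam on class-weighted categorical cross-entropy with validation
# stopping; hand-crafted features enter as constants (no gradient into
# feature extraction).

#' Concatenate the three feature blocks
#'
#' Produces `F_fusion = [F_td | F_fd | F_learning]` for a batch of
#' windows. All three sources are mandatory and must describe the same
#' windows.
#'
#' @param td,fd,learned numeric matrices (rows = windows).
#' @return list with `f_fusion` (the concatenated matrix) and
#'   `block_sizes` (named lengths of the three blocks).
#' @export
concat_features <- function(td, fd, learned) {
  td <- as.matrix(td); fd <- as.matrix(fd); learned <- as.matrix(learned)
  if (ncol(td) == 0L || ncol(fd) == 0L || ncol(learned) == 0L)
    stopf("all three feature blocks are mandatory (got lengths %d, %d, %d)",
          ncol(td), ncol(fd), ncol(learned))
  if (length(unique(c(nrow(td), nrow(fd), nrow(learned)))) != 1L)
    stopf("feature blocks describe different numbers of windows (%d, %d, %d)",
          nrow(td), nrow(fd), nrow(learned))
  list(f_fusion = cbind(td, fd, learned),
       block_sizes = c(td = ncol(td), fd = ncol(fd), learned = ncol(learned)))
}

#' Attention-channel grouping of the fused vector
#'
#' Maps every element of the fused feature vector to an attention
#' channel: each sEMG channel's time-domain block is one group, each
#' sEMG channel's frequency-domain block is one group, and each learned
#' feature map is its own group (`5 + 5 + K` groups by default). With
#' `flat = TRUE` every element is its own channel (pooling degenerates
#' to identity).
#'
#' @param n_channels number of sEMG channels C.
#' @param n_td,n_fd,n_learned total lengths of the three blocks.
#' @param flat if `TRUE`, one group per element.
#' @return integer vector `gidx` of length `n_td + n_fd + n_learned`
#'   assigning each element to a group, with attribute `"n_groups"`.
#' @export
attention_groups <- function(n_channels, n_td, n_fd, n_learned, flat = FALSE) {
  D <- n_td + n_fd + n_learned
  if (flat) {
    gidx <- seq_len(D)
  } else {
    if (n_td %% n_channels != 0L || n_fd %% n_channels != 0L)
      stopf("block lengths (%d, %d) not divisible by %d channels",
            n_td, n_fd, n_channels)
    gidx <- c(rep(seq_len(n_channels), each = n_td / n_channels),
              n_channels + rep(seq_len(n_channels), each = n_fd / n_channels),
              2L * n_channels + seq_len(n_learned))
  }
  structure(gidx, n_groups = max(gidx))
}

#' @noRd
attention_init <- function(n_groups, reduction, seed) {
  hidden <- max(1L, n_groups %/% reduction)
  with_seed(seed, list(
    W1 = init_mat(n_groups, hidden, fan_in = n_groups), b1 = numeric(hidden),
    W2 = init_mat(hidden, n_groups, fan_in = hidden), b2 = numeric(n_groups)))
}

#' Channel-attention gating of a fused feature batch
#'
#' For each attention group g the weight is
#' `w_g = sigmoid(MLP(avg_g) + MLP(max_g))` with one shared two-layer
#' MLP (ELU inside), and the gated output multiplies every element of
#' group g by `w_g`, preserving the input layout.
#'
#' @param f_fusion numeric matrix, windows x fused features.
#' @param params attention parameter list (`W1`, `b1`, `W2`, `b2`).
#' @param gidx group assignment from [attention_groups()]; must cover
#'   every column of `f_fusion`.
#' @return list with `weights` (windows x groups, strictly in (0,1)) and
#'   `f_final` (same shape as `f_fusion`).
#' @export
channel_attention <- function(f_fusion, params, gidx) {
  out <- channel_attention_cache(f_fusion, params, gidx)
  list(weights = out$w, f_final = out$f_final)
}

#' @noRd
channel_attention_cache <- function(f, params, gidx) {
  if (length(gidx) != ncol(f))
    stopf("grouping covers %d elements but the fused vector has %d",
          length(gidx), ncol(f))
  B <- nrow(f); G <- attr(gidx, "n_groups")
  sz <- tabulate(gidx, G)
  if (any(sz == 0L)) stopf("empty attention group")
  groups <- split(seq_along(gidx), gidx)
  P_avg <- matrix(0, B, G); P_max <- matrix(0, B, G)
  amax <- matrix(1L, B, G)
  for (g in seq_len(G)) {
    cols <- groups[[g]]
    sub <- f[, cols, drop = FALSE]
    P_avg[, g] <- rowMeans(sub)
    j <- max.col(sub, ties.method = "first")
    amax[, g] <- cols[j]
    P_max[, g] <- sub[cbind(seq_len(B), j)]
  }
  h_avg_pre <- sweep(P_avg %*% params$W1, 2L, params$b1, "+")
  h_max_pre <- sweep(P_max %*% params$W1, 2L, params$b1, "+")
  h_avg <- elu(h_avg_pre); h_max <- elu(h_max_pre)
  z <- sweep(h_avg %*% params$W2, 2L, params$b2, "+") +
       sweep(h_max %*% params$W2, 2L, params$b2, "+")
  w <- sigmoid(z)
  Wexp <- w[, gidx, drop = FALSE]
  list(w = w, f_final = f * Wexp,
       cache = list(f = f, P_avg = P_avg, P_max = P_max, amax = amax,
                    h_avg = h_avg, h_max = h_max, w = w, Wexp = Wexp,
                    groups = groups, sz = sz, gidx = gidx))
}

#' @noRd
channel_attention_backward <- function(dF_final, cache, params) {
  f <- cache$f; B <- nrow(f); G <- ncol(cache$w)
  gidx <- cache$gidx
  # gate gradient: dw_g = sum_{d in g} dF * f
  prod <- dF_final * f
  dw <- matrix(0, B, G)
  for (g in seq_len(G))
    dw[, g] <- rowSums(prod[, cache$groups[[g]], drop = FALSE])
  dz <- dw * cache$w * (1 - cache$w)
  back_branch <- function(P, h) {
    dh <- dz %*% t(params$W2)
    dh_pre <- dh * elu_grad_from_out(h)
    list(dW2 = crossprod(h, dz), db2 = colSums(dz),
         dW1 = crossprod(P, dh_pre), db1 = colSums(dh_pre),
         dP = dh_pre %*% t(params$W1))
  }
  ba <- back_branch(cache$P_avg, cache$h_avg)
  bm <- back_branch(cache$P_max, cache$h_max)
  grads <- list(W1 = ba$dW1 + bm$dW1, b1 = ba$db1 + bm$db1,
                W2 = ba$dW2 + bm$dW2, b2 = ba$db2 + bm$db2)
  # input gradient: direct gating + avg path + max path
  df <- dF_final * cache$Wexp
  df <- df + sweep(ba$dP[, gidx, drop = FALSE], 2L, cache$sz[gidx], "/")
  for (g in seq_len(G))
    df[cbind(seq_len(B), cache$amax[, g])] <-
      df[cbind(seq_len(B), cache$amax[, g])] + bm$dP[, g]
  list(grads = grads, df_fusion = df)
}

#' Linear + softmax classification of fused features
#'
#' @param f_final numeric matrix, windows x features.
#' @param head list with weight matrix `W` (features x classes) and bias
#'   `b`.
#' @param classes character vector of class names (softmax column
#'   order).
#' @return list with `probabilities` (rows sum to 1) and `label`
#'   (argmax class, ties toward the lowest class index).
#' @export
classify <- function(f_final, head, classes = MOVEMENT_CLASSES) {
  if (ncol(f_final) != nrow(head$W))
    stopf("head expects %d features, got %d", nrow(head$W), ncol(f_final))
  P <- softmax_rows(sweep(f_final %*% head$W, 2L, head$b, "+"))
  colnames(P) <- classes
  list(probabilities = P,
       label = classes[apply(P, 1L, which.max)])
}

#' Inverse-proportion class weights
#'
#' `w_c = p_majority / p_c`: the inverse of each class's share of the
#' training data, scaled so the majority class has weight exactly 1.
#'
#' @param labels factor or character vector of training labels.
#' @param classes class universe; every class must be present.
#' @return named numeric weights in `classes` order.
#' @export
class_weights <- function(labels, classes = sort(unique(as.character(labels)))) {
  counts <- table(factor(as.character(labels), levels = classes))
  if (any(counts == 0L))
    stopf("class absent from training labels: %s",
          paste(names(counts)[counts == 0L], collapse = ", "))
  w <- max(counts) / as.numeric(counts)
  names(w) <- classes
  w
}

#' Training configuration for the fused model
#'
#' @param max_epochs maximum training epochs (validation stopping keeps
#'   the weights with the lowest validation loss seen).
#' @param lr Adam learning rate (Adam otherwise at default
#'   hyperparameters).
#' @param batch_size minibatch size.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param attention_reduction MLP bottleneck ratio of the attention
#'   module.
#' @param normalize_handcrafted z-score the hand-crafted blocks with
#'   statistics fit on the training split (applied to val/test).
#' @param patience epochs without sufficient validation-loss improvement
#'   before stopping early; `Inf` disables early stopping.
#' @param min_delta improvement in validation loss below which an epoch
#'   does not reset the patience counter (the best weights are still
#'   tracked exactly).
#' @param flat_attention treat every fused element as its own attention
#'   channel.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 1000L, lr = 1e-3, batch_size = 64L,
                         seed = 1L, attention_reduction = 4L,
                         normalize_handcrafted = TRUE, patience = Inf,
                         min_delta = 0, flat_attention = FALSE) {
  if (max_epochs < 1L) stopf("max_epochs must be >= 1")
  if (attention_reduction < 1L) stopf("attention_reduction must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 attention_reduction = as.integer(attention_reduction),
                 normalize_handcrafted = isTRUE(normalize_handcrafted),
                 patience = patience, min_delta = min_delta,
                 flat_attention = isTRUE(flat_attention)),
            class = "train_config")
}

#' @noRd
standardizer_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, sd = s)
}

#' @noRd
standardizer_apply <- function(X, st) sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")

# per-channel standardization stats of raw windows (train split)
#' @noRd
window_standardizer_fit <- function(arr) {
  C <- dim(arr)[1]
  mu <- numeric(C); s <- numeric(C)
  for (c in seq_len(C)) {
    v <- arr[c, , ]
    mu[c] <- mean(v); s[c] <- stats::sd(v)
    if (s[c] == 0 || !is.finite(s[c])) s[c] <- 1
  }
  list(mu = mu, sd = s)
}

#' @noRd
window_standardizer_apply <- function(arr, st) {
  (arr - st$mu) / st$sd   # recycles along the channel (first) dimension
}

#' @noRd
hcsnet_forward_cache <- function(params, model, Xhand, arr, gidx, training) {
  mc <- mcsnet_forward_cache(model_with(model, params$mcsnet), arr, training)
  ff <- cbind(Xhand, mc$features)
  at <- channel_attention_cache(ff, params$att, gidx)
  logits <- sweep(at$f_final %*% params$head$W, 2L, params$head$b, "+")
  list(logits = logits, mc = mc, at = at, n_hand = ncol(Xhand))
}

#' @noRd
model_with <- function(model, params) { model$params <- params; model }

#' Train the fused movement-prediction model
#'
#' End-to-end training of the learned extractor, attention fusion and
#' linear head with Adam on class-weighted categorical cross-entropy.
#' Hand-crafted features are computed once and enter as constants. After
#' every epoch the validation loss is evaluated; the returned model
#' carries the weights of the epoch with the lowest validation loss.
#'
#' @param train_ws,val_ws disjoint `window_set`s (validation is the
#'   stopping set, never the test set).
#' @param model_cfg a [mcsnet_config()].
#' @param train_cfg a [train_config()].
#' @param feature_cfg a [feature_config()].
#' @return object of class `hcsnet_model` with elements `params`,
#'   `history` (per-epoch train/val loss and accuracy), `best_epoch`,
#'   `classes`, normalization statistics and configurations.
#' @export
train_hcsnet <- function(train_ws, val_ws, model_cfg = mcsnet_config(),
                         train_cfg = train_config(),
                         feature_cfg = feature_config()) {
  stopifnot(inherits(train_ws, "window_set"), inherits(val_ws, "window_set"))
  if (n_windows(train_ws) == 0L || n_windows(val_ws) == 0L)
    stopf("empty training or validation split")
  classes <- MOVEMENT_CLASSES[MOVEMENT_CLASSES %in% train_ws$meta$label]
  if (length(classes) < 2L)
    stopf("training split contains a single class ('%s')", classes)
  y_tr <- match(train_ws$meta$label, classes)
  y_va <- match(val_ws$meta$label, classes)
  if (anyNA(y_va)) stopf("validation split contains unseen classes")

  fc <- feature_cfg; fc$fs_hz <- train_ws$fs_hz
  Xh_tr <- handcrafted_features(train_ws, fc)
  Xh_va <- handcrafted_features(val_ws, fc)
  n_td <- attr(Xh_tr, "n_td")
  hand_st <- standardizer_fit(Xh_tr)
  if (train_cfg$normalize_handcrafted) {
    Xh_tr <- standardizer_apply(Xh_tr, hand_st)
    Xh_va <- standardizer_apply(Xh_va, hand_st)
  }
  win_st <- window_standardizer_fit(train_ws$windows)
  A_tr <- window_standardizer_apply(train_ws$windows, win_st)
  A_va <- window_standardizer_apply(val_ws$windows, win_st)

  C <- dim(train_ws$windows)[1]
  net <- build_mcsnet(model_cfg, input_shape = dim(train_ws$windows)[1:2],
                      seed = train_cfg$seed)
  gidx <- attention_groups(C, n_td, ncol(Xh_tr) - n_td, net$feature_dim,
                           flat = train_cfg$flat_attention)
  G <- attr(gidx, "n_groups")
  D <- ncol(Xh_tr) + net$feature_dim
  params <- list(
    mcsnet = net$params,
    att = attention_init(G, train_cfg$attention_reduction, train_cfg$seed + 1L),
    head = with_seed(train_cfg$seed + 2L,
                     list(W = init_mat(D, length(classes), fan_in = D),
                          b = numeric(length(classes)))))
  cw <- class_weights(train_ws$meta$label, classes)
  opt <- adam_init(params)
  Ntr <- n_windows(train_ws)
  hist <- vector("list", train_cfg$max_epochs)
  best <- list(loss = Inf, epoch = 0L, params = params)
  improve_ref <- Inf; last_improve <- 0L

  eval_split <- function(par, Xh, A, y) {
    fw <- hcsnet_forward_cache(par, net, Xh, A, gidx, training = FALSE)
    sx <- softmax_xent(fw$logits, y, cw)
    list(loss = sx$loss, acc = mean(apply(sx$probs, 1L, which.max) == y))
  }

  with_seed(train_cfg$seed + 3L, {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(Ntr)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      for (idx in batches) {
        fw <- hcsnet_forward_cache(params, net, Xh_tr[idx, , drop = FALSE],
                                   A_tr[, , idx, drop = FALSE], gidx,
                                   training = TRUE)
        sx <- softmax_xent(fw$logits, y_tr[idx], cw)
        dF_final <- sx$dlogits %*% t(params$head$W)
        ab <- channel_attention_backward(dF_final, fw$at$cache, params$att)
        dLearned <- ab$df_fusion[, (fw$n_hand + 1L):ncol(ab$df_fusion),
                                 drop = FALSE]
        grads <- list(
          mcsnet = mcsnet_backward(net, fw$mc$cache, dLearned),
          att = ab$grads,
          head = list(W = crossprod(fw$at$f_final, sx$dlogits),
                      b = colSums(sx$dlogits)))
        st <- adam_step(params, grads, opt, lr = train_cfg$lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + sx$loss * length(idx)
        ep_n <- ep_n + length(idx)
        ep_correct <- ep_correct + sum(apply(sx$probs, 1L, which.max) == y_tr[idx])
      }
      va <- eval_split(params, Xh_va, A_va, y_va)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / ep_n,
                                  val_loss = va$loss,
                                  train_acc = ep_correct / ep_n,
                                  val_acc = va$acc)
      if (va$loss < best$loss)
        best <- list(loss = va$loss, epoch = epoch, params = params)
      if (va$loss < improve_ref - train_cfg$min_delta) {
        improve_ref <- va$loss; last_improve <- epoch
      }
      if (epoch - last_improve >= train_cfg$patience) break
    }
  })
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  structure(list(params = best$params, net = net, gidx = gidx,
                 classes = classes, class_weights = cw,
                 hand_st = hand_st, win_st = win_st,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 feature_cfg = fc, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "hcsnet_model")
}

#' @export
print.hcsnet_model <- function(x, ...) {
  cat(sprintf("<hcsnet_model> classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs, best epoch %d (val loss %.4f, val acc %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss,
              x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' Predict movement labels for a window set
#'
#' Deterministic evaluation-mode inference: per-window class
#' probabilities from the fused model, with the stored training-split
#' normalization applied to both the hand-crafted features and the raw
#' windows.
#'
#' @param model a trained [train_hcsnet()] model.
#' @param ws a `window_set` matching the training window shape.
#' @return list with `probabilities` (windows x classes) and `label`.
#' @export
predict_hcsnet <- function(model, ws) {
  stopifnot(inherits(model, "hcsnet_model"), inherits(ws, "window_set"))
  if (!identical(dim(ws$windows)[1:2], as.integer(model$net$input_shape)))
    stopf("window shape (%d x %d) does not match model input (%d x %d)",
          dim(ws$windows)[1], dim(ws$windows)[2],
          model$net$input_shape[1], model$net$input_shape[2])
  Xh <- handcrafted_features(ws, model$feature_cfg)
  if (model$train_cfg$normalize_handcrafted)
    Xh <- standardizer_apply(Xh, model$hand_st)
  A <- window_standardizer_apply(ws$windows, model$win_st)
  fw <- hcsnet_forward_cache(model$params, model$net, Xh, A, model$gidx,
                             training = FALSE)
  P <- softmax_rows(fw$logits)
  colnames(P) <- model$classes
  list(probabilities = P, label = model$classes[apply(P, 1L, which.max)])
}

#' Write a training history to CSV
#'
#' @param model a trained [train_hcsnet()] model.
#' @param path output CSV path (columns
#'   `epoch,train_loss,val_loss,train_acc,val_acc`).
#' @export
write_history <- function(model, path) {
  data.table::fwrite(model$history[, c("epoch", "train_loss", "val_loss",
                                       "train_acc", "val_acc")], path)
  invisible(path)
}
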