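# Minimal neural-network primitives (forward + analytic backward) used by
# the learned feature extractor and the fusion head. All layers operate
# on plain numeric matrices/arrays; training is driven by Adam on a flat
# named list of parameter arrays. Only what the model needs is
# implemented: LSTM, 1-D convolution (im2col), average pooling, a
# depthwise convolution across the sEMG-channel axis, ELU, dropout,
# softmax cross-entropy.

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
elu <- function(x, alpha = 1) {
  neg <- x < 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

# derivative of ELU expressed through its output y = elu(x)
#' @noRd
elu_grad_from_out <- function(y, alpha = 1) {
  neg <- y < 0
  y[!neg] <- 1
  y[neg] <- y[neg] + alpha
  y
}

# uniform fan-in initialization, the classic sqrt(1/fan_in) scheme
#' @noRd
init_mat <- function(nr, nc, fan_in = nr) {
  s <- sqrt(1 / fan_in)
  matrix(runif(nr * nc, -s, s), nr, nc)
}

## ---- LSTM (single layer, shared across sequences) -----------------------

#' @noRd
lstm_init <- function(d_in, h) {
  Wx <- init_mat(d_in, 4L * h)
  Wh <- init_mat(h, 4L * h, fan_in = h)
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1  # forget-gate bias 1 for stable early training
  list(Wx = Wx, Wh = Wh, b = b)
}

# X: (N, L, d) -> list(H = (N, L, h), cache)
#' @noRd
lstm_forward <- function(X, p, h_dim) {
  N <- dim(X)[1]; L <- dim(X)[2]
  h <- h_dim
  H <- array(0, c(N, L, h))
  gi <- array(0, c(N, L, h)); gf <- gi; gg <- gi; go <- gi
  Cs <- array(0, c(N, L, h))
  hprev <- matrix(0, N, h); cprev <- matrix(0, N, h)
  ii <- 1:h; fi <- (h + 1L):(2L * h); gix <- (2L * h + 1L):(3L * h)
  oi <- (3L * h + 1L):(4L * h)
  for (t in seq_len(L)) {
    z <- X[, t, , drop = FALSE]
    dim(z) <- c(N, dim(X)[3])
    a <- z %*% p$Wx + hprev %*% p$Wh
    a <- sweep(a, 2L, p$b, "+")
    i <- sigmoid(a[, ii, drop = FALSE]); f <- sigmoid(a[, fi, drop = FALSE])
    g <- tanh(a[, gix, drop = FALSE]);   o <- sigmoid(a[, oi, drop = FALSE])
    cc <- f * cprev + i * g
    hh <- o * tanh(cc)
    gi[, t, ] <- i; gf[, t, ] <- f; gg[, t, ] <- g; go[, t, ] <- o
    Cs[, t, ] <- cc; H[, t, ] <- hh
    hprev <- hh; cprev <- cc
  }
  list(H = H, cache = list(X = X, gi = gi, gf = gf, gg = gg, go = go, Cs = Cs))
}

# dH: (N, L, h) -> parameter gradients (input gradient not needed: the
# LSTM is the first trainable stage)
#' @noRd
lstm_backward <- function(dH, cache, p, h_dim) {
  X <- cache$X
  N <- dim(X)[1]; L <- dim(X)[2]; d <- dim(X)[3]; h <- h_dim
  dWx <- matrix(0, d, 4L * h); dWh <- matrix(0, h, 4L * h); db <- numeric(4L * h)
  dh_next <- matrix(0, N, h); dc_next <- matrix(0, N, h)
  ii <- 1:h; fi <- (h + 1L):(2L * h); gix <- (2L * h + 1L):(3L * h)
  oi <- (3L * h + 1L):(4L * h)
  for (t in seq(L, 1L)) {
    i <- cache$gi[, t, , drop = TRUE]; f <- cache$gf[, t, , drop = TRUE]
    g <- cache$gg[, t, , drop = TRUE]; o <- cache$go[, t, , drop = TRUE]
    cc <- cache$Cs[, t, , drop = TRUE]
    if (N == 1L) { dim(i) <- dim(f) <- dim(g) <- dim(o) <- dim(cc) <- c(1L, h) }
    tc <- tanh(cc)
    dh <- dh_next + matrix(dH[, t, ], N, h)
    dc <- dc_next + dh * o * (1 - tc^2)
    cprev <- if (t > 1L) matrix(cache$Cs[, t - 1L, ], N, h) else matrix(0, N, h)
    da <- matrix(0, N, 4L * h)
    da[, ii] <- dc * g * i * (1 - i)
    da[, fi] <- dc * cprev * f * (1 - f)
    da[, gix] <- dc * i * (1 - g^2)
    da[, oi] <- dh * tc * o * (1 - o)
    xt <- matrix(X[, t, ], N, d)
    hp <- if (t > 1L) matrix(cacheH(cache, t - 1L, N, h), N, h) else matrix(0, N, h)
    dWx <- dWx + crossprod(xt, da)
    dWh <- dWh + crossprod(hp, da)
    db <- db + colSums(da)
    dh_next <- da %*% t(p$Wh)
    dc_next <- dc * f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

#' @noRd
cacheH <- function(cache, t, N, h) {
  # recompute h_{t} from cached o and c (avoids storing H twice)
  o <- matrix(cache$go[, t, ], N, h)
  cc <- matrix(cache$Cs[, t, ], N, h)
  o * tanh(cc)
}

## ---- 1-D convolution along time via im2col ------------------------------

# X: (N, L, Cin), W: (k*Cin, Cout) with columns blocks ordered by tap
# position tau (Cin-contiguous within each tap); returns (N, L-k+1, Cout)
#' @noRd
conv1d_forward <- function(X, W, b, k) {
  N <- dim(X)[1]; L <- dim(X)[2]; Cin <- dim(X)[3]
  Lout <- L - k + 1L
  if (Lout < 1L) stopf("conv kernel (%d) longer than sequence (%d)", k, L)
  Xc <- matrix(0, N * Lout, k * Cin)
  for (tau in seq_len(k)) {
    sl <- X[, tau:(tau + Lout - 1L), , drop = FALSE]
    Xc[, ((tau - 1L) * Cin + 1L):(tau * Cin)] <- matrix(sl, N * Lout, Cin)
  }
  out <- sweep(Xc %*% W, 2L, b, "+")
  list(Y = array(out, c(N, Lout, ncol(W))), Xc = Xc)
}

#' @noRd
conv1d_backward <- function(dY, Xc, W, k, dimX) {
  N <- dimX[1]; L <- dimX[2]; Cin <- dimX[3]
  Lout <- dim(dY)[2]; Cout <- dim(dY)[3]
  dYm <- matrix(dY, N * Lout, Cout)
  dW <- crossprod(Xc, dYm)
  db <- colSums(dYm)
  dXc <- dYm %*% t(W)
  dX <- array(0, dimX)
  for (tau in seq_len(k)) {
    blk <- array(dXc[, ((tau - 1L) * Cin + 1L):(tau * Cin)], c(N, Lout, Cin))
    dX[, tau:(tau + Lout - 1L), ] <- dX[, tau:(tau + Lout - 1L), , drop = FALSE] + blk
  }
  list(dX = dX, W = dW, b = db)
}

## ---- average pooling along time (non-overlapping) -----------------------

#' @noRd
avgpool_forward <- function(X, p) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  Lout <- L %/% p
  Y <- array(0, c(N, Lout, C))
  for (q in seq_len(Lout)) {
    acc <- X[, (q - 1L) * p + 1L, , drop = FALSE]
    if (p > 1L) for (j in 2:p) acc <- acc + X[, (q - 1L) * p + j, , drop = FALSE]
    Y[, q, ] <- acc / p
  }
  Y
}

#' @noRd
avgpool_backward <- function(dY, p, dimX) {
  N <- dimX[1]; C <- dimX[3]
  Lout <- dim(dY)[2]
  dX <- array(0, dimX)
  for (q in seq_len(Lout)) {
    g <- array(dY[, q, ] / p, c(N, 1L, C))
    for (j in seq_len(p)) dX[, (q - 1L) * p + j, ] <- g
  }
  dX
}

## ---- depthwise convolution across the sEMG-channel axis -----------------

# A: (B, C, L, F); W: (C, F, m); kernel spans the full channel axis so
# each of the F feature maps is combined across muscles into m outputs.
# Returns (B, L, F*m).
#' @noRd
depthwise_forward <- function(A, W, b) {
  B <- dim(A)[1]; C <- dim(A)[2]; L <- dim(A)[3]; F <- dim(A)[4]
  m <- dim(W)[3]
  Y <- array(0, c(B, L, F * m))
  for (j in seq_len(F)) {
    Mj <- matrix(aperm(A[, , , j, drop = FALSE], c(1, 3, 2, 4)), B * L, C)
    Yj <- Mj %*% matrix(W[, j, ], C, m)
    Y[, , ((j - 1L) * m + 1L):(j * m)] <- array(Yj, c(B, L, m))
  }
  sweep(Y, 3L, b, "+")
}

#' @noRd
depthwise_backward <- function(dY, A, W) {
  B <- dim(A)[1]; C <- dim(A)[2]; L <- dim(A)[3]; F <- dim(A)[4]
  m <- dim(W)[3]
  dW <- array(0, dim(W)); dA <- array(0, dim(A))
  db <- numeric(F * m)
  for (j in seq_len(F)) {
    cols <- ((j - 1L) * m + 1L):(j * m)
    dYj <- matrix(dY[, , cols], B * L, m)
    Mj <- matrix(aperm(A[, , , j, drop = FALSE], c(1, 3, 2, 4)), B * L, C)
    dW[, j, ] <- crossprod(Mj, dYj)
    db[cols] <- colSums(dYj)
    dMj <- dYj %*% t(matrix(W[, j, ], C, m))
    dA[, , , j] <- aperm(array(dMj, c(B, L, C)), c(1, 3, 2))
  }
  list(dA = dA, W = dW, b = db)
}

## ---- softmax cross-entropy ----------------------------------------------

#' @noRd
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# weighted categorical cross-entropy; y: integer class 1..K; w: per-class
# weights. Returns loss (weighted mean NLL) and dlogits.
#' @noRd
softmax_xent <- function(logits, y, class_w) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  wi <- class_w[y]
  nll <- -log(pmax(P[cbind(seq_len(B), y)], 1e-12))
  loss <- sum(wi * nll) / sum(wi)
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ * (wi / sum(wi))
  list(loss = loss, dlogits = dZ, probs = P)
}

## ---- Adam ----------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  zero <- function(x) { x[] <- 0; x }
  list(m = rapply(params, zero, how = "replace"),
       v = rapply(params, zero, how = "replace"), t = 0L)
}

# params/grads: nested named lists of numeric arrays with identical shape
#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}
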