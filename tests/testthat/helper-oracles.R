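# independent naive-loop / DFT oracles, coded separately from the package

oracle_td <- function(x) {
  N <- length(x)
  mav <- sum(abs(x)) / N
  ssi <- 0; for (v in x) ssi <- ssi + v * v
  wl <- 0; for (i in 1:(N - 1)) wl <- wl + abs(x[i + 1] - x[i])
  zc <- 0
  for (i in 1:(N - 1)) if (x[i] * x[i + 1] < 0) zc <- zc + 1
  ssc <- 0
  if (N >= 3) for (i in 2:(N - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0) ssc <- ssc + 1
  c(MAV = mav, SSI = ssi, WL = wl, RMS = sqrt(ssi / N), ZC = zc, SSC = ssc)
}

oracle_fd <- function(x, fs) {
  N <- length(x)
  nb <- floor(N / 2) + 1
  P <- numeric(nb)
  for (j in 0:(nb - 1)) {   # brute-force DFT
    re <- sum(x * cos(-2 * pi * j * (0:(N - 1)) / N))
    im <- sum(x * sin(-2 * pi * j * (0:(N - 1)) / N))
    P[j + 1] <- (re^2 + im^2) / N
  }
  f <- (0:(nb - 1)) * fs / N
  cum <- cumsum(P)
  c(MNP = mean(P), PKF = f[which.max(P)],
    MDF = f[which(cum >= sum(P) / 2)[1]])
}

# Yule-Walker solved directly from the biased autocovariance system
oracle_ar <- function(x, p) {
  N <- length(x)
  r <- vapply(0:p, function(k) sum(x[1:(N - k)] * x[(1 + k):N]) / N, 0)
  R <- toeplitz(r[1:p])
  as.numeric(solve(R, r[2:(p + 1)]))
}
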