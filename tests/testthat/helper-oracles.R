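# Independent brute-force oracles used to cross-check the statistics
# implementations. These deliberately expand sums of squares explicitly
# and never share code with the package.

oracleAnova <- function(groups) {
  allv <- unlist(groups)
  grand <- mean(allv)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  dfb <- length(groups) - 1
  dfw <- length(allv) - length(groups)
  msb <- ssb / dfb
  msw <- ssw / dfw
  Fv <- msb / msw
  list(F = Fv, p = 1 - pf(Fv, dfb, dfw), msError = msw, dfError = dfw)
}

oraclePooledT <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

oracleIcc <- function(m) {
  # two-way decomposition via an explicit cell-by-cell expansion
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
    }
  }
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(
    single = (msr - mse) / (msr + (k - 1) * mse),
    average = (msr - mse) / msr
  )
}

oracleCohensD <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  (mean(x) - mean(y)) / sp
}

oraclePearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# tiny deterministic phantom settings shared by several test files
testPhantomConfig <- function(k = 1, seed = 5, size = 64L, ...) {
  phantomConfig(
    imageHeightPx = size, imageWidthPx = size,
    scTopDepthMm = 0.1, scThicknessMm = 0.08,
    kTrueNPerMm = k, seed = seed, ...
  )
}

testProtocol <- function(pressurePa = 2e4, ...) {
  airJetProtocol(preS = 1, onS = 1, postS = 1, pressurePa = pressurePa, ...)
}
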