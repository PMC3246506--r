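# Independent oracles, written as plain scalar loops so they share no code
# path with the package implementation.

# scalar forward pass over one weight vector and one (s1, s2) signal
oraclePerceptron <- function(w, s1, s2, omega = 4) {
  h <- (length(w) - 1) / 4
  sigma <- function(x) 1 / (1 + exp(-x))
  theta <- numeric(h)
  for (j in seq_len(h)) {
    w1 <- w[3 * (j - 1) + 1]
    w2 <- w[3 * (j - 1) + 2]
    bh <- w[3 * (j - 1) + 3]
    xi <- s1 * w1 + s2 * w2 - bh
    theta[j] <- sigma(omega * xi)
  }
  xiOut <- 0
  for (j in seq_len(h)) xiOut <- xiOut + theta[j] * w[3 * h + j]
  xiOut <- xiOut - w[length(w)]
  sigma(omega * xiOut)
}

# element-wise mean by explicit loop
oracleExpress <- function(h1, h2) {
  out <- numeric(length(h1))
  for (i in seq_along(h1)) out[i] <- (h1[i] + h2[i]) / 2
  out
}

# double-loop column totals
oracleNicheTotals <- function(e) {
  out <- numeric(ncol(e))
  for (k in seq_len(ncol(e)))
    for (i in seq_len(nrow(e)))
      out[k] <- out[k] + e[i, k]
  out
}

# the discriminator genome of the worked example: hidden node 1 switches at
# s1 = 0.3, giving rounded responses [1, 0, 0, 0] on the default signals
discriminatorWeights <- function() {
  w <- numeric(13)
  w[1] <- -20   # w11
  w[3] <- -6    # bh1
  w[10] <- 20   # wout1
  w[13] <- 10   # bo
  w
}
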