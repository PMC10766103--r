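# Independent brute-force oracles used to pin the spectral estimators.

# Literal triple-sum third-order cumulant (no mean subtraction).
brute_c3 <- function(x, L) {
  n <- length(x)
  out <- matrix(0, 2 * L + 1, 2 * L + 1)
  for (k in -L:L) for (l in -L:L) {
    s <- 0
    for (nn in seq_len(n)) {
      i1 <- nn + k; i2 <- nn + l
      if (i1 >= 1 && i1 <= n && i2 >= 1 && i2 <= n)
        s <- s + x[nn] * x[i1] * x[i2]
    }
    out[k + L + 1, l + L + 1] <- s / n
  }
  out
}

# Literal double-sum bispectrum on the fftshifted grid.
brute_bispectrum <- function(c3_values, max_lag, nfft) {
  f <- seq.int(-floor(nfft / 2), ceiling(nfft / 2) - 1) / nfft
  lags <- -max_lag:max_lag
  out <- matrix(0 + 0i, nfft, nfft)
  for (p in seq_len(nfft)) for (q in seq_len(nfft)) {
    e1 <- exp(-2i * pi * f[p] * lags)
    e2 <- exp(-2i * pi * f[q] * lags)
    out[p, q] <- sum(outer(e1, e2) * c3_values)
  }
  out
}

# Quadratically phase-coupled triple: components at 0.12, 0.18 and their sum
# 0.30, with the sum's phase locked to the pair.
qpc_signal <- function(n = 256, ph1, ph2, f1 = 0.12, f2 = 0.18) {
  t <- 0:(n - 1)
  cos(2 * pi * f1 * t + ph1) + cos(2 * pi * f2 * t + ph2) +
    cos(2 * pi * (f1 + f2) * t + ph1 + ph2)
}

# Argmax (row, col) of |BS| restricted to a mask.
masked_argmax <- function(grid, mask) {
  a <- abs(grid$values)
  a[!mask] <- -Inf
  arrayInd(which.max(a), dim(a))
}

# Small desk-scale configs shared across tests.
tiny_hos <- function() hos_config(window = 256, max_lag = 31, nfft = 64)
tiny_geom <- function() map_geometry(window = 256, hop = 128)

# Random (seeded) network samples with tiny images, for contract tests that
# do not need the phantom pipeline.
random_samples <- function(n, K = 4, hw = 16, seed = 0, shift = 0.15) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    y <- i %% 2
    list(x = lapply(seq_len(K), function(k)
           array(runif(hw * hw * 3) + shift * y, c(hw, hw, 3))),
         y = y, frame_id = sprintf("r%03d", i))
  })
}
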