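test_that("cumulant lattice matches the literal triple-sum oracle", {
  # tiny hand-checkable segment, mean subtraction off
  x <- c(1, 2, -1, 3)
  got <- estimate_c3(x, 1, demean = FALSE)$values
  expect_equal(got, brute_c3(x, 1), tolerance = 1e-14,
               ignore_attr = TRUE)
  # random segments at realistic sizes
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(64)
    got <- estimate_c3(x, 15, demean = FALSE)$values
    expect_equal(got, brute_c3(x, 15), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("cumulant lattice is symmetric under lag exchange and zero on silence", {
  z <- estimate_c3(numeric(256), 16)
  expect_true(all(z$values == 0))
  set.seed(1)
  c3 <- estimate_c3(rnorm(256), 20)
  expect_equal(c3$values, t(c3$values), tolerance = 1e-15)
  expect_equal(c3$values["3", "5"], c3$values["5", "3"], tolerance = 0)
  expect_error(estimate_c3(rnorm(16), 16), "max_lag")
})

test_that("indirect bispectrum equals the literal double sum on every bin", {
  for (n in c(32, 64)) {
    set.seed(n)
    x <- rnorm(n)
    L <- n / 4 - 1
    c3 <- estimate_c3(x, L)
    g <- bispectrum_indirect(c3, n)
    expect_lt(max(abs(g$values - brute_bispectrum(c3$values, L, n))), 1e-9)
  }
  # zero lattice -> zero grid; nfft validation
  zg <- bispectrum_indirect(estimate_c3(numeric(64), 10), 32)
  expect_true(all(zg$values == 0))
  expect_error(bispectrum_indirect(estimate_c3(rnorm(64), 10), 16), "nfft")
})

test_that("bispectrum inherits the frequency-exchange symmetry", {
  set.seed(2)
  g <- bispectrum_indirect(estimate_c3(rnorm(128), 31), 64)
  expect_lt(max(abs(g$values - t(g$values))), 1e-10)
})

test_that("principal domain matches exhaustive enumeration of its inequalities", {
  for (nfft in c(8, 16)) {
    m <- principal_domain(nfft)
    f <- seq.int(-nfft / 2, nfft / 2 - 1) / nfft
    count <- 0
    for (i in seq_len(nfft)) for (j in seq_len(nfft)) {
      inside <- f[j] >= 0 && f[j] <= f[i] && f[i] + f[j] <= 0.5
      if (inside) count <- count + 1
      expect_identical(m$S0[i, j], inside)
    }
    expect_equal(sum(m$S0), count)
  }
  # f2 > f1 always excluded
  m <- principal_domain(32)
  f <- m$freqs
  expect_false(any(m$S0 & outer(f, f, function(a, b) b > a)))
})

test_that("band subdivision partitions S0 into equal thirds of the split axis", {
  for (nfft in c(16, 64, 128)) {
    m <- subdivide_bands(principal_domain(nfft))
    expect_false(any(m$S1 & m$S2))
    expect_false(any(m$S1 & m$S3))
    expect_false(any(m$S2 & m$S3))
    expect_identical(m$S1 | m$S2 | m$S3, m$S0)
  }
  expect_equal(subdivide_bands(principal_domain(12))$band_edges,
               c(0, 1 / 6, 1 / 3, 1 / 2))
  # per-band cardinalities against exhaustive enumeration at nfft = 16
  m <- subdivide_bands(principal_domain(16))
  f <- m$freqs
  counts <- c(0, 0, 0)
  for (i in 1:16) for (j in 1:16) {
    if (!(f[j] >= 0 && f[j] <= f[i] && f[i] + f[j] <= 0.5)) next
    band <- if (f[i] < 1 / 6) 1 else if (f[i] < 1 / 3) 2 else 3
    counts[band] <- counts[band] + 1
  }
  expect_equal(c(sum(m$S1), sum(m$S2), sum(m$S3)), counts)
  # f2 split honors the alternative axis convention
  m2 <- subdivide_bands(principal_domain(16), split_axis = "f2")
  expect_identical(m2$S1 | m2$S2 | m2$S3, m2$S0)
  expect_false(identical(m2$S1, m$S1))
})

test_that("region energy sums squared magnitudes over the mask", {
  g <- structure(list(values = matrix(1 + 0i, 16, 16),
                      freqs = bisqus:::grid_freqs(16), nfft = 16L),
                 class = "bispectrum_grid")
  mask <- matrix(FALSE, 16, 16); mask[1:10] <- TRUE
  expect_equal(region_energy(g, mask), 10)
  expect_equal(region_energy(g, mask, "magnitude"), 10)
  g$values <- matrix(0 + 0i, 16, 16)
  expect_equal(region_energy(g, mask), 0)
  expect_error(region_energy(g, matrix(TRUE, 4, 4)), "shape")
})

test_that("band energies exactly partition the principal-domain energy", {
  cfg <- tiny_hos()
  for (seed in 1:5) {
    set.seed(seed)
    e <- segment_features(rnorm(256), cfg)
    expect_identical(unname(e["E_S1"] + e["E_S2"] + e["E_S3"]),
                     unname(e["E_S0"]))
    expect_true(all(e >= 0))
  }
  expect_equal(segment_features(numeric(256), cfg),
               c(E_S1 = 0, E_S2 = 0, E_S3 = 0, E_S0 = 0))
})

test_that("coupled bifrequencies land in the expected band", {
  # pair (0.12, 0.18): coupled bifrequency in the low-f1 band -> E_S1 wins
  set.seed(7)
  x <- qpc_signal(256, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
  e <- segment_features(x, hos_config(window = 256, max_lag = 63, nfft = 128))
  expect_gt(e["E_S1"], e["E_S3"])
  # high-frequency coupling at (0.35, 0.05): S3 peak
  set.seed(8)
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  t <- 0:255
  xh <- cos(2 * pi * 0.35 * t + ph1) + cos(2 * pi * 0.05 * t + ph2) +
    cos(2 * pi * 0.40 * t + ph1 + ph2)
  cfg <- hos_config(window = 256, max_lag = 63, nfft = 128)
  eh <- segment_features(xh, cfg)
  expect_gt(eh["E_S3"], 0)
  g <- bispectrum_indirect(estimate_c3(xh, 63), 128)
  m <- subdivide_bands(principal_domain(128))
  ij <- masked_argmax(g, m$S0)
  expect_true(m$S3[ij[1], ij[2]])
})

test_that("direct and indirect estimators agree on the coupling peak", {
  nfft <- 64
  m <- principal_domain(nfft)
  acc_d <- matrix(0 + 0i, nfft, nfft)
  acc_i <- matrix(0 + 0i, nfft, nfft)
  set.seed(11)
  for (r in 1:16) {
    x <- qpc_signal(4096, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    acc_d <- acc_d + bispectrum_direct(x, nfft, 64)$values
    acc_i <- acc_i + bispectrum_indirect(estimate_c3(x[1:256], 31), nfft)$values
  }
  gd <- structure(list(values = acc_d, freqs = m$freqs, nfft = nfft),
                  class = "bispectrum_grid")
  gi <- structure(list(values = acc_i, freqs = m$freqs, nfft = nfft),
                  class = "bispectrum_grid")
  expect_true(all(abs(masked_argmax(gd, m$S0) -
                      masked_argmax(gi, m$S0)) <= 1))
})

test_that("Gaussian noise has a far weaker bispectrum than coupled signal", {
  nfft <- 64
  m <- principal_domain(nfft)
  set.seed(12)
  xq <- qpc_signal(4096, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
  xn <- rnorm(4096, sd = sd(xq))  # equal power
  peak_q <- max(abs(bispectrum_direct(xq, nfft, 64)$values[m$S0]))
  peak_n <- max(abs(bispectrum_direct(xn, nfft, 64)$values[m$S0]))
  expect_gt(peak_q, 10 * peak_n)
  # zero signal -> zero grid
  expect_true(all(bispectrum_direct(numeric(256), 32, 4)$values == 0))
  expect_error(bispectrum_direct(rnorm(64), 32, 0), "n_blocks")
})
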