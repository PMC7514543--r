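# Mother wavelets and the continuous wavelet transform.

test_that("Morlet closed form: unit value at 0, Gaussian envelope, pure-tone limit", {
  expect_equal(morlet_timedomain(0, 1), 1 + 0i)
  expect_equal(abs(morlet_timedomain(1, sigma = 1)), exp(-0.5))
  expect_equal(abs(morlet_timedomain(0.7, sigma = 0.7)), exp(-0.5))
  # sigma -> infinity leaves the bare carrier: Re psi(1/4) = cos(pi/2) = 0
  expect_equal(Re(morlet_timedomain(0.25, sigma = 1e9)), 0, tolerance = 1e-12)
  expect_error(morlet_timedomain(0, sigma = -1), "sigma")
})

test_that("Mexican hat closed form: zero crossings at +/- sigma and zero integral", {
  expect_equal(mexican_hat_timedomain(0, 1), 1)
  expect_equal(mexican_hat_timedomain(c(-1, 1), sigma = 1), c(0, 0))
  expect_equal(mexican_hat_timedomain(c(-2.5, 2.5), sigma = 2.5), c(0, 0))
  tt <- seq(-40, 40, by = 1e-3)
  for (s in c(0.5, 1, 2)) {
    integral <- sum(mexican_hat_timedomain(tt, s)) * 1e-3
    expect_lt(abs(integral), 1e-6)
  }
  # Morlet admissibility at the default sigma: near-zero mean
  m <- abs(sum(morlet_timedomain(tt, 1)) * 1e-3)
  expect_lt(m, 1e-3)
})

test_that("Bump spectrum: unit peak, interior value, exact compact support", {
  expect_equal(bump_fourierdomain(5, mu = 5, sigma = 0.6), 1)
  expect_equal(bump_fourierdomain(5 + 0.3, mu = 5, sigma = 0.6), exp(-1 / 3))
  edges <- c(5 - 0.6, 5 + 0.6, 0, 4, 6, 100)
  expect_identical(bump_fourierdomain(edges, 5, 0.6), rep(0, length(edges)))
  expect_error(mother_wavelet("bump", sigma = 6, mu = 5), "support")
})

test_that("fast transform matches the Riemann-sum oracle on short signals", {
  fs <- 200
  t <- (0:199) / fs
  x <- sin(2 * pi * (6 * t + 8 * t^2))  # chirp 6 -> 22 Hz
  grid <- frequency_grid(8, 20, n = 3)  # 8, 14, 20 Hz
  freqs <- grid$freqs
  for (kind in c("morlet", "mexican_hat", "bump")) {
    w <- mother_wavelet(kind)
    sc <- cwt_forward(x, fs, grid, w, boundary = "zero")
    for (r in seq_along(freqs)) {
      o <- cwt_oracle(x, fs, freqs[r], w)
      expect_lt(max_rel_err(o, sc$coefficients[r, ]), 1e-6)
    }
  }
})

test_that("transform is linear and vanishes on the zero signal", {
  fs <- 250
  t <- (0:299) / fs
  g <- frequency_grid(8, 20, n = 5)
  w <- mother_wavelet("morlet")
  expect_true(all(cwt_forward(numeric(300), fs, g, w)$values == 0))
  x1 <- sin(2 * pi * 10 * t)
  x2 <- cos(2 * pi * 15 * t) * t
  c1 <- cwt_forward(x1, fs, g, w)$coefficients
  c2 <- cwt_forward(x2, fs, g, w)$coefficients
  c12 <- cwt_forward(x1 + x2, fs, g, w)$coefficients
  expect_equal(c12, c1 + c2, tolerance = 1e-10)
})

test_that("pure tones peak at the matching grid row for all wavelets", {
  fs <- 250
  t <- (0:499) / fs
  g <- frequency_grid(5, 35, step = 0.5)
  for (kind in c("morlet", "mexican_hat", "bump")) {
    w <- mother_wavelet(kind)
    for (f0 in c(8, 10, 13, 20, 30)) {
      sc <- cwt_forward(sin(2 * pi * f0 * t), fs, g, w)
      peak <- g$freqs[which.max(rowMeans(sc$values))]
      expect_lte(abs(peak - f0), 0.5)
    }
  }
})

test_that("scalogram magnitudes are shift-equivariant away from boundaries", {
  fs <- 250
  t <- (0:499) / fs
  set.seed(4)
  x <- as.vector(stats::filter(rnorm(500), rep(1, 5), sides = 2))
  x[is.na(x)] <- 0
  shift <- 60L
  xs <- c(x[(shift + 1):500], x[1:shift])
  g <- frequency_grid(8, 20, n = 4)
  w <- mother_wavelet("morlet")
  v1 <- cwt_forward(x, fs, g, w, boundary = "zero")$values
  v2 <- cwt_forward(xs, fs, g, w, boundary = "zero")$values
  inner <- 150:250  # columns well clear of both edges after the shift
  expect_equal(v2[, inner], v1[, inner + shift], tolerance = 1e-6)
})

test_that("a delta impulse reproduces the scaled wavelet shape", {
  fs <- 100
  x <- numeric(120)
  m0 <- 60L
  x[m0] <- 1
  w <- mother_wavelet("morlet")
  f <- 10
  s <- w$center_freq / f
  o <- cwt_oracle(x, fs, f, w)
  n_idx <- 30:90
  expected <- morlet_timedomain(((m0 - n_idx) / fs) / s, w$sigma) / (fs * s)
  expect_equal(o[n_idx], expected, tolerance = 1e-12)
})

test_that("frequency grid and transform inputs are validated", {
  expect_error(frequency_grid(0, 10, n = 5), "f_min")
  expect_error(frequency_grid(10, 5, n = 5), "f_min")
  expect_error(cwt_forward(sin(1:100), 100, frequency_grid(10, 60, n = 3),
                           mother_wavelet("morlet")), "Nyquist")
  expect_error(cwt_oracle(numeric(1000), 100, 10, mother_wavelet("morlet")),
               "short signals")
  expect_equal(length(mu_grid()$freqs), 26L)
  expect_equal(length(beta_grid()$freqs), 37L)
})

test_that("inverse transform recovers band-limited signals up to high correlation", {
  fs <- 250
  t <- (0:499) / fs
  g <- frequency_grid(2, 50, n = 64, spacing = "log")
  w <- mother_wavelet("morlet")
  tone <- sin(2 * pi * 10 * t)
  rec <- cwt_inverse(cwt_forward(tone, fs, g, w))
  expect_gt(stats::cor(rec, tone), 0.95)
  # band-passed noise within the grid band
  set.seed(8)
  bf <- signal::butter(4, c(8, 30) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, rnorm(500))
  rec2 <- cwt_inverse(cwt_forward(xb, fs, g, w))
  expect_gt(stats::cor(rec2, xb), 0.9)
  # zero scalogram -> zero signal
  z <- cwt_forward(numeric(500), fs, g, w)
  expect_equal(cwt_inverse(z), numeric(500))
  # sparse linear grid warns
  expect_warning(cwt_inverse(cwt_forward(tone, fs, frequency_grid(5, 15, n = 6),
                                         w)), "sparse|log")
})
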