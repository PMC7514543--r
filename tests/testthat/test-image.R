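# Time-frequency image construction.

test_that("band extraction selects the printed row counts and validates bounds", {
  fs <- 250
  t <- (0:499) / fs
  x <- sin(2 * pi * 10 * t)
  sc <- cwt_forward(x, fs, frequency_grid(0.5, 50, step = 0.1),
                    mother_wavelet("morlet"))
  mu <- extract_band(sc, 8, 13)
  expect_equal(nrow(mu$values), 51L)  # 0.1 Hz grid: 8.0 .. 13.0
  full <- extract_band(sc, 0.5, 50)
  expect_identical(full$values, sc$values)
  expect_error(extract_band(sc, 100, 110), "no rows")
  # the default mu grid reproduces the 26 x 500 band image
  sc26 <- cwt_forward(x, fs, mu_grid(), mother_wavelet("morlet"))
  expect_equal(dim(extract_band(sc26, 8, 13)$values), c(26L, 500L))
})

test_that("minimum-power window scan finds a planted power dip", {
  fs <- 250
  n <- 500
  tt <- (0:(n - 1)) / fs
  base <- matrix(1, 10, n)
  dip <- base
  dip[, tt >= 1.0 & tt < 1.5] <- 0.2  # ERD confined to 1.0-1.5 s
  bands <- list(fake_scalogram(dip, fs, "C3"),
                fake_scalogram(base, fs, "Cz"),
                fake_scalogram(dip, fs, "C4"))
  win <- select_min_power_window(bands, 0.5)
  expect_equal(win[2] - win[1] + 1L, 125L)  # 0.5 s at 250 Hz
  # overlap with the planted interval of at least 50%
  overlap <- sum(tt[win[1]:win[2]] >= 1.0 & tt[win[1]:win[2]] < 1.5) / 125
  expect_gte(overlap, 0.5)
  # agreement with a coarse-stride exhaustive scan
  w <- 125L
  sums <- vapply(seq(1L, n - w + 1L, by = 5L), function(s) {
    idx <- s:(s + w - 1L)
    sum(dip[, idx]) * 2 + sum(base[, idx])
  }, 0)
  coarse_start <- seq(1L, n - w + 1L, by = 5L)[which.min(sums)]
  expect_lte(abs(win[1] - coarse_start), 5L)
})

test_that("constant power ties break to the earliest window", {
  bands <- lapply(c("C3", "Cz", "C4"), function(ch)
    fake_scalogram(matrix(1, 5, 300), 250, ch))
  expect_equal(select_min_power_window(bands, 0.5)[1], 1L)
  expect_error(select_min_power_window(bands, 2), "does not fit")
})

test_that("cubic-spline resize is exact on identities, constants and ramps", {
  m <- matrix(rnorm(20 * 30), 20, 30)
  expect_equal(resize_spline(m, 20, 30), m, tolerance = 1e-10)
  expect_equal(resize_spline(matrix(3.5, 6, 125), 6, 32),
               matrix(3.5, 6, 32), tolerance = 1e-12)
  ramp <- matrix(rep(seq(0, 1, length.out = 125), each = 4), 4, 125)
  out <- resize_spline(ramp, 4, 32)
  expect_equal(out, matrix(rep(seq(0, 1, length.out = 32), each = 4), 4, 32),
               tolerance = 1e-10)
  expect_error(resize_spline(matrix(c(1, NA, 3, 4), 2), 2, 2), "non-finite")
})

test_that("dual-band image is 93 x 32 with 31-row electrode blocks and full row map", {
  p <- test_params(noise_sigma = 0.3)
  ep <- generate_epoch("left", p, seed = 5)
  sc <- micwt:::epoch_scalograms(ep, mother_wavelet("morlet"))
  img <- build_image_dual(sc$mu, sc$beta)
  expect_equal(dim(img$values), c(93L, 32L))
  expect_equal(nrow(img$row_map), 93L)
  expect_equal(as.vector(table(img$row_map$electrode)[c("C3", "Cz", "C4")]),
               c(31L, 31L, 31L))
  expect_equal(sum(img$row_map$band == "mu"), 45L)   # 15 rows x 3 electrodes
  expect_equal(sum(img$row_map$band == "beta"), 48L) # 16 rows x 3 electrodes
  # block order C3, Cz, C4 top to bottom; mu above beta within a block
  expect_equal(img$row_map$electrode[c(1, 32, 63)], c("C3", "Cz", "C4"))
  expect_equal(img$row_map$band[1:31], c(rep("mu", 15), rep("beta", 16)))
  # 2 s of task interval at 250 Hz gives the printed 500 scalogram columns
  expect_equal(ncol(sc$mu[[1]]$values), 500L)
})

test_that("mu-only image keeps native frequency rows (78 x 32 by default)", {
  p <- test_params(noise_sigma = 0.3)
  ep <- generate_epoch("right", p, seed = 6)
  sc <- micwt:::epoch_scalograms(ep, mother_wavelet("morlet"))
  img <- build_image_mu(sc$mu)
  expect_equal(dim(img$values), c(78L, 32L))
  expect_true(all(img$row_map$band == "mu"))
  zero_bands <- lapply(c("C3", "Cz", "C4"), function(ch)
    fake_scalogram(matrix(0, 26, 500), 250, ch))
  expect_true(all(build_image_mu(zero_bands)$values == 0))
})

test_that("image shape is invariant to the sampling rate", {
  p <- erd_params(fs = 128, duration_s = 8, cue_onset_s = 3,
                  noise_sigma = 0.3)
  ep <- generate_epoch("left", p, seed = 2)
  img <- epoch_to_image(ep)
  expect_equal(dim(img$values), c(93L, 32L))
})

test_that("constant scalograms propagate as constant image rows", {
  bands <- lapply(c("C3", "Cz", "C4"), function(ch)
    fake_scalogram(matrix(2, 26, 500), 250, ch))
  beta <- lapply(c("C3", "Cz", "C4"), function(ch)
    fake_scalogram(matrix(2, 37, 500), 250, ch))
  img <- build_image_dual(bands, beta)
  expect_equal(img$values, matrix(2, 93, 32), tolerance = 1e-12)
})

test_that("min-max normalisation maps to [0, 1] and is affine-invariant", {
  m <- matrix(rnorm(50), 10, 5)
  img <- micwt:::new_mi_image(m, data.frame(electrode = "C3", band = "mu",
                                            frequency = 1:10),
                              window = c(0, 1))
  n1 <- normalize_image(img)
  expect_equal(range(n1$values), c(0, 1))
  expect_true(n1$normalized)
  img2 <- img
  img2$values <- 3.7 * m + 11
  expect_equal(normalize_image(img2)$values, n1$values, tolerance = 1e-12)
  img3 <- img
  img3$values[] <- 5
  expect_warning(n3 <- normalize_image(img3), "constant")
  expect_true(all(n3$values == 0))
})

test_that("left-hand imagery leaves C4 mu rows weaker than C3 in the built image", {
  p <- test_params(noise_sigma = 0, erd_attenuation = 0.4)
  ep <- generate_epoch("left", p, seed = 9)
  img <- epoch_to_image(ep)
  mu_c4 <- img$values[img$row_map$electrode == "C4" & img$row_map$band == "mu", ]
  mu_c3 <- img$values[img$row_map$electrode == "C3" & img$row_map$band == "mu", ]
  expect_lt(mean(mu_c4), mean(mu_c3))
})

test_that("mismatched electrode sets are rejected", {
  bands <- lapply(c("C3", "C4", "Cz"), function(ch)
    fake_scalogram(matrix(1, 5, 300), 250, ch))
  expect_error(select_min_power_window(bands, 0.5), "C3, Cz, C4")
})
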