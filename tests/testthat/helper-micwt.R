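# Shared fixtures and oracles, built in code at test time.

## Short-epoch generator parameters: 5 s epochs keep filtering and CWT fast
## while preserving the 2 s analysis interval and a clean 1 s pre-cue
## baseline clear of filter edge transients.
test_params <- function(...) {
  erd_params(duration_s = 5, cue_onset_s = 2, task_window_s = c(0.5, 2.5), ...)
}

## Band-limited power of one channel over a time interval, via zero-phase
## Butterworth filtering -- the independent route used to verify the
## generator's amplitude bookkeeping.
band_power <- function(x, fs, band, t_lo, t_hi) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  tt <- (seq_along(x) - 1L) / fs
  mean(xf[tt >= t_lo & tt <= t_hi]^2)
}

## A scalogram-shaped object with prescribed magnitude values, for window
## selection tests that need exact control of the power landscape.
fake_scalogram <- function(values, fs = 250, channel = "C3", t0 = 0,
                           freqs = seq_len(nrow(values))) {
  structure(list(channel = channel, freqs = freqs,
                 times = t0 + (seq_len(ncol(values)) - 1L) / fs,
                 values = values, coefficients = values + 0i,
                 wavelet = mother_wavelet("morlet"), fs = fs,
                 grid_spacing = "linear"),
            class = "scalogram")
}

## Central finite-difference gradient of the CNN batch loss with respect to
## one named parameter block.
numeric_grad <- function(model, Zcat, y, name, eps = 1e-6) {
  w <- model[[name]]
  g <- w
  g[] <- 0
  for (i in seq_along(w)) {
    m1 <- model; m1[[name]][i] <- w[i] + eps
    m2 <- model; m2[[name]][i] <- w[i] - eps
    g[i] <- (micwt:::cnn_loss_grad(m1, Zcat, y)$loss -
             micwt:::cnn_loss_grad(m2, Zcat, y)$loss) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

## Linearly separable toy images: class "left" carries energy in the top
## rows, class "right" in the bottom rows, plus seeded noise.
toy_images <- function(n = 20, nv = 12, nt = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2 == 0) "left" else "right"
    m <- matrix(stats::runif(nv * nt, 0, 0.2), nv, nt)
    rows <- if (lab == "left") 1:(nv %/% 2) else (nv %/% 2 + 1):nv
    m[rows, ] <- m[rows, ] + 0.8
    micwt:::new_mi_image(m, data.frame(electrode = "C3", band = "mu",
                                       frequency = seq_len(nv)),
                         window = c(0, 1), label = lab)
  })
}
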