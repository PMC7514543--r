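# Mother wavelets and frequency grids.
#
# Three analysing wavelets are supported: Morlet and Mexican hat (Ricker),
# defined in the time domain, and the Bump wavelet, defined in the Fourier
# domain on the scaled angular frequency axis with compact support.

#' Construct a mother wavelet
#'
#' Builds a mother-wavelet descriptor used by [cwt_forward()] and friends.
#' The scale-to-frequency map is `f = center_freq / s`, where `center_freq`
#' is the peak response frequency of the wavelet at scale 1:
#' 1 Hz for the Morlet carrier, `sqrt(2) / (2 * pi * sigma)` for the
#' Mexican hat (the peak of its Fourier magnitude), and `mu / (2 * pi)` for
#' the Bump wavelet (its Fourier-domain peak at angular frequency `mu`).
#'
#' @param kind One of `"morlet"`, `"mexican_hat"`, `"bump"`.
#' @param sigma Shape parameter \eqn{\sigma > 0}. For Morlet and Mexican hat
#'   this is the Gaussian envelope width in seconds; for Bump it is the
#'   half-width of the compact Fourier support.
#' @param mu Peak angular frequency of the Bump wavelet (ignored otherwise).
#' @return An object of class `mother_wavelet` with fields `kind`, `sigma`,
#'   `mu` and `center_freq` (Hz at scale 1).
#' @examples
#' w <- mother_wavelet("morlet")
#' w$center_freq # 1 Hz carrier
#' @export
mother_wavelet <- function(kind = c("morlet", "mexican_hat", "bump"),
                           sigma = NULL, mu = 5) {
  kind <- match.arg(kind)
  if (is.null(sigma)) sigma <- if (kind == "bump") 0.6 else 1.0
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_input("sigma must be a positive scalar, got %s", format(sigma))
  if (kind == "bump") {
    if (!is.numeric(mu) || length(mu) != 1L || mu - sigma <= 0)
      stop_input("bump support [mu - sigma, mu + sigma] must be positive (mu = %s, sigma = %s)",
                 format(mu), format(sigma))
  }
  center_freq <- switch(kind,
    morlet      = 1,
    mexican_hat = sqrt(2) / (2 * pi * sigma),
    bump        = mu / (2 * pi)
  )
  structure(
    list(kind = kind, sigma = sigma,
         mu = if (kind == "bump") mu else NA_real_,
         center_freq = center_freq),
    class = "mother_wavelet"
  )
}

#' @export
print.mother_wavelet <- function(x, ...) {
  cat(sprintf("<mother_wavelet: %s, sigma = %g%s, center_freq = %g Hz>\n",
              x$kind, x$sigma,
              if (x$kind == "bump") sprintf(", mu = %g", x$mu) else "",
              x$center_freq))
  invisible(x)
}

#' Morlet wavelet in the time domain
#'
#' Evaluates \eqn{\psi(t) = e^{2\pi i t} e^{-t^2 / 2\sigma^2}}: a unit-frequency
#' complex carrier under a Gaussian envelope of width `sigma` seconds.
#'
#' @param t Time grid (s).
#' @param sigma Envelope width (s), must be positive.
#' @return Complex samples of the wavelet on `t`.
#' @export
morlet_timedomain <- function(t, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_input("sigma must be a positive scalar")
  exp(2i * pi * t) * exp(-t^2 / (2 * sigma^2))
}

#' Mexican hat (Ricker) wavelet in the time domain
#'
#' Evaluates \eqn{\psi(t) = (1 - t^2/\sigma^2) e^{-t^2 / 2\sigma^2}}, the
#' negated, normalised second derivative of a Gaussian. Its integral is zero
#' (admissibility) and it crosses zero exactly at \eqn{t = \pm\sigma}.
#'
#' @inheritParams morlet_timedomain
#' @return Real samples of the wavelet on `t`.
#' @export
mexican_hat_timedomain <- function(t, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_input("sigma must be a positive scalar")
  (1 - t^2 / sigma^2) * exp(-t^2 / (2 * sigma^2))
}

#' Bump wavelet in the Fourier domain
#'
#' Evaluates \eqn{\psi(sw) = \exp(1 - 1/(1 - (sw-\mu)^2/\sigma^2))} on the
#' scaled angular-frequency axis, and exactly 0 outside the compact support
#' \eqn{[\mu - \sigma, \mu + \sigma]} (indicator function). The value at
#' \eqn{sw = \mu} is 1.
#'
#' @param sw Scaled angular frequency grid (rad/s times scale).
#' @param mu Peak (support centre), must satisfy `mu - sigma > 0`.
#' @param sigma Support half-width.
#' @return Real spectral samples, zero outside the support.
#' @export
bump_fourierdomain <- function(sw, mu = 5, sigma = 0.6) {
  if (mu - sigma <= 0)
    stop_input("bump support [mu - sigma, mu + sigma] must be positive")
  u <- (sw - mu) / sigma
  out <- numeric(length(sw))
  inside <- abs(u) < 1
  out[inside] <- exp(1 - 1 / (1 - u[inside]^2))
  out
}

## Fourier transform psihat(w) of each mother wavelet at scale 1, with the
## convention psihat(w) = integral psi(t) exp(-i w t) dt. Closed forms for
## Morlet and Mexican hat; the Bump wavelet is defined here directly.
wavelet_fourier <- function(wavelet, w) {
  s <- wavelet$sigma
  switch(wavelet$kind,
    morlet      = sqrt(2 * pi) * s * exp(-s^2 * (w - 2 * pi)^2 / 2),
    mexican_hat = sqrt(2 * pi) * s^3 * w^2 * exp(-s^2 * w^2 / 2),
    bump        = bump_fourierdomain(w, wavelet$mu, wavelet$sigma)
  )
}

## Time-domain samples of the Bump wavelet by quadrature of the inverse
## Fourier integral over its compact support. The integrand is smooth and
## vanishes with all derivatives at the endpoints, so the trapezoid rule
## converges spectrally fast.
bump_timedomain <- function(t, mu = 5, sigma = 0.6, n_quad = 2001L) {
  w <- seq(mu - sigma, mu + sigma, length.out = n_quad)
  ph <- bump_fourierdomain(w, mu, sigma)
  dw <- w[2L] - w[1L]
  ## psi(t) = (1 / 2 pi) * int psihat(w) exp(-i w t) dw
  E <- exp(-1i * outer(t, w))
  as.vector(E %*% ph) * dw / (2 * pi)
}

## Sampled time-domain kernel psi(t / s) of a wavelet at scale s on a grid
## of sample offsets j = -J..J (dt = 1 / fs). Used by the spectral-
## convolution transform (Morlet, Mexican hat) and by the oracle.
wavelet_kernel <- function(wavelet, s, fs, J) {
  tt <- (-J:J) / (fs * s)
  switch(wavelet$kind,
    morlet      = morlet_timedomain(tt, wavelet$sigma),
    mexican_hat = mexican_hat_timedomain(tt, wavelet$sigma),
    bump        = bump_timedomain(tt, wavelet$mu, wavelet$sigma)
  )
}

## Half-width, in samples, at which the scaled kernel is numerically
## negligible. Gaussian-envelope wavelets die off at 8 sigma; the Bump
## wavelet decays only super-polynomially, so its support is taken wide.
kernel_halfwidth <- function(wavelet, s, fs) {
  mult <- switch(wavelet$kind,
    morlet = 8, mexican_hat = 8,
    bump = 320 / wavelet$sigma)
  as.integer(ceiling(mult * wavelet$sigma * s * fs))
}

#' Construct a frequency grid for the wavelet transform
#'
#' @param f_min,f_max Frequency bounds in Hz, `0 < f_min < f_max`.
#' @param n Number of grid points (mutually exclusive with `step`).
#' @param step Linear step in Hz (linear spacing only).
#' @param spacing `"linear"` or `"log"`.
#' @return Object of class `frequency_grid` with fields `freqs`, `spacing`,
#'   `f_min`, `f_max`.
#' @examples
#' length(frequency_grid(8, 13, step = 0.2)$freqs) # 26 mu-band bins
#' @export
frequency_grid <- function(f_min, f_max, n = NULL, step = NULL,
                           spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!(f_min > 0 && f_max > f_min))
    stop_input("need 0 < f_min < f_max, got [%g, %g]", f_min, f_max)
  if (is.null(n) && is.null(step))
    stop_input("one of n or step must be given")
  if (!is.null(step)) {
    if (spacing != "linear") stop_input("step applies to linear spacing only")
    freqs <- seq(f_min, f_max, by = step)
  } else if (spacing == "linear") {
    freqs <- seq(f_min, f_max, length.out = n)
  } else {
    freqs <- exp(seq(log(f_min), log(f_max), length.out = n))
  }
  if (anyDuplicated(freqs) || is.unsorted(freqs, strictly = TRUE))
    stop_input("frequency grid must be strictly ascending without duplicates")
  structure(list(freqs = freqs, spacing = spacing,
                 f_min = f_min, f_max = f_max),
            class = "frequency_grid")
}

#' Default mu-band grid: 8--13 Hz in 0.2 Hz steps (26 bins)
#' @return A [frequency_grid()].
#' @export
mu_grid <- function() frequency_grid(8, 13, step = 0.2)

#' Default beta-band grid: 37 linearly spaced bins over 13--30 Hz
#' @return A [frequency_grid()].
#' @export
beta_grid <- function() frequency_grid(13, 30, n = 37)
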