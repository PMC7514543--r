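# Continuous wavelet transform.
#
# The transform follows the correlation form
#   CWT(w, s) = (1 / |s|) * int x(t) psi((t - w) / s) dt
# with the scale of each analysis row tied to frequency by
# s = center_freq / f. Coefficients are evaluated at every sample position.
# Morlet and Mexican hat rows are computed by FFT convolution with the
# sampled, scaled time-domain kernel; Bump rows are computed natively in the
# Fourier domain, where that wavelet is defined. A direct Riemann-sum
# evaluation (cwt_oracle) serves as the reference implementation for short
# signals.

## Fold an arbitrary integer index onto 1..n by mirror reflection
## (whole-sample symmetric, period 2n - 2). Handles pads longer than n.
fold_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

## Precompute per-row transfer functions for a given signal length so that
## many signals on the same grid reuse the FFT kernels.
cwt_plan <- function(n, fs, grid, wavelet, boundary = "mirror") {
  freqs <- grid$freqs
  if (any(freqs > fs / 2))
    stop_input("grid frequency %g Hz above Nyquist (%g Hz)", max(freqs), fs / 2)
  if (any(freqs <= 0)) stop_input("grid frequencies must be positive")
  scales <- wavelet$center_freq / freqs
  J <- vapply(scales, function(s) kernel_halfwidth(wavelet, s, fs), integer(1))
  pad <- max(J)
  N2 <- stats::nextn(n + 2L * pad + 1L, c(2, 3, 5))
  H <- matrix(0i, nrow = N2, ncol = length(freqs))
  if (wavelet$kind == "bump") {
    k <- 0:(N2 - 1L)
    fk <- ifelse(k <= N2 / 2, k, k - N2) * fs / N2
    wk <- 2 * pi * fk
    for (r in seq_along(freqs))
      H[, r] <- wavelet_fourier(wavelet, scales[r] * wk)
  } else {
    for (r in seq_along(freqs)) {
      s <- scales[r]
      g <- wavelet_kernel(wavelet, s, fs, J[r])   # g[j], j = -J..J
      G <- complex(N2)
      jj <- -J[r]:J[r]
      ## place h[k] = g[-k] so circular convolution realises
      ## z[p] = sum_m x[m] g[m - p]
      G[((-jj) %% N2) + 1L] <- g
      H[, r] <- stats::fft(G) / (fs * s)
    }
  }
  list(n = n, fs = fs, freqs = freqs, scales = scales, pad = pad, N2 = N2,
       H = H, wavelet = wavelet, boundary = boundary, grid = grid)
}

## Apply a plan to one signal; returns the complex coefficient matrix
## (rows = frequencies, cols = sample positions).
cwt_apply <- function(plan, x) {
  n <- plan$n
  if (length(x) != n) stop_input("signal length %d does not match plan (%d)",
                                 length(x), n)
  xp <- numeric(plan$N2)
  xp[plan$pad + seq_len(n)] <- x
  if (plan$boundary == "mirror" && plan$pad > 0L) {
    left  <- fold_index(0L - (seq_len(plan$pad) - 1L), n)       # 0, -1, ...
    right <- fold_index(n + seq_len(plan$N2 - plan$pad - n), n) # n+1, n+2, ...
    xp[plan$pad:1L] <- x[left]
    xp[(plan$pad + n + 1L):plan$N2] <- x[right]
  }
  X <- stats::fft(xp)
  out <- matrix(0i, nrow = length(plan$freqs), ncol = n)
  sel <- plan$pad + seq_len(n)
  for (r in seq_along(plan$freqs)) {
    z <- stats::fft(X * plan$H[, r], inverse = TRUE) / plan$N2
    out[r, ] <- z[sel]
  }
  out
}

make_scalogram <- function(coef, freqs, fs, wavelet, grid,
                           channel = NA_character_, t0 = 0) {
  structure(
    list(channel = channel, freqs = freqs,
         times = t0 + (seq_len(ncol(coef)) - 1L) / fs,
         values = abs(coef), coefficients = coef,
         wavelet = wavelet, fs = fs, grid_spacing = grid$spacing),
    class = "scalogram")
}

#' Forward continuous wavelet transform
#'
#' Computes `CWT(w, s) = (1/|s|) * int x(t) psi((t - w)/s) dt` at every
#' sample position, for one scale per grid frequency (`s = center_freq / f`).
#' Morlet and Mexican hat rows use FFT convolution with the sampled scaled
#' kernel; Bump rows are evaluated in the Fourier domain. With this
#' normalisation the magnitude response to a pure tone peaks exactly at the
#' grid row matching the tone frequency.
#'
#' @param signal Real sample vector (length >= 2).
#' @param fs Sampling rate in Hz.
#' @param grid A [frequency_grid()]; all frequencies must lie in (0, fs/2].
#' @param wavelet A [mother_wavelet()].
#' @param boundary `"mirror"` (default) reflects the signal at its edges
#'   before convolution, suppressing wrap-around transients; `"zero"`
#'   extends with zeros, matching the Riemann-sum definition on a
#'   zero-extended signal (used when comparing against [cwt_oracle()]).
#' @param channel Optional channel name stored in the result.
#' @param t0 Time of the first sample (s), for the time axis metadata.
#' @return Object of class `scalogram`: fields `freqs`, `times`, `values`
#'   (magnitudes, rows = frequencies), `coefficients` (complex), `wavelet`,
#'   `fs`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 250))
#' sc <- cwt_forward(x, 250, frequency_grid(5, 15, step = 0.5),
#'                   mother_wavelet("morlet"))
#' sc$freqs[which.max(rowMeans(sc$values))] # 10 Hz
#' @export
cwt_forward <- function(signal, fs, grid, wavelet,
                        boundary = c("mirror", "zero"),
                        channel = NA_character_, t0 = 0) {
  boundary <- match.arg(boundary)
  if (length(signal) < 2L) stop_input("signal must have at least 2 samples")
  if (!inherits(grid, "frequency_grid")) stop_input("grid must be a frequency_grid")
  if (!inherits(wavelet, "mother_wavelet")) stop_input("wavelet must be a mother_wavelet")
  plan <- cwt_plan(length(signal), fs, grid, wavelet, boundary)
  coef <- cwt_apply(plan, as.numeric(signal))
  make_scalogram(coef, grid$freqs, fs, wavelet, grid, channel, t0)
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram: %s, %d freqs [%g, %g] Hz x %d samples @ %g Hz%s>\n",
              x$wavelet$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$values), x$fs,
              if (!is.na(x$channel)) paste0(", channel ", x$channel) else ""))
  invisible(x)
}

#' Direct Riemann-sum CWT at one frequency (reference implementation)
#'
#' Evaluates the transform definition by brute-force quadrature: for each
#' shift, the inner product of the zero-extended signal with the scaled,
#' shifted wavelet, times `dt / s`. Intended for short signals (at most
#' `2 * fs` samples) as an independent check of [cwt_forward()].
#' For the Bump wavelet the time-domain kernel is itself obtained by
#' numerical quadrature of the inverse Fourier integral, so the two routes
#' share no code path.
#'
#' @inheritParams cwt_forward
#' @param freq Analysis frequency in Hz.
#' @return Complex coefficient vector, one per sample position.
#' @export
cwt_oracle <- function(signal, fs, freq, wavelet) {
  n <- length(signal)
  if (n > 2 * fs)
    stop_input("cwt_oracle is for short signals (<= 2 * fs samples), got %d", n)
  if (freq <= 0 || freq > fs / 2) stop_input("freq must lie in (0, fs/2]")
  s <- wavelet$center_freq / freq
  kk <- (-(n - 1L)):(n - 1L)
  psi <- switch(wavelet$kind,
    morlet      = morlet_timedomain(kk / (fs * s), wavelet$sigma),
    mexican_hat = mexican_hat_timedomain(kk / (fs * s), wavelet$sigma),
    bump        = bump_timedomain(kk / (fs * s), wavelet$mu, wavelet$sigma)
  )
  M <- matrix(psi[outer(seq_len(n), seq_len(n), `-`) + n], n, n)
  as.vector(crossprod(M, as.complex(signal))) / (fs * s)
}

#' Inverse continuous wavelet transform (approximate)
#'
#' Reconstructs a band-limited signal from the complex coefficients of a
#' scalogram on a dense logarithmic frequency grid, by summing coefficients
#' over log-scale with the single-integral (delta) reconstruction and a
#' numerically computed admissibility constant. The inversion is a
#' discretised approximation: a signal whose spectrum lies inside the grid
#' is recovered up to small discretisation error (correlation, not
#' equality, is the appropriate check).
#'
#' @param scalogram A `scalogram` from [cwt_forward()] with complex
#'   coefficients on a log-spaced grid.
#' @return Real reconstructed sample vector.
#' @export
cwt_inverse <- function(scalogram) {
  if (!inherits(scalogram, "scalogram")) stop_input("need a scalogram")
  w <- scalogram$wavelet
  f <- scalogram$freqs
  if (!identical(scalogram$grid_spacing, "log") || length(f) < 16L)
    warning("reconstruction expects a dense log-spaced grid; result may be poor")
  dlns <- abs(mean(diff(log(f))))
  R <- colSums(scalogram$coefficients) * dlns
  bounds <- switch(w$kind,
    morlet      = c(max(1e-9, 2 * pi - 12 * max(1, 1 / w$sigma)), 2 * pi + 12 / w$sigma),
    mexican_hat = c(1e-9, 40 / w$sigma),
    bump        = c(w$mu - w$sigma, w$mu + w$sigma))
  K <- stats::integrate(function(u) wavelet_fourier(w, u) / u,
                        bounds[1], bounds[2], rel.tol = 1e-10)$value
  if (w$kind == "mexican_hat") Re(R) / K else 2 * Re(R) / K
}
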