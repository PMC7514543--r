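# Construction of the CNN input image from per-electrode scalograms.
#
# The pipeline: per electrode, mu (8-13 Hz) and beta (13-30 Hz) band
# scalograms of the 2 s task interval; the 0.5 s sub-window with the
# smallest total mu-band magnitude (summed over frequencies and all three
# electrodes) is selected; both bands are restricted to that window and
# resized by cubic-spline interpolation -- mu to 15 x 32 and beta to
# 16 x 32 so each electrode contributes a 31 x 32 block -- and the three
# electrode blocks are stacked vertically into a 93 x 32 image. A mu-only
# variant keeps the native frequency rows (26 at the default grid) and
# resizes the time axis only.

#' Extract a frequency band from a scalogram
#'
#' @param scalogram A `scalogram` from [cwt_forward()].
#' @param f_lo,f_hi Band edges in Hz (inclusive).
#' @return A `scalogram` restricted to rows with `f_lo <= f <= f_hi`,
#'   order preserved.
#' @export
extract_band <- function(scalogram, f_lo, f_hi) {
  if (!inherits(scalogram, "scalogram")) stop_input("need a scalogram")
  keep <- scalogram$freqs >= f_lo & scalogram$freqs <= f_hi
  if (!any(keep))
    stop_input("band [%g, %g] Hz selects no rows of grid [%g, %g] Hz",
               f_lo, f_hi, min(scalogram$freqs), max(scalogram$freqs))
  out <- scalogram
  out$freqs <- scalogram$freqs[keep]
  out$values <- scalogram$values[keep, , drop = FALSE]
  out$coefficients <- scalogram$coefficients[keep, , drop = FALSE]
  out
}

check_electrodes <- function(bands) {
  chs <- vapply(bands, `[[`, "", "channel")
  if (!identical(unname(chs), CHANNELS))
    stop_input("expected scalograms for electrodes C3, Cz, C4 in order, got: %s",
               paste(chs, collapse = ", "))
}

#' Select the minimum-power time window from mu-band scalograms
#'
#' Scans all contiguous windows of `win_s` seconds at stride 1 and returns
#' the one minimising total mu-band magnitude summed over frequencies and
#' electrodes; ties break toward the earliest start.
#'
#' @param mu_bands List of three band scalograms (C3, Cz, C4).
#' @param win_s Window length in seconds (default 0.5).
#' @return Integer vector `c(start, end)` of column indices (inclusive).
#' @export
select_min_power_window <- function(mu_bands, win_s = 0.5) {
  check_electrodes(mu_bands)
  fs <- mu_bands[[1L]]$fs
  n_col <- ncol(mu_bands[[1L]]$values)
  w <- round(win_s * fs)
  if (w < 1L || w > n_col)
    stop_input("window of %g s (%d columns) does not fit in %d columns",
               win_s, w, n_col)
  colpow <- Reduce(`+`, lapply(mu_bands, function(b) colSums(b$values)))
  cs <- c(0, cumsum(colpow))
  winsum <- cs[(w + 1L):(n_col + 1L)] - cs[1L:(n_col - w + 1L)]
  start <- which.min(winsum)  # first minimum = earliest tie-break
  c(start, start + w - 1L)
}

#' Resize a matrix by cubic-spline interpolation
#'
#' Interpolates independently along each axis onto uniformly spaced target
#' coordinates spanning the original extent. Cubic splines reproduce
#' constants and linear ramps exactly, and an identity resize returns the
#' input unchanged.
#'
#' @param m Real matrix, at least 2 x 2.
#' @param out_rows,out_cols Target dimensions (>= 1).
#' @return The resized `out_rows` x `out_cols` matrix.
#' @export
resize_spline <- function(m, out_rows, out_cols) {
  if (!is.matrix(m) || nrow(m) < 2L || ncol(m) < 2L)
    stop_input("input must be a matrix of at least 2 x 2")
  if (!all(is.finite(m))) stop_input("input contains non-finite values")
  if (out_rows < 1L || out_cols < 1L) stop_input("output dims must be >= 1")
  interp_axis <- function(mat, n_out) {
    n_in <- nrow(mat)
    if (n_out == n_in) return(mat)
    xout <- seq(1, n_in, length.out = n_out)
    apply(mat, 2L, function(col)
      stats::spline(seq_len(n_in), col, xout = xout, method = "fmm")$y)
  }
  m2 <- interp_axis(m, out_rows)
  if (!is.matrix(m2)) m2 <- matrix(m2, nrow = out_rows)
  m3 <- t(interp_axis(t(m2), out_cols))
  if (!is.matrix(m3)) m3 <- matrix(m3, nrow = out_rows)
  m3
}

## Interpolated frequency labels for resized rows.
resize_freqs <- function(freqs, n_out) {
  if (n_out == length(freqs)) return(freqs)
  stats::approx(seq_along(freqs), freqs,
                xout = seq(1, length(freqs), length.out = n_out))$y
}

new_mi_image <- function(values, row_map, window, label = NULL) {
  structure(list(values = values, row_map = row_map, window = window,
                 label = label, normalized = FALSE),
            class = "mi_image")
}

#' @export
print.mi_image <- function(x, ...) {
  cat(sprintf("<mi_image: %d x %d%s, window [%.2f, %.2f] s%s>\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) ", normalized" else "",
              x$window[1], x$window[2],
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Build the dual-band (mu + beta) CNN input image
#'
#' Selects the minimum-power 0.5 s window from the mu band, applies the
#' same window to beta, resizes mu to 15 x `nt_out` and beta to 16 x
#' `nt_out` (31 rows per electrode), and stacks the three electrode blocks
#' (C3, Cz, C4 top to bottom; mu above beta, frequencies ascending) into a
#' `93 x nt_out` image.
#'
#' @param mu_bands,beta_bands Lists of three band scalograms in electrode
#'   order C3, Cz, C4.
#' @param win_s Selected window length in seconds (default 0.5).
#' @param nt_out Output time columns (default 32).
#' @param label Optional class label carried on the image.
#' @return An `mi_image` of size `(31 * 3) x nt_out` with a complete
#'   `row_map` (electrode, band, frequency per row).
#' @export
build_image_dual <- function(mu_bands, beta_bands, win_s = 0.5,
                             nt_out = 32L, label = NULL) {
  check_electrodes(mu_bands)
  check_electrodes(beta_bands)
  win <- select_min_power_window(mu_bands, win_s)
  idx <- win[1L]:win[2L]
  blocks <- vector("list", 3L)
  maps <- vector("list", 3L)
  for (e in 1:3) {
    mu_m <- resize_spline(mu_bands[[e]]$values[, idx, drop = FALSE], 15L, nt_out)
    be_m <- resize_spline(beta_bands[[e]]$values[, idx, drop = FALSE], 16L, nt_out)
    blocks[[e]] <- rbind(mu_m, be_m)
    maps[[e]] <- data.frame(
      electrode = CHANNELS[e],
      band = c(rep("mu", 15L), rep("beta", 16L)),
      frequency = c(resize_freqs(mu_bands[[e]]$freqs, 15L),
                    resize_freqs(beta_bands[[e]]$freqs, 16L)))
  }
  tt <- mu_bands[[1L]]$times
  new_mi_image(do.call(rbind, blocks), do.call(rbind, maps),
               window = c(tt[win[1L]], tt[win[2L]]), label = label)
}

#' Build the mu-only CNN input image
#'
#' Same window selection and time resize as [build_image_dual()], but the
#' frequency axis is kept at the native mu grid so no frequency information
#' is lost: `(3 * n_mu_rows) x nt_out` (78 x 32 at the default grid).
#'
#' @inheritParams build_image_dual
#' @return An `mi_image`.
#' @export
build_image_mu <- function(mu_bands, win_s = 0.5, nt_out = 32L, label = NULL) {
  check_electrodes(mu_bands)
  win <- select_min_power_window(mu_bands, win_s)
  idx <- win[1L]:win[2L]
  blocks <- lapply(mu_bands, function(b)
    resize_spline(b$values[, idx, drop = FALSE], nrow(b$values), nt_out))
  maps <- lapply(1:3, function(e)
    data.frame(electrode = CHANNELS[e], band = "mu",
               frequency = mu_bands[[e]]$freqs))
  tt <- mu_bands[[1L]]$times
  new_mi_image(do.call(rbind, blocks), do.call(rbind, maps),
               window = c(tt[win[1L]], tt[win[2L]]), label = label)
}

#' Min-max normalise an image to [0, 1]
#'
#' @param img An `mi_image`.
#' @return The image rescaled so its minimum is 0 and maximum 1, with the
#'   `normalized` flag set. A constant image becomes all zeros with a
#'   warning.
#' @export
normalize_image <- function(img) {
  if (!inherits(img, "mi_image")) stop_input("need an mi_image")
  rng <- range(img$values)
  if (rng[2] > rng[1]) {
    img$values <- (img$values - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("constant image: normalised to all zeros")
    img$values[] <- 0
  }
  img$normalized <- TRUE
  img
}

#' Compute per-electrode band scalograms and the CNN image for one epoch
#'
#' Convenience wrapper over [cwt_forward()], [extract_band()] and the image
#' builders: cuts the task interval from the epoch, transforms each channel
#' on the mu and beta grids, and builds the (normalised) image.
#'
#' @param epoch An `eeg_epoch`.
#' @param wavelet A [mother_wavelet()].
#' @param variant `"dual"` (93 x 32) or `"mu"` (78 x 32 at default grid).
#' @param task_window_s Analysis interval relative to the cue (s).
#' @param win_s Selected window length (s).
#' @param normalize Min-max normalise the result (default TRUE).
#' @return An `mi_image` carrying the epoch's label.
#' @export
epoch_to_image <- function(epoch, wavelet = mother_wavelet("morlet"),
                           variant = c("dual", "mu"),
                           task_window_s = c(0.5, 2.5), win_s = 0.5,
                           normalize = TRUE) {
  variant <- match.arg(variant)
  sc <- epoch_scalograms(epoch, wavelet, task_window_s)
  img <- if (variant == "dual") {
    build_image_dual(sc$mu, sc$beta, win_s, label = epoch$label)
  } else {
    build_image_mu(sc$mu, win_s, label = epoch$label)
  }
  if (normalize) img <- normalize_image(img)
  img
}

## Task-interval mu/beta scalograms for the three channels of one epoch.
## `plans`, when given, carries precomputed FFT kernels (see build_images).
epoch_scalograms <- function(epoch, wavelet, task_window_s = c(0.5, 2.5),
                             plans = NULL) {
  fs <- epoch$fs
  i0 <- round((epoch$cue_onset_s + task_window_s[1]) * fs) + 1L
  n_task <- round((task_window_s[2] - task_window_s[1]) * fs)
  idx <- i0:(i0 + n_task - 1L)
  if (idx[1L] < 1L || idx[length(idx)] > nrow(epoch$data))
    stop_input("task interval outside the epoch")
  if (is.null(plans)) {
    plans <- list(mu = cwt_plan(n_task, fs, mu_grid(), wavelet),
                  beta = cwt_plan(n_task, fs, beta_grid(), wavelet))
  }
  t0 <- (idx[1L] - 1L) / fs
  one <- function(plan, ch) {
    coef <- cwt_apply(plan, epoch$data[idx, ch])
    make_scalogram(coef, plan$freqs, fs, plan$wavelet, plan$grid,
                   channel = ch, t0 = t0)
  }
  list(mu = lapply(CHANNELS, function(ch) one(plans$mu, ch)),
       beta = if (!is.null(plans$beta))
         lapply(CHANNELS, function(ch) one(plans$beta, ch)))
}

#' Build CNN input images for every epoch of a set
#'
#' FFT kernels are computed once and reused across trials.
#'
#' @param epochs An `epoch_set`.
#' @inheritParams epoch_to_image
#' @return List of `mi_image`, one per epoch, each carrying its label.
#' @export
build_images <- function(epochs, wavelet = mother_wavelet("morlet"),
                         variant = c("dual", "mu"),
                         task_window_s = c(0.5, 2.5), win_s = 0.5,
                         normalize = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$epochs[[1L]]$fs
  n_task <- round((task_window_s[2] - task_window_s[1]) * fs)
  plans <- list(mu = cwt_plan(n_task, fs, mu_grid(), wavelet),
                beta = if (variant == "dual")
                  cwt_plan(n_task, fs, beta_grid(), wavelet))
  lapply(epochs$epochs, function(ep) {
    sc <- epoch_scalograms(ep, wavelet, task_window_s, plans)
    img <- if (variant == "dual") {
      build_image_dual(sc$mu, sc$beta, win_s, label = ep$label)
    } else {
      build_image_mu(sc$mu, win_s, label = ep$label)
    }
    if (normalize) img <- normalize_image(img)
    img
  })
}
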