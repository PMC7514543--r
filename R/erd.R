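# ERD/ERS quantification.
#
# Band power averaged over trials is referenced to a pre-cue baseline:
#   avg(j) = (1/N) sum_i s_ij^2        (s_ij band-pass filtered trials)
#   ref    = (1/k) sum_{j in ref} avg(j)
#   ERD/ERS(%) = 100 * (avg(j) - ref) / ref
# Negative values are desynchronization (power loss), positive values
# synchronization. Filtering is zero-phase (forward-backward 4th-order
# Butterworth) so ERD latencies are not shifted.

band_limits <- function(band) {
  if (is.character(band)) {
    band <- switch(match.arg(band, c("mu", "beta", "mu+beta")),
                   "mu" = c(8, 13), "beta" = c(13, 30), "mu+beta" = c(8, 30))
  }
  if (length(band) != 2L || band[1] >= band[2])
    stop_input("band must be (f_lo, f_hi) with f_lo < f_hi")
  band
}

bandpass <- function(x, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Trial-averaged band power per channel
#'
#' Band-pass filters every trial to `band`, squares the samples, and
#' averages across trials at each time index.
#'
#' @param epochs An `epoch_set` (all epochs share fs and length).
#' @param band `"mu"`, `"beta"`, `"mu+beta"`, a numeric `(f_lo, f_hi)` in
#'   Hz, or `NULL` to skip filtering (power of the raw samples).
#' @return List with `power` (samples x channels matrix), `times`,
#'   `channels`, `fs`, `n_trials`.
#' @export
average_power <- function(epochs, band = "mu") {
  if (!inherits(epochs, "epoch_set") || length(epochs$epochs) < 1L)
    stop_input("epochs must be a non-empty epoch_set")
  if (!is.null(band)) {
    band <- band_limits(band)
    fs <- epochs$epochs[[1L]]$fs
    if (band[2] > fs / 2) stop_input("band above Nyquist")
  }
  n <- nrow(epochs$epochs[[1L]]$data)
  acc <- matrix(0, n, 3L, dimnames = list(NULL, CHANNELS))
  for (ep in epochs$epochs) {
    for (ch in CHANNELS) {
      x <- ep$data[, ch]
      if (!is.null(band)) x <- bandpass(x, band, ep$fs)
      acc[, ch] <- acc[, ch] + x^2
    }
  }
  fs <- epochs$epochs[[1L]]$fs
  list(power = acc / length(epochs$epochs),
       times = (seq_len(n) - 1L) / fs, channels = CHANNELS,
       fs = fs, n_trials = length(epochs$epochs))
}

#' Reference power over a baseline interval
#'
#' @param avg_power Numeric power time series.
#' @param ref_interval `(start, end)` in seconds, inclusive.
#' @param times Time stamps of the series (s); defaults to sample index
#'   seconds starting at 0 are not assumed -- supply `fs` instead to derive
#'   them.
#' @param fs Sampling rate, used to derive `times` when not given.
#' @return Scalar mean of the series over the interval.
#' @export
reference_power <- function(avg_power, ref_interval, times = NULL, fs = NULL) {
  if (is.null(times)) {
    if (is.null(fs)) stop_input("supply times or fs")
    times <- (seq_along(avg_power) - 1L) / fs
  }
  keep <- times >= ref_interval[1] & times <= ref_interval[2]
  if (!any(keep)) stop_input("reference interval [%g, %g] s selects no samples",
                             ref_interval[1], ref_interval[2])
  mean(avg_power[keep])
}

#' Relative power change in percent
#'
#' @param avg_power Power time series.
#' @param ref_power Positive scalar baseline power.
#' @return `100 * (avg_power - ref_power) / ref_power` per time index.
#' @export
erd_ers_percent <- function(avg_power, ref_power) {
  if (!is.numeric(ref_power) || length(ref_power) != 1L || ref_power <= 0)
    stop_input("ref_power must be a positive scalar")
  100 * (avg_power - ref_power) / ref_power
}

#' ERD/ERS time course per channel
#'
#' Composes [average_power()], smoothing, [reference_power()] and
#' [erd_ers_percent()] for each channel. The default reference interval is
#' the 1 s window ending 0.5 s before the cue.
#'
#' @inheritParams average_power
#' @param ref_interval `(start, end)` of the baseline in epoch seconds;
#'   default `cue - 1.5` to `cue - 0.5`.
#' @param smooth_s Length of the centred moving-average smoother applied to
#'   the average power before referencing (s); 0 disables smoothing.
#' @return Named list (C3, Cz, C4) of `erd_curve` objects with fields
#'   `channel`, `band`, `times`, `values` (%), `ref_interval`, `n_trials`.
#' @examples
#' set <- generate_dataset(8, params = erd_params(noise_sigma = 0), seed = 1)
#' curves <- erd_timecourse(set, band = "mu")
#' @export
erd_timecourse <- function(epochs, band = "mu", ref_interval = NULL,
                           smooth_s = 0.25) {
  ap <- average_power(epochs, band)
  cue <- epochs$epochs[[1L]]$cue_onset_s
  if (is.null(ref_interval)) ref_interval <- c(cue - 1.5, cue - 0.5)
  k <- max(1L, round(smooth_s * ap$fs))
  band_num <- if (is.null(band)) c(NA_real_, NA_real_) else band_limits(band)
  out <- lapply(CHANNELS, function(ch) {
    sm <- moving_average(ap$power[, ch], k)
    ref <- reference_power(sm, ref_interval, times = ap$times)
    structure(list(channel = ch, band = band_num, times = ap$times,
                   values = erd_ers_percent(sm, ref),
                   ref_interval = ref_interval, n_trials = ap$n_trials),
              class = "erd_curve")
  })
  names(out) <- CHANNELS
  out
}

#' @export
print.erd_curve <- function(x, ...) {
  cat(sprintf("<erd_curve: %s, band [%g, %g] Hz, %d trials, range [%.1f, %.1f]%%>\n",
              x$channel, x$band[1], x$band[2], x$n_trials,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Mean ERD/ERS over the task window
#'
#' Summarises an ERD curve as its mean percent change over an interval,
#' typically the imagery task window (with a margin inside the amplitude
#' ramps).
#'
#' @param curve An `erd_curve`.
#' @param interval `(start, end)` in epoch seconds.
#' @return Scalar mean percent change.
#' @export
erd_task_mean <- function(curve, interval) {
  keep <- curve$times >= interval[1] & curve$times <= interval[2]
  if (!any(keep)) stop_input("interval selects no samples")
  mean(curve$values[keep])
}
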