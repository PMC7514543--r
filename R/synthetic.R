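# Synthetic motor-imagery EEG.
#
# Three-channel (C3, Cz, C4) epochs carrying a controllable, lateralised
# event-related desynchronization: band-limited mu and beta oscillators with
# random phase ride on 1/f (pink) background noise. During the cued task
# window the oscillator amplitude on the channel contralateral to the
# imagined hand is multiplied by `erd_attenuation` (amplitude factor, so
# band power scales with its square); after the task window an optional
# rebound factor `ers_rebound` models event-related synchronization.
# Amplitude transitions use 0.1 s raised-cosine ramps to avoid the
# broadband splatter a step modulation would inject into the beta band.

CHANNELS <- c("C3", "Cz", "C4")
RAMP_S <- 0.1

#' Parameters of the synthetic ERD/ERS epoch generator
#'
#' Defaults mirror a standard cued motor-imagery protocol at 250 Hz: 8 s
#' epochs, visual cue at 3 s, imagery analysed 0.5--2.5 s after the cue.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Epoch length (s).
#' @param cue_onset_s Cue time within the epoch (s).
#' @param task_window_s Length-2 vector: start and end of the imagery
#'   interval relative to the cue (s).
#' @param mu_freq,beta_freq Centre frequencies of the mu and beta
#'   oscillators (Hz).
#' @param mu_amp,beta_amp Baseline oscillator amplitudes (arbitrary units;
#'   beta is weaker by default, as in real sensorimotor EEG).
#' @param erd_attenuation Multiplicative amplitude factor in (0, 1] applied
#'   contralaterally during the task window (1 = no ERD). Band power scales
#'   with the square of this factor.
#' @param ers_rebound Amplitude factor >= 1 applied after the task window
#'   (1 = no ERS).
#' @param noise_sigma Standard deviation of the pink (1/f) background noise.
#' @param cz_mix Fraction in `[0, 1]` of the lateralised amplitude effect
#'   that also reaches the midline channel Cz.
#' @return Object of class `erd_params`.
#' @export
erd_params <- function(fs = 250, duration_s = 8, cue_onset_s = 3,
                       task_window_s = c(0.5, 2.5),
                       mu_freq = 10, beta_freq = 22,
                       mu_amp = 1, beta_amp = 0.5,
                       erd_attenuation = 0.5, ers_rebound = 1.2,
                       noise_sigma = 0.5, cz_mix = 0.25) {
  p <- list(fs = fs, duration_s = duration_s, cue_onset_s = cue_onset_s,
            task_window_s = task_window_s, mu_freq = mu_freq,
            beta_freq = beta_freq, mu_amp = mu_amp, beta_amp = beta_amp,
            erd_attenuation = erd_attenuation, ers_rebound = ers_rebound,
            noise_sigma = noise_sigma, cz_mix = cz_mix)
  if (fs <= 0 || duration_s <= 0) stop_input("fs and duration_s must be positive")
  if (!(erd_attenuation > 0 && erd_attenuation <= 1))
    stop_input("erd_attenuation must lie in (0, 1], got %g", erd_attenuation)
  if (ers_rebound < 1) stop_input("ers_rebound must be >= 1, got %g", ers_rebound)
  if (cz_mix < 0 || cz_mix > 1) stop_input("cz_mix must lie in [0, 1]")
  if (length(task_window_s) != 2L || task_window_s[1] >= task_window_s[2])
    stop_input("task_window_s must be an increasing (start, end) pair")
  tw <- cue_onset_s + task_window_s
  if (tw[1] < 0 || tw[2] > duration_s)
    stop_input("task window [%g, %g] s lies outside the epoch [0, %g] s",
               tw[1], tw[2], duration_s)
  if (noise_sigma < 0) stop_input("noise_sigma must be non-negative")
  structure(p, class = "erd_params")
}

## Pink (1/f power) noise of length n, unit variance, from the current RNG
## stream: white Gaussian Fourier coefficients shaped by f^(-1/2).
pink_noise <- function(n) {
  nf <- n %/% 2L
  amp <- seq_len(nf)^(-0.5)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  S <- complex(n)
  S[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) S[nf + 1L] <- complex(real = Re(spec[nf]), imaginary = 0)
  k <- 2:(if (n %% 2L == 0L) nf else nf + 1L)
  S[n - k + 2L] <- Conj(S[k])
  x <- Re(stats::fft(S, inverse = TRUE)) / n
  x / stats::sd(x)
}

## Amplitude envelope over the epoch: 1 at baseline, `a_task` inside the
## task window, `a_post` afterwards, with raised-cosine ramps of RAMP_S
## seconds starting at each boundary.
amplitude_envelope <- function(t, t_start, t_end, a_task, a_post) {
  env <- rep(1, length(t))
  ramp <- function(tt, t0) pmin(pmax((tt - t0) / RAMP_S, 0), 1)
  r1 <- 0.5 * (1 - cos(pi * ramp(t, t_start)))   # 0 before task, 1 inside
  env <- 1 + (a_task - 1) * r1
  r2 <- 0.5 * (1 - cos(pi * ramp(t, t_end)))     # task -> post transition
  env + (a_post - a_task) * r2
}

contralateral_channel <- function(label) if (label == "left") "C4" else "C3"

## Per-channel (attenuation, rebound) amplitude factors for a given label.
channel_factors <- function(label, params) {
  att <- c(C3 = 1, Cz = 1, C4 = 1)
  reb <- c(C3 = 1, Cz = 1, C4 = 1)
  contra <- contralateral_channel(label)
  att[contra] <- params$erd_attenuation
  reb[contra] <- params$ers_rebound
  att["Cz"] <- 1 - params$cz_mix * (1 - params$erd_attenuation)
  reb["Cz"] <- 1 + params$cz_mix * (params$ers_rebound - 1)
  list(att = att, reb = reb)
}

#' Generate one synthetic motor-imagery epoch
#'
#' @param label `"left"` or `"right"` (imagined hand). Left-hand imagery
#'   attenuates C4 (right hemisphere), right-hand imagery attenuates C3.
#' @param params An [erd_params()] object.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   epochs. The caller's RNG state is preserved.
#' @return Object of class `eeg_epoch`: `channels`, `data` (samples x 3
#'   matrix, microvolt-scale arbitrary units), `fs`, `label`, `cue_onset_s`.
#' @examples
#' ep <- generate_epoch("left", erd_params(noise_sigma = 0), seed = 1)
#' dim(ep$data) # 2000 x 3
#' @export
generate_epoch <- function(label, params = erd_params(), seed = 1L) {
  if (!is.character(label) || length(label) != 1L || !label %in% c("left", "right"))
    stop_input("label must be \"left\" or \"right\", got %s", deparse(label))
  if (!inherits(params, "erd_params")) stop_input("params must be erd_params()")
  n <- round(params$fs * params$duration_s)
  t <- (seq_len(n) - 1L) / params$fs
  t_start <- params$cue_onset_s + params$task_window_s[1]
  t_end <- params$cue_onset_s + params$task_window_s[2]
  fac <- channel_factors(label, params)
  data <- with_seed(seed, {
    m <- matrix(0, n, 3L, dimnames = list(NULL, CHANNELS))
    for (ch in CHANNELS) {
      env <- amplitude_envelope(t, t_start, t_end, fac$att[ch], fac$reb[ch])
      phase_mu <- stats::runif(1, 0, 2 * pi)
      phase_beta <- stats::runif(1, 0, 2 * pi)
      x <- params$mu_amp * env * sin(2 * pi * params$mu_freq * t + phase_mu) +
        params$beta_amp * env * sin(2 * pi * params$beta_freq * t + phase_beta)
      if (params$noise_sigma > 0)
        x <- x + params$noise_sigma * pink_noise(n)
      m[, ch] <- x
    }
    m
  })
  structure(list(channels = CHANNELS, data = data, fs = params$fs,
                 label = label, cue_onset_s = params$cue_onset_s),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch: %s, %d samples x %d channels @ %g Hz, cue %g s>\n",
              x$label, nrow(x$data), ncol(x$data), x$fs, x$cue_onset_s))
  invisible(x)
}

#' Generate a labelled synthetic epoch set
#'
#' Draws `round(class_fraction * n_trials)` left-hand and the remainder
#' right-hand epochs in a seeded random order, each epoch generated from its
#' own seed derived deterministically from the master seed.
#'
#' @param n_trials Number of epochs (>= 2).
#' @param class_fraction Fraction of left-hand trials in (0, 1).
#' @param params An [erd_params()] object.
#' @param seed Master integer seed.
#' @return Object of class `epoch_set`: `epochs` (list of `eeg_epoch`),
#'   `seed`, `params`.
#' @export
generate_dataset <- function(n_trials, class_fraction = 0.5,
                             params = erd_params(), seed = 1L) {
  if (!is_count(n_trials) || n_trials < 2L)
    stop_input("n_trials must be an integer >= 2, got %s", format(n_trials))
  if (!(class_fraction > 0 && class_fraction < 1))
    stop_input("class_fraction must lie in (0, 1)")
  n_left <- round(class_fraction * n_trials)
  labels <- c(rep("left", n_left), rep("right", n_trials - n_left))
  ord_and_seeds <- with_seed(seed, list(
    ord = sample.int(n_trials),
    seeds = sample.int(.Machine$integer.max - 1L, n_trials)
  ))
  labels <- labels[ord_and_seeds$ord]
  epochs <- lapply(seq_len(n_trials), function(i)
    generate_epoch(labels[i], params, seed = ord_and_seeds$seeds[i]))
  structure(list(epochs = epochs, seed = seed, params = params),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  labs <- vapply(x$epochs, `[[`, "", "label")
  cat(sprintf("<epoch_set: %d epochs (%d left / %d right) @ %g Hz, seed %d>\n",
              length(x$epochs), sum(labs == "left"), sum(labs == "right"),
              x$params$fs, x$seed))
  invisible(x)
}

#' Analytic expected ERD/ERS per channel (noise-free)
#'
#' The generator multiplies oscillator amplitudes by `erd_attenuation`
#' during the task window, so relative band power changes by
#' `100 * (erd_attenuation^2 - 1)` percent on the contralateral channel,
#' `0` on the ipsilateral channel, and the `cz_mix`-blended equivalent on
#' Cz. This is the ground truth that ERD quantification should recover on
#' noise-free data.
#'
#' @param params An [erd_params()] object.
#' @param label Imagined hand, determining which channel is contralateral.
#' @return Named numeric vector (C3, Cz, C4) of expected task-window
#'   ERD/ERS in percent.
#' @examples
#' expected_erd_percent(erd_params(erd_attenuation = 0.5)) # C4 = -75
#' @export
expected_erd_percent <- function(params, label = "left") {
  fac <- channel_factors(label, params)
  100 * (fac$att^2 - 1)
}
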