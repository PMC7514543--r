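---
title: "Decoding motor imagery from wavelet images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from wavelet images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During imagined hand movement, the sensorimotor mu (8–13 Hz) and beta
(13–30 Hz) rhythms lose power over the hemisphere contralateral to the
imagined hand — event-related desynchronization (ERD) — and may rebound
afterwards (event-related synchronization, ERS). A brain–computer interface
can decode *which* hand was imagined from three electrodes (C3 over the
left motor cortex, Cz at the midline, C4 over the right) by detecting on
which side the band power dropped.

`micwt` implements one complete decoding pipeline:

1. a **continuous wavelet transform** (CWT) turns each channel of a trial
   into a time–frequency magnitude map (scalogram),
2. the mu- and beta-band scalograms of the three electrodes are combined
   into one fixed-size **image** (93 × 32),
3. a **shallow convolutional network** whose kernels span the full image
   height and slide only along time classifies left vs right,
4. an **ERD/ERS quantifier** verifies that the images encode the expected
   physiology, and
5. a **synthetic EEG generator** provides labelled data with a known,
   controllable ERD depth so that every stage can be tested offline with an
   analytic ground truth.

## Continuous wavelet transform

The transform is the correlation form

$$\mathrm{CWT}(\omega, s) = \frac{1}{|s|}\int x(t)\,
  \psi\!\left(\frac{t-\omega}{s}\right) dt,$$

evaluated at every sample position $\omega$, one scale $s$ per analysis
frequency. Three mother wavelets are supported:

* **Morlet** $\psi(t) = e^{2\pi i t} e^{-t^2/2\sigma^2}$ — a 1 Hz complex
  carrier under a Gaussian envelope;
* **Mexican hat** $\psi(t) = (1 - t^2/\sigma^2)\,e^{-t^2/2\sigma^2}$ — real,
  broad-band;
* **Bump**, defined in the Fourier domain as
  $\exp\!\big(1 - 1/(1 - (sw-\mu)^2/\sigma^2)\big)$ on the compact support
  $[\mu-\sigma, \mu+\sigma]$ and exactly zero outside — narrow-band with no
  spectral leakage outside its support.

**Scale–frequency map.** The map is $f = f_c / s$ with $f_c$ the peak
response frequency of the mother wavelet: 1 Hz for Morlet (its carrier),
$\sqrt{2}/(2\pi\sigma)$ for the Mexican hat (the peak of its Fourier
magnitude $\propto w^2 e^{-\sigma^2 w^2/2}$), and $\mu/(2\pi)$ for Bump.
With the $1/|s|$ normalisation above, the magnitude response to a pure tone
then peaks exactly at the grid row matching the tone frequency — a property
the test suite asserts at 8, 10, 13, 20 and 30 Hz for all three wavelets.

**Defaults.** Morlet $\sigma = 1$ s (a frequency resolution of
$\sigma_f = f/2\pi$, adequate to separate mu from beta), Mexican hat
$\sigma = 1$, Bump $\mu = 5$, $\sigma = 0.6$ (a common pairing giving a
relative bandwidth of 12%). All are configurable and recorded in output
metadata. Magnitudes $|CWT|$ populate the scalogram; complex coefficients
are retained for the inverse transform.

**Numerics.** Morlet and Mexican hat rows are computed by FFT convolution
with the sampled scaled kernel, truncated where the Gaussian envelope falls
below $e^{-32}$ (8 envelope widths). Bump rows are computed natively in the
Fourier domain, where that wavelet is defined; because a compactly
supported spectrum decays only super-polynomially in time, the padded
length extends to 320 scaled time units so that periodisation error stays
below $10^{-9}$ relative. Two boundary rules exist: `mirror` (default)
reflects the signal at its edges, suppressing wrap-around transients that
would otherwise bias the minimum-power window selection near the interval
edges; `zero` extends with zeros and is the rule under which the fast
transform is compared to the direct Riemann-sum oracle (which, by
definition, sees a zero-extended signal). The oracle for the Bump wavelet
reconstructs the time-domain kernel by trapezoid quadrature of the inverse
Fourier integral over the compact support — the integrand vanishes with all
derivatives at the endpoints, so the rule converges spectrally — giving two
genuinely independent computational routes.

The inverse transform uses the single-integral (delta) reconstruction over
a dense log-spaced grid with a numerically integrated admissibility
constant. It is a discretised approximation: the package's contract is
correlation > 0.95 with a band-limited input, not exact recovery.

## Image construction

For each trial the 2 s imagery interval (0.5–2.5 s after the cue) is
transformed on two grids: mu 8–13 Hz in 0.2 Hz steps (26 rows) and beta
13–30 Hz in 37 linearly spaced rows — at 250 Hz these reproduce the
26 × 500 and 37 × 500 band images the pipeline is built around. The
discretisation of the bands is a package choice; these are the unique
uniform grids consistent with those shapes.

Within the task interval, the contiguous 0.5 s window with the **smallest
total mu-band magnitude** (summed over frequencies and all three
electrodes, exhaustive stride-1 scan, earliest window on ties) is selected:
this is the moment of deepest desynchronization, where the lateralised
signature is strongest. "Smallest summed magnitude" is our reading of the
window criterion; the beta band reuses the mu-selected window, since the
selection is defined on the mu image only.

Both bands are then resized by cubic-spline interpolation
(`stats::spline`, applied independently along each axis onto uniform target
coordinates): mu to 15 rows, beta to 16 rows — the unique near-equal split
summing to the 31 rows per electrode, with the wider band keeping the extra
row — and both to 32 time columns. Per electrode the mu block sits above
the beta block (frequencies ascending); the three electrode blocks stack
C3, Cz, C4 top-to-bottom, giving 93 × 32. The row order is a fixed
convention recorded per row in `row_map`, so every row is attributable to
exactly one (electrode, band, frequency). A mu-only variant skips the
frequency resize entirely (78 × 32 at the default grid), trading image
compactness for unresampled frequency resolution.

Because the resize targets fixed output sizes, the image shape is invariant
to the sampling rate — 128 Hz recordings produce the same 93 × 32 images,
only from 256-column band scalograms.

Each image is min–max normalised to [0, 1] *per image*. This is
deliberately trial-local: no statistic of other trials (in particular, of
training trials) enters a test image, so cross-validation cannot leak
through normalisation. A constant image (degenerate input) maps to all
zeros with a warning.

## The classifier

Kernels of size 93 × 3 span the full image height — all electrodes and
frequencies — and slide only along the 32 time columns (stride 1, no
padding): the network learns *which spatial-spectral patterns occur*,
treating their exact timing within the selected window as nuisance. The
dimension chain at defaults is

$$93 \times 32 \;\to\; 30 \text{ maps} \times 30 \;\to\;
  \text{ReLU} \;\to\; \text{max-pool}(10) \to 30 \times 3 \;\to\;
  90 \;\to\; 2 \text{ logits}.$$

Max-pooling uses non-overlapping windows and discards a trailing remainder
(no zero padding). Training is plain mini-batch gradient descent (batch 50,
300 epochs, learning rate 0.01 by default) on softmax cross-entropy.
Choices the architecture leaves open are resolved as follows: the output
nonlinearity is softmax with cross-entropy (the standard pairing for
two-class networks, and the one whose gradient is the simple
`probability − target`); the fully connected layer has biases; weights are
initialised zero-mean uniform scaled by $1/\sqrt{\text{fan-in}}$ from a
seed, and batch order is reshuffled per epoch from the same stream, so
training is bit-reproducible. "Convolution" is implemented as correlation
(no kernel flip), the convention of CNN practice. Analytic gradients are
verified against central finite differences to below $10^{-4}$ relative
error in the test suite (observed ~$10^{-9}$).

## ERD/ERS quantification

Per channel and band: trials are band-pass filtered, squared and averaged
across trials ($\mathrm{avg}(j) = \frac1N \sum_i s_{ij}^2$); a reference
power is the mean of that series over a pre-cue baseline; the ERD/ERS
time course is $100\,(\mathrm{avg}(j) - \mathrm{ref})/\mathrm{ref}$.
The filter is a 4th-order Butterworth applied forward–backward
(`signal::filtfilt`): zero phase, so ERD latencies are not shifted. The
baseline defaults to the 1 s window ending 0.5 s before the cue — late
enough to avoid filter edge transients, early enough to precede
anticipatory desynchronization. The averaged power is smoothed with a
0.25 s centred moving average (edge windows shrink rather than pad) before
referencing; the constant is configurable and only affects curve
smoothness, not window means. Because amplitudes enter squared in both
numerator and denominator, the curves are exactly invariant to rescaling
all trials — a property the tests assert.

## The synthetic generator: what it emulates, what it does not

Each epoch is mu and beta sinusoids with per-channel random phase over
pink (1/f power) background noise. Pink rather than white noise because EEG
spectra fall off roughly as 1/f; white noise would make band-power
baselines unrealistically flat and the decoding task artificially easy at
high frequencies. During the task window the oscillator *amplitude* on the
contralateral channel is multiplied by `erd_attenuation`; Cz receives a
`cz_mix` fraction of the effect; after the window an `ers_rebound ≥ 1`
factor models the rebound. Transitions use 0.1 s raised-cosine ramps — a
step modulation would splatter broadband energy into the beta band and
contaminate it. Because power is amplitude squared, the analytic ground
truth is $\mathrm{ERD}\% = 100\,(a^2 - 1)$ for attenuation $a$:
`expected_erd_percent()` returns exactly this, and the recovery tests close
the loop at $a = 0.5 \to -75\%$ within 5 percentage points.

Default geometry mirrors a standard cued protocol: 250 Hz, 8 s epochs, cue
at 3 s, imagery analysed 0.5–2.5 s post-cue. Amplitude defaults (mu 1.0 at
10 Hz, beta 0.5 at 22 Hz, noise SD 0.5) were chosen once as plausible
band-to-background ratios for sensorimotor EEG; attenuation defaults to
0.5, with 0.3 used for the strongly separable decoding checks. No
quantitative ERD depth per subject exists to calibrate against, so these
are free parameters of the generator, not estimates.

The generator deliberately omits volume conduction, ocular/muscle
artifacts, inter-trial nonstationarity and subject variability. Passing
tests therefore demonstrate that the pipeline is *correct* (it recovers
known parameters and separates classes whose only difference is a
lateralised band-power change); they do not predict accuracy on real
recordings, where class overlap is far larger. Accuracies near 100% on
synthetic data at attenuation 0.3 reflect the cleanness of the simulation,
not expected field performance.

## Evaluation protocol

10-fold cross-validation repeated 10 times with fresh shuffles — 100 test
sets — reporting mean and standard deviation (population form, over the
100 split accuracies) of accuracy in percent. "Repeated 10 times" is read
as 10 repetitions of a 10-fold partition; the alternative reading, 100
independent 90/10 random splits, is available via `protocol = "random"`.
Each split trains a freshly initialised network (seed offset per split).

Folds are **stratified by class**: each class is shuffled and dealt into
the folds separately, so every training fold carries the overall class
ratio. This matters for the permutation-null control. With unstratified
folds, a training fold that happens to be, say, 47/43 pushes a classifier
trained on pure label noise toward the majority class, while the held-out
fold is imbalanced the *opposite* way — the null then lands systematically
below 50%, a well-known pessimistic bias of unstratified cross-validation.
With stratified folds the label-permutation control run through the
identical pipeline sits at chance within binomial noise, confirming that
no part of the pipeline leaks labels.

## Problem sizes

The test suite and the reproduction script run the statistical checks at
100 trials, 50 training epochs and 10 × 10-fold CV; ERD recovery uses 100
noise-free trials; oracle equivalence uses 500-sample signals on 5-frequency
grids. These sizes were chosen so the full suite completes in minutes while
leaving every estimate's tolerance comfortably met; the package defaults
(400 trials, 300 epochs) match the full protocol.

## Known limitations

* GDF/EDF ingestion of competition recordings is not implemented; external
  data enter via the JSON container or a plain delimited matrix format.
* The inverse CWT is approximate by construction (single-integral
  reconstruction on a discrete grid).
* Only the three-channel C3/Cz/C4 montage and two classes are supported.
* The 15/16-row band split and the minimum-summed-power window criterion
  are documented package choices among the readings consistent with the
  printed image sizes; alternatives (e.g. per-band resize to 31 rows with
  averaging) are not implemented.
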