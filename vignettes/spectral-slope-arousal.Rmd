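---
title: "Tracking arousal states with the aperiodic spectral slope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking arousal states with the aperiodic spectral slope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopetrack)
```

## The model

Away from its oscillatory peaks, the EEG power spectrum decays approximately
as a power law, $S(f) \propto f^{\beta}$ with $\beta < 0$. On a log-log plot
this aperiodic background is a straight line, and its slope $\beta$ is the
central statistic of this package. In cortical circuit models the slope
steepens as inhibition comes to dominate excitation, and empirically it
separates arousal states that conventional band power confuses: wakefulness
shows the shallowest decay, NREM sleep an intermediate one, and REM sleep --
whose band-power profile is deceptively wake-like -- the steepest. Propofol
anesthesia also steepens the slope relative to wakefulness. The package
estimates $\beta$ over 30--45 Hz, a band chosen to sit above the strong
physiological oscillations (slow waves, spindles, alpha) and below mains
interference and the bulk of broadband EMG.

The workflow has five stages, each usable on its own:

1. **Spectral estimation** (`compute_psd`): non-overlapping segments,
   demeaned and linearly detrended, decomposed with a multitaper estimator.
   The Slepian taper count follows the time-bandwidth rule $K = 2TW - 1$
   (`dpss_taper_count`): 29 tapers for 30 s sleep segments at $\pm$0.5 Hz
   smoothing, 9 for 10 s anesthesia segments. Single-taper (Hann),
   periodogram and Welch estimators exist for the signal-to-noise
   comparison; multitaper wins because averaging $K$ orthogonal eigenspectra
   divides the estimator variance by roughly $K$.
2. **Slope fitting** (`fit_slope_linear` and controls): ordinary least
   squares of $\log_{10}$ power on $\log_{10} f$ over the grid points inside
   the band, endpoints inclusive (31 points on the half-Hz grid). Robust
   (bisquare) regression, an aperiodic-model fit with Gaussian peak removal,
   and IRASA fractal separation are provided as cross-checks; on peak-free
   spectra all agree within 0.1.
3. **State tracking** (`time_resolved_slope`, `mi_surrogate_test`): one
   slope per 30 s segment, aligned to the scored hypnogram, discretized into
   five equal-width bins and scored by mutual information, with block-swap
   surrogates supplying the null.
4. **Slow-wave dynamics** (`detect_slow_waves`, `event_locked_slope`):
   zero-crossing detection on the 0.16--1.25 Hz filtered trace with a
   duration (0.8--2 s) and amplitude (75th percentile) criterion, then a
   sliding single-taper decomposition ($\pm$2 Hz smoothing, 0.5 s windows,
   0.25 s steps) of trough-locked epochs.
5. **Discrimination** (`lda_balanced_cv`, `glm_state_model`): balanced
   leave-one-out linear discriminant analysis of state from single features,
   and a GLM variance decomposition (eta squared per term, Type II sums of
   squares) of slope versus slow-wave power.

## What the synthetic generator emulates

Real overnight polysomnography is large and access-restricted, so the
package ships a generator (`gen_recording`) that reproduces the statistical
structure the analysis relies on, not the physiology:

* a per-state 1/f background with exact spectral control (white noise shaped
  by $f^{\beta/2}$ in the frequency domain, flat below 1 Hz so that steep
  exponents keep finite variance). Default exponents follow published group
  means: wake $-1.84$, N2 $-3.67$, N3 $-3.46$, REM $-4.73$, propofol
  anesthesia $-3.10$. N1 has no published mean and is set to $-3.0$, between
  wake and N2;
* band-limited oscillation bursts (posterior alpha in wake, spindles in
  N2/N3, theta in N1/REM) with raised-cosine gating. Amplitudes and duty
  cycles are generator choices, set so that oscillations are visible in the
  spectrum without dominating the band used for slope fitting;
* biphasic slow waves (one $-\sin$ cycle, 0.8--2 s) at state-dependent rates
  -- published where available (N3 28.79, wake 5.05, REM 2.16 per minute),
  interpolated otherwise (N2 15/min) -- placed on jittered regular slots so
  that ground-truth trough times are exact and events never overlap;
* one EMG channel: Gaussian noise high-pass filtered above 40 Hz, scaled per
  state (atonia in REM, maximal tone in wake);
* a first-order Markov hypnogram whose stay probabilities give realistic
  bout lengths and whose stationary distribution approximates a healthy
  night (W 13%, N1 6%, N2 39%, N3 24%, REM 18%). A two-hour simulated night
  is long enough for the first REM bouts to appear at a realistic latency.

Epochs are cross-faded over 1 s cosine ramps so state changes do not inject
spectral edges. Everything is reproducible from a single master seed.

What the generator does *not* emulate: K-complexes, sawtooth waves, eye
movements, electrode artifacts, inter-subject variability, or any
low-frequency bend ("knee") in the aperiodic spectrum. Passing tests on
these data therefore certify the estimators and statistics, not robustness
to clinical recordings. One visible consequence: because the synthetic
exponent contrast spans the whole spectrum, the fit-band scan
(`slope_parameter_scan`) finds lower-frequency bands at least as informative
as 30--45 Hz on synthetic nights, whereas on real data the low bands are
contaminated by oscillations and the 30--45 Hz choice is the robust one.

## Numerical choices

* **Taper concentration filter.** The taper-count rule at $TW = 15$ includes
  Slepian orders whose energy concentration drops to 0.89; on spectra
  spanning several decades the leaked fraction of total variance floors the
  30--45 Hz range and biases steep slopes toward zero. `compute_psd`
  therefore drops tapers with leakage fraction above `taper_leak_tol`
  (default $10^{-5}$, chosen so the leakage floor sits an order of magnitude
  below the steepest target spectrum's density at 45 Hz). The nominal K is
  reported as `n_tapers`, the retained count as `n_tapers_used`. With this
  filter, generating exponents from $-1$ to $-4$ are recovered with bias
  below 0.05; without it, a $-4$ signal reads as $-3.1$.
* **Slow-wave filtering.** A 4th-order Butterworth bandpass at 0.16 Hz of
  normalized frequency $8 \times 10^{-4}$ is numerically fragile, so
  detection runs on an anti-aliased decimated copy near 100 Hz (low- and
  high-pass biquads applied forward-backward); event times are reported in
  seconds and are rate-independent.
* **Surrogate construction.** The block-swap surrogate is implemented two
  ways. `"swap_ops"` (default) applies S cut-and-swap operations (S = number
  of stages present), which composes to a random circular rotation and
  yields a null whose two-tailed $|z| > 1.96$ rate is closest to the nominal
  5% (measured 5.8% over 500 null nights), also for autocorrelated series.
  `"block_permute"` cuts into S contiguous blocks and permutes them; at
  small S it is measurably conservative (about 3%). Since downstream
  interpretation reads $z = 1.96$ as $p = 0.05$, calibration decided the
  default.
* **Permutation p-values** use the add-one convention
  $(\#\{|t^*| \ge |t|\} + 1)/(n_{perm} + 1)$, switching to exact enumeration
  when $2^n \le n_{perm}$. Greenhouse--Geisser epsilon comes from the
  double-centered covariance of conditions; degenerate inputs (no
  within-subject variance) are defined to $F = 0$, $\epsilon = 1$.
* **Detector floor.** The 75th-percentile amplitude criterion is relative,
  so a recording with no slow-band content would still yield "events";
  candidates below 5% of the broadband SD are discarded first.
* **Equal-width discretization** for MI spans $[\min, \max]$ with the
  maximum closed into the top bin; it is invariant to affine transforms of
  the slope series. Quantile binning is not used because the published
  procedure discretizes amplitudes, not ranks.
* **LDA degeneracy.** If the pooled within-class covariance is singular the
  discriminant is ridge-regularized ($10^{-6} \cdot \mathrm{tr}/p$).
  Leave-one-out on an uninformative feature sits slightly *below* chance
  (the held-out trial repels its own training mean); tests account for this
  known property.

## Design decisions that were genuinely open

* **Band endpoints** are inclusive (30.0 and 45.0 on the half-Hz grid). The
  slope is insensitive to this at the stated grid, and inclusiveness makes
  the 31-point band reproducible.
* **Amplitude criterion** for slow waves is trough-to-peak, thresholded per
  channel across all duration-valid candidates; trough depth is available
  via `amplitude_measure = "trough"`.
* **Ordinal depth coding** for rank correlations is W=0, REM=1, N1=2, N2=3,
  N3=4 (increasing cortical synchronization), configurable in
  `stage_depth`.
* **GLM sums of squares** default to Type II -- each main effect adjusted
  for the other, the interaction for both -- with Types I/III available and
  the type always recorded; for orthogonal designs all types coincide, which
  the tests verify.
* **IRASA** uses resampling factors 1.1--1.9 in steps of 0.05, cubic-spline
  resampling with an anti-aliasing low-pass before downsampling, geometric
  means per factor and the median across factors.

## Problem sizes

Simulated nights in the analysis scripts span two hours at 200 Hz with two
EEG channels plus EMG; test fixtures use 1--10 minute signals. Calibration
properties (type-I error of the surrogate-MI z and of the sign-flip
permutation test) are measured over 500 simulated null nights of 120 epochs;
slope-recovery bias is assessed at 400 Hz with 30 s segments over exponents
$-1$ to $-4$. A single 30 s multitaper slope estimate carries an intrinsic
SD of about 0.3 at these settings, which is why state means are compared and
per-segment values are never interpreted alone.

## Known limitations

* The aperiodic model has no knee term by default; recordings with a clear
  spectral bend need the wider-band estimators (IRASA) or an explicit knee.
* Plug-in mutual information is biased upward at short nights; the surrogate
  calibration absorbs the bias for testing, but raw MI values from short
  recordings should not be compared across lengths.
* The cluster-permutation sign-flip null degrades when the effect dwarfs
  the subject-level noise (constant differences make the flipped maxima
  heavy); this is a property of the method, not of the implementation.
* The EDF reader covers continuous 16-bit EDF/EDF+ recordings only;
  discontinuous files and annotation decoding are out of scope.
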