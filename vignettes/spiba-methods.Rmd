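---
title: "Micro-movement spikes and Gamma signatures: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement spikes and Gamma signatures: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiba)
```

## The model

Biorhythmic signals — inter-beat intervals, limb acceleration, facial
landmark speeds, speech envelopes — differ in units, sampling and anatomy,
but share a common stochastic skeleton: a stream of fluctuation peaks
around an individual baseline. `spiba` standardizes that stream into
micro-movement spikes (MMS). For each peak of the absolute-deviation field
(deviations of the signal from its empirically estimated Gamma mean
amplitude), the spike amplitude is

$$\mathrm{MMS} = \frac{\mathrm{Peak}}{\mathrm{Peak} + \overline{A}_{\min\to\min}},$$

with $\overline{A}$ the mean of all samples between the two troughs
flanking the peak (both trough samples included). The ratio is unitless
and invariant to any uniform rescaling of the signal, which is the point:
amplitude differences that merely reflect body size, electrode gain or
camera distance cancel, while the *relative* structure of the fluctuations
survives. Event timestamps are carried along unchanged, so spike trains
remain temporally aligned with the recording.

Spike amplitudes are then summarized by a two-parameter Gamma fit
(maximum likelihood). With shape $a$ and scale $b$: mean $ab$, variance
$ab^2$, skewness $2/\sqrt a$, kurtosis $3 + 6/a$ (full kurtosis, stated in
the output metadata), and the noise-to-signal ratio
$\mathrm{NSR} = \mathrm{variance}/\mathrm{mean} = b$ — the scale parameter
itself. Shape 1 marks the memoryless exponential regime of pure random
noise; large shapes approach the Gaussian, predictive regime. Across
well-controlled movement, $\log a$ and $\log b$ trade off along a
negative-slope power law (`fit_power_law()`), so the NSR alone is already
a compact personalized summary.

A structural consequence worth stating: because the min-to-min window
average can never exceed the window's own maximum, every MMS amplitude
lies in $[\tfrac12, 1)$, a strict subset of the nominal $(0, 1]$ bound.
Fitted Gamma shapes for spike amplitudes are therefore large (hundreds)
and fitted means sit around 0.6–0.8; the informative contrast between
signals is carried by the scale/NSR, not by the mean.

## Peak detection conventions

"Peak detection" hides several decisions; the package fixes them as
follows and applies them uniformly:

* a peak is a strict local maximum; plateaus collapse to their first
  sample; boundary samples are never peaks;
* `min_prominence` filters on *topographic* prominence (height above the
  higher of the two saddles reached before the signal next exceeds the
  peak). Micro-ripple riding on a summit does not mask the summit; this
  matters for spline-reconstructed speed fields, where naive
  nearest-minimum prominence collapses;
* peaks closer than `min_separation` keep the larger;
* the min-to-min window of a retained peak spans the deepest
  troughs between it and its neighbouring retained peaks (record
  boundaries count as window ends). On ripple-free signals this is
  identical to "nearest local minima", but it keeps the window meaningful
  when small ripple would otherwise shrink it to a sliver and truncate the
  spike distribution.

Only strictly positive peak amplitudes enter Gamma fits; fits on fewer
than 20 samples, or on samples whose relative spread is below $10^{-9}$,
are refused as degenerate rather than silently returned.

## Confidence intervals

The Gamma MLE solves the profile score equation by Newton iteration,
which stays stable across the extreme dynamic range the pipelines produce
(first-stage fits of nearly constant peak trains reach shapes above
$10^8$). For the 95% intervals the package defaults to profile
likelihood-ratio intervals: calibration runs during development showed
observed-information (Wald) intervals covering the truth jointly only
~88–90% of the time at realistic spike counts (100–300), whereas the
profile intervals reach ~93–95%, in line with the platform's requirement
that recovery of known synthetic parameters lands inside the 95% CI in at
least 90% of runs. `gamma_fit(..., ci = "wald")` restores the classical
intervals.

## Modality pipelines: parameters that matter

**Cardiac.** Raw ECG (mV, 250 Hz) is band-passed 5–30 Hz (8th-order
Butterworth) and band-stopped 40–125 Hz (2nd order), both zero-phase; the
design band edges are pre-widened so that the forward–backward cascade has
its −3 dB points at the stated frequencies, and reflective padding keeps
startup transients out of the record (at 250 Hz the stop band's upper edge
is clipped to 0.99 × Nyquist). R peaks come from a two-stage adaptive
rule: prominence ≥ 4 × median(|filtered|) with a 0.25 s refractory, then a
second pass keeping candidates above 0.4 × the 75th-percentile candidate
height — the second stage rejects filter-ringing sidelobes that the first
admits. Intervals outside 0.3–2.0 s are flagged artifacts and excluded
from all statistics. Poincaré SD1/SD2 use the closed forms
$\mathrm{SD1}^2 = \tfrac12\mathrm{Var}(\Delta RR)$,
$\mathrm{SD2}^2 = 2\mathrm{Var}(RR) - \tfrac12\mathrm{Var}(\Delta RR)$
(clamped at zero for pathological alternating records). Spectral LF
(0.04–0.15 Hz) and HF (0.15–0.4 Hz) powers integrate the classical
normalized Lomb–Scargle periodogram on a 0.005 Hz grid — the estimator of
choice for unevenly sampled event series. Scalograms use the generalized
Morse wavelet ($\gamma = 3$, $\beta = 20$) after linear resampling of the
IBI to 4 Hz, with scales expressed as equivalent Fourier frequencies.
Windowed RR statistics use 30 s windows advancing by 20 s (10 s overlap);
the mode is the median of the most populated 10 ms histogram bin, which is
exact for repeated values.

**Kinematics.** The triaxial magnitude $\sqrt{x^2+y^2+z^2}$ keeps gravity
(resting ≈ 1 g; 1 g = 9.8 m/s² for SI output). The "center of position"
reported with each task signature is the per-axis mean of raw acceleration
over the task window, alongside the magnitude mean — a documented
definition choice, since the quantity is otherwise under-specified.

**Face.** Every frame is shape-normalized: centroid to (0,0), isotropic
scale so the standard deviation of the 68 landmark distances from the
origin is 1. This removes similarity transforms exactly and is idempotent.
Landmark speeds come from cubic splines (GCV-penalized by default for
noisy tracks, with `smoothing = "interpolate"` for clean trajectories —
smoothing shrinks amplitude dispersion and biases Gamma shapes upward, so
interpolation is preferred whenever tracking noise is negligible; splines
use all knots, because default knot thinning distorts frame-rate speed
structure in longer recordings). Speeds are computed on normalized
coordinates so signatures are unitless. The V1/V2/V3 trigeminal
parcellation ships as a configurable default (V1 eyebrows+eyes, V2
nose+upper jaw margin, V3 chin+mouth in iBUG numbering) — a documented
choice, not an anatomical standard. Region signatures pool spike
amplitudes across the region's landmarks into one Gamma fit; the three
regional moment points (mean, variance, skewness; kurtosis as marker
size) form a triangle whose area summarizes how differentiated the
regions are. Windowed Earth-mover's-distance trajectories compare each
window's spike sample against per-emotion references (5 s windows, 50%
overlap by default; 10% overlap is supported as the slower-trajectory
variant); spikes are detected once over the recording and assigned to
windows by event time, avoiding per-window refits of the reference
amplitude. Transfer entropy between region speed series uses a plug-in
estimator with 3 equal-frequency bins at lag 1, in bits, without bias
correction; on independent series the estimator's small-sample bias is
roughly $(B-1)B^2 / (2n\ln 2)$ bits for $B$ bins.

**Voice.** Envelopes come from a 4th-order gammatone band (zero-phase
frequency-domain magnitude response on the Glasberg–Moore ERB scale, 10
channels spanning 100–8000 Hz), half-wave rectification, and a 4th-order
20 Hz Butterworth low-pass, normalized to session maximum 1. The default
analysis band is selected by center frequency (nearest 5600 Hz — band 9
under this layout), because filterbank ordinal numbering is
toolbox-dependent while the informative 4–7 kHz channel is not.
Segmentation is median-thresholded: retained maxima are local maxima above
the session median (highest kept where several compete between minima,
earliest on ties), retained minima mirror the rule below the median, and
leading/trailing partial phases are discarded. Attack slopes run
minimum→maximum, decay maximum→minimum; absolute slopes get Gamma
signatures (their scale is the per-phase NSR), areas are left-Riemann
sums, and the memory score is the arithmetic mean of the longest forward
and backward digit spans.

**Group comparison.** Kruskal–Wallis with tie correction (all-tied input
returns $H = 0$, $p = 1$ by convention); pairwise emotion comparisons use
the two-group version (equivalent to the rank-sum test up to the
chi-square approximation) with marks at $p < 0.05$ and $p < 0.01$ and no
multiple-testing correction by default, matching how such matrices are
conventionally reported; a Benjamini–Hochberg option exists. The 1-D EMD
is computed exactly as the integral of the absolute CDF difference.

## What the synthetic generators emulate

The generators exist so every stage is testable without participant data.
Their central device is inverse construction: draw target spike amplitudes
$m_i \sim \Gamma(a_0, b_0)$, then build a bump train whose min-to-min
window averages solve $m = P/(P+\overline A)$ exactly (a linear blend of a
narrow and a wide smooth bump profile, solved per bump; out-of-band draws
are clamped, which with the default targets affects < 1% of draws). The
raw signal is baseline-minus-bumps with tiny valley jitter, so the
pipeline's first-stage Gamma mean lands a known hair's breadth from the
baseline and downstream spike amplitudes reproduce the drawn targets to
about $10^{-4}$. Defaults are chosen once for realism at the study's
sampling rates: RR baseline 0.9 s with 0.03 s oscillations at 0.1/0.25 Hz
and 0.15 s fluctuation bumps spanning 8 beats; IMU tasks set both bump
amplitude (0.02–0.3 g) and spike dispersion (NSR $9\times10^{-4}$ to
$5\times10^{-3}$, mean held at 0.7); faces run at 30 Hz with 150-frame
clips; voice bursts rise in 50 ms with attack slopes
$\sim\Gamma(4, 2)$ amplitude/s.

Facial movers follow fixed-radius circular orbits whose phase advances at
speed/radius (trapezoid-integrated), the one motion model that reproduces
an arbitrary nonnegative speed profile with no velocity reversals and
bounded excursion. Per-frame shape normalization couples landmarks — the
centroid and scatter terms spread a fraction of every mover's velocity
onto all 68 points — so exact ground truth is only available before
normalization; recovery checks therefore run the spike machinery on
generator output already expressed in normalized-scale coordinates, while
the normalization itself is verified exactly by its own invariants
(centroid, unit distance SD, similarity invariance, idempotence).
Mirror-partner counterweights are available for experiments that need the
centroid pinned under animation.

What passing these tests shows — and does not show: the pipelines recover
the statistical structure they are designed to measure when that
structure is present and clean. Synthetic records contain no electrode
motion, missing frames, occlusions, breathing artifacts or nonstationary
baselines; real-data performance depends on the artifact handling layers
(physiologic band flags, confidence-based frame dropping, prominence
thresholds) that the tests exercise only lightly.

## Problem sizes and calibration checks

The shipped checks run at desk scale, chosen as the smallest sizes at
which the estimators' own uncertainty statements are trustworthy: CI
coverage of parameter recovery uses 100 seeded runs of ~600 spikes per
modality (about an hour of RR data, four minutes of accelerometry, 100 s
of facial video, 600 voice bursts), where joint profile-CI coverage was
measured at ~94–95% during design; Kruskal–Wallis type-I calibration uses
1000 null simulations at $n = 20$ per group; EMD is checked against a
$10^4$-sample quantile-integral oracle; transfer entropy at $n = 5000$
with 3 bins.

## Known limitations

* The shape–scale power law is estimated by OLS on log–log pairs without
  errors-in-variables correction; with few signatures the slope is noisy.
* The binned TE estimator is biased upward on short series and is not
  corrected by default; compare conditions at matched $n$ and bins.
* The gammatone band is applied as a zero-phase magnitude response, not
  the toolbox IIR cascade; envelopes agree closely but not sample-exactly
  with time-domain implementations.
* Spike recovery through per-frame face normalization is approximate by
  construction (landmark coupling); treat normalized-path Gamma
  signatures as comparative, not absolute, measurements.
* The Lomb–Scargle band powers are normalized-periodogram integrals;
  compare ratios (LF/HF) across recordings rather than raw powers.
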