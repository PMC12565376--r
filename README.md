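# spiba — spike-based standardization of biorhythmic signals

`spiba` is an R implementation of a unified statistical platform for
personalized biometrics. It converts heterogeneous physiological time
series — ECG-derived inter-beat intervals, triaxial accelerometry, 68-point
facial landmark kinematics, and speech amplitude envelopes — into a single
standardized data type, the **micro-movement spike (MMS)**, and
characterizes each person's moment-to-moment fluctuations with an
empirically estimated Gamma distribution.

## The core statistic

For a biorhythmic series, the pipeline is:

1. detect the local peaks of the raw series and fit a Gamma distribution to
   their amplitudes by maximum likelihood; take its mean as the empirical
   reference amplitude;
2. form the absolute deviations of the series from that mean;
3. detect the peaks of the deviation field; each peak is normalized by its
   local min-to-min window,

   MMS = Peak / (Peak + Avrg_min-to-min),

   where `Avrg` is the mean of all samples between the two troughs flanking
   the peak. The ratio is unitless, bounded in (0, 1], and invariant to
   uniform rescaling of the signal — removing allometric (body-size)
   differences across people and sensors;
4. fit the Gamma distribution to the spike amplitudes by MLE with 95%
   confidence intervals. With shape *a* and scale *b*, the Gamma mean is
   *a·b*, the variance *a·b²*, and the **noise-to-signal ratio**
   NSR = variance/mean = *b*: the scale parameter itself. Shape 1 is the
   memoryless exponential regime (random noise); larger shapes approach the
   Gaussian, predictive regime, and empirically log(a) and log(b) trade off
   along a negative power law.

Around this engine the package provides the four modality pipelines
(cardiac: Butterworth preprocessing, R peaks, Poincaré SD1/SD2,
Lomb–Scargle LF/HF, Morse-wavelet scalograms, windowed RR statistics;
kinematics: acceleration magnitude and task signatures; face: shape
normalization, trigeminal V1/V2/V3 parcellation, spline speed fields,
Gamma-moment triangles, EMD trajectories, transfer entropy; voice:
gammatone envelopes and attack/decay stochastics), Kruskal–Wallis group
comparison with pairwise EMD/significance matrices, and seeded synthetic
generators with machine-readable ground truth for every modality.

## Worked example

```r
library(spiba)

# a 10-minute synthetic RR series with Gamma-structured fluctuations
tr  <- gen_ibi(duration = 600, seed = 42, a_lf = 0, a_hf = 0)
fit <- cardiac_gamma(tr)   # spike pipeline on the IBI sequence
fit
#> <mms_result> 90 spikes
#> <gamma_signature> n = 90
#>   shape a = 273.246  [201.033, 360.986]
#>   scale b = 0.00257016  [0.00194504, 0.00349454]  (= NSR)
#>   mean 0.702287  variance 0.00180499  skewness 0.120991  kurtosis 3.02196 (full)

poincare(tr)
#> # A tibble: 1 × 4
#>      sd1    sd2 ratio_sd2_sd1     n
#>    <dbl>  <dbl>         <dbl> <int>
#> 1 0.0338 0.0488          1.45   721

# a record with a pure 0.25 Hz (respiratory-band) oscillation
hf <- gen_ibi(duration = 300, seed = 42, a_lf = 0, a_hf = 0.05, fluct_scale = 0)
ibi_spectrum(hf)
#> # A tibble: 1 × 4
#>   lf_power hf_power lf_hf_ratio lf_resolved
#>      <dbl>    <dbl>       <dbl> <lgl>
#> 1 0.000894    0.923    0.000969 TRUE
```

The generator injected spikes with Gamma shape 240 and scale 0.00292
(NSR); the fitted signature recovers both inside its 95% confidence
intervals. The Poincaré descriptors summarize the lag-1 scatter of the
intervals (SD1: short-term, parasympathetic proxy; SD2: long-term,
sympathetic proxy), and the spectral row shows the injected
high-frequency oscillation dominating the 0.15–0.4 Hz band
(LF/HF « 1).

Each fitted object supports `tidy()`/`glance()` and has `autoplot()`/
`plot_*()` companions (`plot_gamma_plane()`, `plot_poincare()`,
`plot_emd_trajectory()`, ...).

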