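---
title: "Oscillation phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillation phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscphen)
```

## The model

A resting-state EEG/LFP power spectrum is decomposed into an aperiodic
(broadband, 1/f-like) component and a periodic residual. The aperiodic
component is a Lorentzian in log-log space,

$$y(f) = b - \log_{10}\!\left(k + f^{-m}\right),$$

with intercept $b$ (log10 power), slope $m \le 0$ and knee $k \ge 0$. With
$k = 0$ this is a straight line $b + m\,\log_{10} f$ (surface EEG); depth
LFP spectra bend at low frequencies and need $k > 0$. The periodic spectrum
is the log-power residual after subtracting the fit; its maxima are the
oscillatory peaks (human Pk1 below / Pk2 above 15 Hz; a single smoothed
peak below 10 Hz for mouse surface EEG; sub-peaks Pk1a/Pk1b of the 2-10 Hz
window for mouse LFP, split at the most prominent smoothed local minimum).

The fit is anchored rather than least-squares, by design: the linear
variant fixes a low-frequency anchor (mean log power over the lowest
0.6 Hz of the fitting range) and chooses, among all bins above 8 Hz, the
candidate giving the line of largest slope magnitude; any shallower line
would cut through the spectrum and make periodic power negative somewhere.
The knee variant works from the other end: the high anchor is the power
minimum up to 175 Hz (skipping a 45-75 Hz hole when mains filtering left
one), the slope candidate (9-25 Hz) is the one giving the *smallest*
slope magnitude, and the knee is the mean of $k = 10^{b-y} - x^{-m}$ over
low-frequency (1.5-2.24 Hz) spectrum values below the line. Both
constructions guarantee a non-negative residual at every candidate
frequency, which the test suite asserts as a property over random spectra.

## Numerical choices in the fits

* **Anchor x-coordinates.** Every anchor or candidate y-value is an
  average over a bin and its neighbours; we give the point the mean of
  $\log_{10} f$ over the *same* bins rather than the raw bin frequency.
  With the raw-frequency convention even a spectrum of the model's own
  class is recovered with a visible discretization bias (about 0.05 in $m$
  on a 0.2 Hz grid); with the mean-log convention model-class recovery is
  exact to machine precision, which is the contract the tests pin.
* **Knee candidates on smooth spectra.** On a noiseless monotone
  Lorentzian the 1.5-2.24 Hz window contains no interior local minimum of
  log power. Real spectra have one (the dip before the first periodic
  peak), and the local-minimum rule is used when it applies; when no local
  minimum exists, every knee-window bin lying below the line contributes a
  knee estimate. Without this fallback the knee of any smooth spectrum
  would silently be zero.
* **Knee accuracy is range-limited.** The slope is estimated at 9-25 Hz,
  where a knee of $k$ still depresses the spectrum by
  $\log_{10}(1 + k/f^{|m|})$. For knees whose corner frequency
  $k^{1/|m|}$ lies inside the 1.5-2.24 Hz search window (the method's
  design range, $k \approx 2\text{-}5$ at $m = -2$) recovery is within
  ~15%; a large knee such as $k = 25$ (corner at 5 Hz) is recovered at
  about $-0.2$ in $\log_{10} k$. The tests assert $\pm 0.3$ on
  $\log_{10} k$ for $k \ge 10$, which is the honest accuracy of the
  algorithm, not a defect of the implementation.
* **Ties** in candidate selection go to the lowest frequency; plateau
  local minima take their leftmost bin. Percentiles (burst thresholds) use
  linear interpolation between order statistics (R type 7).

## Spectral estimation

Multitaper PSDs use Slepian tapers with the cross-species calibration
$TW = (FR \times \text{segment length})/2$ and $K = 2TW - 1$ tapers, so a
2 Hz resolution gives (TW 2, K 3) on 2 s human segments and (TW 5, K 9) on
5 s mouse segments; the sub-peak pass uses FR 1 Hz (TW 2.5, K 4). Epochs
are averaged in linear power before the log is taken, because fits operate
on each subject's epoch-averaged absolute spectrum. Tapers are computed
from the symmetric tridiagonal formulation; long windows seed from a
reduced-length dense solve and are polished by inverse iteration (verified
against an independent reference implementation to ~1e-13). Pediatric-style
0.1 Hz grids are produced by linear interpolation of log power, which
reproduces native bins exactly.

One bias is worth knowing about: at the lower fit edge the multitaper
estimator averages the steeply convex $f^{m}$ curve over its $\pm W$
bandwidth, so the low anchor of the linear fit sits slightly high
(~+0.1 log10 units at 2 Hz for $m=-2$, $W=1$ Hz) and the recovered slope
is correspondingly steep by ~0.1-0.15. This is a property of the method at
the published resolution, visible in the loop-closure numbers the
acceptance report prints.

## Phase-amplitude coupling

Comodulograms follow the 18-bin modulation index: band-pass both signals
(two-pass least-squares FIR, order three cycles of the band's low edge),
Hilbert transform, average the fast envelope within 18 phase bins of the
slow signal, normalize to a distribution $PA$, and compute
$MI = (\log N - H(PA))/\log N$. The band grid is 6 phase bands (2 Hz wide,
centres 3-8 Hz) by 26 amplitude bands (4 Hz wide, centres 12-62 Hz) — the
only placements consistent with the stated band counts; the alternative
10-60 step-2 centre reading is recorded in output metadata. Noise
comodulograms pair the phase of one epoch with the amplitude of a
different epoch, never the same.

A physical caveat the tests encode: amplitude modulation at $f_p$ puts
sidebands at $f_c \pm f_p$, which a 4 Hz-wide analysis band can never
capture together with its carrier. Measured MI at the grid's bands is
therefore an attenuated version of the generative coupling, and the
comodulogram maximum sits within about one phase-frequency of the coupled
amplitude centre rather than exactly on it. The generator oracle is
validated with a wide measuring band ($f_c \pm 3 f_p$), where measured MI
agrees with the analytic value to a few percent.

## Bursts and movement

Burst dynamics threshold the band-limited analytic envelope (or its
log-squared, in power units, for human data) at its 90th percentile over a
fixed-length continuous window (100 s mouse, 90 s human); supra-threshold
runs longer than 3 ms are bursts. Movement bouts are piezo excursions
above 2 mV with sub-threshold gaps shorter than 750 ms bridged; a burst
counts as "during movement" when its onset sample is in a movement state
(an overlap-fraction rule is available). Spectrograms use 2 tapers, 3 s
windows, 750 ms steps.

## The synthetic world

The generator is the oracle for every stage, and its defaults are the
stated conditions of the analyses:

* **Aperiodic background**: frequency-domain shaping of random-phase noise
  with deterministic target amplitudes, so the expected log PSD *is*
  $b - \log_{10}(k + f^{-m})$. The target is held flat below a 1 Hz
  high-pass corner because a knee-free power law diverges at DC and no
  physical recording does; this mirrors the acquisition high-pass implied
  by fitting ranges that start at "the lowest frequency unaffected by
  high-pass filtering".
* **Peaks** are injected in the time domain as envelope-modulated carriers
  so burst statistics are ground-truthed. A continuous peak of height $h$
  (log10 residual units) gets amplitude
  $a = \sqrt{2\cdot 2W\,(10^h - 1)\,P_{ap}(f_c)}$: line power $a^2/2$
  smeared over the $2W$ analysis bandwidth. Bursty peaks draw Poisson
  onsets and exponential durations; overlapping events are merged in the
  emitted ground truth because they are observationally one burst.
* **Coupling**: the slow rhythm is narrowband noise (FWHM $f_p/5$, the
  bandwidth of a physiological rhythm of quality factor ~5) rather than a
  pure sinusoid — a perfect 5 Hz clock would stay phase-locked across 5 s
  epochs and epoch shuffling could not destroy alignment. The fast
  component is narrowband noise (FWHM $f_p$) at the amplitude frequency,
  modulated by $1 + \kappa\cos\phi_{slow}$, giving the analytic
  phase-amplitude distribution $PA_j \propto 1 + \kappa\cos\phi_j$.
* **Cohorts**: group -> subject -> epoch, with additive Gaussian
  subject-level perturbations (sd 0.1 by default) on the log-scale
  parameters ($b$, $m$, peak heights) and optional additive group effects
  on any parameter. Bootstrap calibration worlds use 15 subjects per
  group, matching the mid-range of the published cohort sizes (15-67 per
  genotype); with very small groups (&le; 8) the percentile bootstrap's
  99% CIs under-cover noticeably, which is a property of the statistic,
  not of the implementation.

What a green suite establishes: the pipeline recovers the parameters of
signals *of this synthetic form* at the stated tolerances, and its
internal contracts (non-negativity, determinism, masking rules, matched
resampling) hold. It does not establish performance on real recordings
with artifacts, nonstationarity, reference choices or electrode noise, nor
does it validate the biological interpretation of any parameter.

## Statistics

Group comparisons of spectra, phase-amplitude distributions and
comodulograms use the non-parametric hierarchical bootstrap: resample
subjects with replacement, then epochs within each selected subject,
average, difference, repeat 1000 times, and read the median and the
5th/995th (99%) or 25th/975th (95%) rank values per element; elements
whose CI excludes zero are flagged. Matched mode drives both groups with
the same index streams when sizes permit (littermate-pair designs).
Noise-subtracted comodulograms resample two epoch lists per subject, the
second never positionally matching the first, and zero out cells whose CI
includes zero. Scalar metrics use stock Wilcoxon tests with BH-FDR
correction, Cliff's delta effect sizes, and $r^2 = 1 - SS_{res}/SS_{tot}$
for correlations.

## Known limitations

* EDF support covers continuous uncompressed EDF only (no EDF+
  annotations or discontinuous records).
* The exact FIR coefficients of the original filtering routine are not
  reproducible from its description; ours is a least-squares design with
  the same order rule and two-pass application.
* Human preprocessing pipelines (ICA, channel interpolation, source
  localization) are out of scope; inputs are assumed preprocessed.
* The aperiodic slope estimator is deliberately an extreme-line, not a
  regression: it trades a known steepness bias for a non-negative
  periodic spectrum. Comparisons should always be within-method.
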