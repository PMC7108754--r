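---
title: "Methods: stimulus-locked fOCT analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus-locked fOCT analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insfoct)
```

## The measurement problem

Infrared neural stimulation (INS) depolarizes cortical tissue with
pulsed 1870-nm light; functional optical coherence tomography (fOCT)
reads the evoked activity out as a fractional change of the
backscattered intensity, label-free and depth-resolved. The raw
observable is a B-M-mode series: the same cross-section (depth `z`
by lateral `x`) imaged repeatedly at 100 or 240 frames/s through a
trial of 1 s prestimulus, 0.5 s stimulation (250-us pulses at 200 Hz,
i.e. 100 pulses) and 18.5 s recovery, repeated over 15 trials at
radiant exposures of 0.3-1.0 J/cm^2 per pulse. The analysis problem
is to turn these stacks into activation maps and clean stimulus-locked
time courses despite three confounds: multiplicative speckle,
hemodynamic signals from vessels, and detection noise at depth.

All times in the package are INS-onset-locked: frame `k` at rate `f`
is stamped `(k-1)/f - 1` s, so the prestimulus window is `[-1, 0)`.

## The analysis chain

**Baseline (per pixel, per trial).** `compute_baseline()` averages the
prestimulus frames into `Ib(z,x)` and computes the sample standard
deviation `sigma_b(z,x)` (N-1 denominator, the conventional estimator
choice for N samples).

**Adaptive significance.** `detect_significant()` labels a
pixel-frame `+1` when the intensity strictly exceeds
`Ib + k*sigma_b` in `run_length` consecutive frames starting there
(defaults `k = 3`, `run_length = 5`), `-1` for the mirrored condition
below `Ib - k*sigma_b`. Ties at the threshold are not significant
(the inequalities are strict). Labels are stored at run starts —
faithful to the run-indexed inequality — and
`significance_coverage()` dilates them to every frame covered by a
run, which is what pooling consumes. The detector is invariant to
affine intensity rescaling, and its false-positive rate on blank data
is set by `k` and `run_length` alone (about `0.00135^5` per start for
Gaussian noise), which is why the run requirement is what makes the
detector usable at `k = 3`.

**Vascular exclusion.** Moving red blood cells decorrelate speckle
between adjacent B-scans. `angiogram_series()` computes, per frame
pair, `D = 1 - rho` with `rho` the windowed (default 3x3) zero-lag
normalized cross-correlation — the standard intensity-decorrelation
form; `D` is clipped to [0,1], gain-invariant, and defined as 0 for
zero-energy windows. `build_vascular_mask()` binarizes each map at a
threshold chosen by Otsu's method on the temporal-mean map (the
standard parameter-free choice; a fixed threshold can be configured),
extends every vessel label down its A-line (the shadow/tail
artifact; taking the full A-line below the vessel is the
conservative choice), and intersects
the per-frame avascular masks across all frames (logical AND), so a
vessel seen in any frame is excluded. The decorrelation value also
serves as the blood-flow velocity index (`velocity_index()`,
`run_velocity_pipeline()`); on flow phantoms it grows monotonically
with velocity from 0 to the full-refresh plateau
(`decorrelation_velocity_curve()`).

**Intensity mask.** Pixels whose baseline is not at least 6 noise
standard deviations above the noise floor are excluded
(`intensity_mask()`). The noise floor is estimated from the deepest
10% of depth rows — of the blank condition when one is available,
otherwise of the prestimulus frames of the series itself; there is no
hard-coded fallback beyond that, and the function errors with
instructions if no statistics are supplied.

**Fractional change and pooling.** `fractional_change()` computes
`dR/R = (I - Ib)/Ib`; pixels with non-positive baseline become `NA`
and are excluded rather than propagated. `aggregate_foct()` pools
dR/R over pixels that are significant AND avascular AND
intensity-sufficient, inverting the sign of negative-labeled pixels
so darkening responses normalize with positive ones, then averages
within frames and across trials.

Two pooling conventions are provided, and this was a genuinely open
design point. Pooling strictly per pixel-frame (only frames covered
by a run contribute; mode `"frame"`) leaves the prestimulus part of
the course undefined, because almost no pixel is significant before
the stimulus — yet the onset-latency definition needs exactly that
prestimulus baseline, and a stimulus-locked course is only
interpretable with one. The default mode `"pixel"` therefore
selects, per trial,
the pixels that carried a significant run anywhere in the trial and
pools them at every frame with the sign of their dominant label;
mode `"frame"` remains available and flags (rather than zeroes)
frames with no eligible pixels. `depth_resolved()` repeats the
aggregation in half-open 100-um depth slabs (six bins, 0-600 um).

**OISI.** `oisi_signal()` computes the same per-pixel fractional
change on the camera series, averaged over a 20x20-pixel ROI and over
trials, with no masks — speckle and depth do not apply to the
incoherent en-face modality.

**Latency, dose, coregistration, spikes.** `onset_delay()` reports
the first sample at `t >= 0` where the signal power exceeds the
prestimulus mean of the power by `k = 3` of its prestimulus SD;
power is `|value|` (a squared option exists), which treats scattering
increases and OISI darkening uniformly. No sub-sample interpolation
is attempted, so the resolution is one frame interval (4.2 ms at
240 fps, 17 ms at 60 fps). A frame-wise 3-sigma rule fires on
isolated noise excursions roughly once per several hundred frames,
so on a course with many samples between `t = 0` and the true
response (the velocity index has ~240) a plain first crossing would
report a spurious early onset in a substantial fraction of
realizations; the crossing is therefore required to hold for 5
consecutive samples — the same consecutive-frames logic the adaptive
significance detector uses against spontaneous fluctuations — and
the onset is the first sample of that run (identical to the plain
rule on noiseless steps). `peak_delay()` is the
earliest argmax of `|value|` after onset. `dose_response_fit()` is
ordinary least squares of peak value on exposure with Pearson's r.
`coregister()` does an exhaustive integer translation search
maximizing Pearson correlation over the overlap (ties: smallest
shift, then lexicographic); rotation and scale are out of scope since
the acquisition shifts a ROI only. The electrophysiology branch
thresholds negative-going crossings at -41 mV with a 1-ms refractory
period (`detect_spikes()`), bins half-open PSTHs (`build_psth()`),
compares per-trial spike counts in `[0, 0.5)` s against `[-0.5, 0)`
and `[0.5, 1.0)` s by paired two-tailed t-tests
(`ins_response_test()`; identical counts give t = 0, p = 1, constant
nonzero differences are flagged as degenerate), and reads the spike
onset from the first 1-ms PSTH bin above the prestimulus mean + 3 SD.

## The synthetic test bed

No public recordings exist for this preparation, so the package
ships a generator whose defaults are the reference acquisition and
response conditions, and whose
ground truth makes every stage testable.

**Speckle and vessels.** A static reflectivity map (exponential depth
attenuation, 300-um length) is multiplied by a per-pixel exponential
speckle factor drawn once per trial — fully developed speckle with
the correct unit-mean multiplicative statistics. Vessel pixels redraw
their speckle each frame with probability
`m = min(1, v * dt / beam_width)` (beam width 10 um, the lateral
resolution): a scatterer population moving at `v` replaces a fraction
`m` of the resolution cell between frames. The redraw keeps the
exponential marginal exact and gives adjacent-frame correlation
`1 - m`, hence decorrelation monotone in velocity with saturation at
`v = beam_width * fps` — the behavior the flow-phantom calibration
verifies. Tail pixels under each vessel get 0.6x intensity and half
the vessel's redraw probability (shadowing plus decorrelation
leakage). Detector noise is additive zero-mean Gaussian with SD 5% of
the mean tissue reflectivity, then intensities are clipped at zero
(material only in the deep noise rows).

**Response template.** The activation disc (0.4 mm lateral diameter,
0-500 um depth, at the frame center) modulates reflectivity by
`1 + s(t) * E` where the template `s` is zero before the onset delay,
rises to its peak amplitude at the peak delay, and recovers
exponentially (tau = 2 s). The rise is
`0.5*u^(1/4) + 0.5*u^3` in normalized time `u` — a fast saturating
component plus a slower accumulating one. The shape is the package's
own choice (only onset, peak time and amplitude are anchored to the
reference measurements the generator emulates): the evoked
scattering response is synchronous with stimulus onset at the
temporal resolution of the instrument, which requires a steep
departure from baseline; a
half-cosine or linear rise has (near-)zero initial slope and would
push any threshold-crossing onset estimate tens of milliseconds late
regardless of SNR, contradicting the latencies the generator is
supposed to emulate. The cubic component keeps the approach to the
peak non-flat so the argmax is well defined against noise. Defaults:
fOCT onset 30 ms, peak 528 ms, sign +1, amplitude calibrated so the
programmed fractional change at t = 0.5 s equals 2.5% at 1 J/cm^2;
OISI onset 40 ms, peak 533 ms, sign -1, 0.12% at 0.5 s (the OISI
latencies are the fOCT values plus the ~10/~5 ms modality lags, which
are the quantities actually measured). The reference amplitudes are
trial means quoted at t = 0.5 s — just before the respective peak
times — so the calibration anchors the template at that time rather
than at its maximum (the implied maxima are 2.74% and 0.134%).
Amplitude scales linearly with
exposure (slope = amplitude at 1 J/cm^2, intercept 0), and per-trial
amplitudes carry multiplicative Gaussian jitter with CV 20%,
consistent with the reference trial scatter (0.52% on 2.5%).

**Hemodynamics.** Vessels optionally respond to INS with a velocity
step `v -> v * (1 + 0.5 * E)` at 1.0 s after onset (plateau to 6 s,
exponential recovery, tau = 3 s): functional-hyperemia onset latency
of about a second, with a velocity increase in the tens of percent.

**OISI scene.** Uniform reflectance with dark surface vessels (shared
with the OCT scene so coregistration is testable) and a central
activation disc darkened by the OISI template. Camera noise is
additive with SD 0.2% of mean reflectance — the shot-noise scale of a
high-full-well scientific camera. This value matters: the generator
must make its programmed latencies recoverable (that is its stated
validation purpose), and at ~0.5% noise the 3-sigma onset threshold
of the trial-averaged ROI course lands within a fraction of a
standard deviation of the course value at the first frame after the
40-ms onset, so the estimated onset flips between adjacent frames
from seed to seed. At 0.2% the first informative frame clears the
threshold with a >4-sigma margin.

**Spikes.** Inhomogeneous Poisson trains (baseline 5 Hz, 200 Hz
during the drive, 4-ms onset latency, 30 trials) — a deliberately
minimal rate model sufficient for PSTH, paired-test and onset-latency
validation.

**What the generator does not emulate.** No spectral-domain forward
model (intensities are generated directly, not reconstructed from
spectra); no wavelength-dependent absorption or photothermal physics;
no bulk motion, breathing or slow drift; speckle is spatially
uncorrelated between pixels rather than point-spread-correlated;
vessels are rectangular blocks; the neural and hemodynamic responses
are deterministic templates plus amplitude jitter, with no
trial-to-trial latency jitter. Tests passing on these data therefore
validate the algebra and the estimators — masking, inversion,
averaging, thresholds, latencies, dose slopes — not robustness to
motion artifacts or physiological variability in real recordings.

## Numerical and degenerate-input choices

- Frame geometry default 64 x 64 px at 10 um pitch: 640 um depth
  covers the six 100-um bins, the 0.4-mm activation disc spans 40 px.
  These sizes, with the full 20-s, 15-trial protocol at 240 fps, are
  the problem sizes used by the package's own validation runs.
- Intensities are stored linearly; TIFF pages are 32-bit samples
  scaled into [0,1] by a power-of-two factor recorded in the JSON
  sidecar (a write-load cycle is exact to one 32-bit quantum).
- Otsu binarization degenerates gracefully: an all-zero decorrelation
  stack yields "no vessels" rather than an arbitrary threshold.
- Zero-energy correlation windows give D = 0; D is clipped to [0,1].
- A pixel labeled both + and - at different times contributes with
  each label's sign at the respective times in `"frame"` pooling; in
  `"pixel"` pooling its dominant label wins (ties: positive). A
  simultaneous +/- conflict is impossible by construction.
- Frames (or depth slabs) with no eligible pixels are `NA` and
  flagged, never silently zero; a blank run with no significant
  pixels reports "not detected" latencies.
- `which.max` tie-breaking gives the earliest peak; coregistration
  ties prefer the smallest shift.
- Seeds: every generator takes an explicit integer seed and is
  bit-reproducible; pipeline stages derive sub-seeds by fixed
  offsets.

## Known limitations

- The onset estimator inherits the frame-interval quantization and a
  small spurious-crossing probability (a 3-sigma rule applied to a
  handful of pre-onset frames); both are properties of the
  threshold-crossing definition itself, not of the implementation.
- The peak estimator is a raw argmax; on a flat-topped course its
  Monte-Carlo spread is tens of milliseconds at the default SNR.
- Otsu's threshold assumes a bimodal decorrelation histogram; scenes
  with no vessels at all are handled by the degenerate branch, but
  near-zero-contrast vessels may binarize poorly — a fixed threshold
  can be configured for such data.
- `"pixel"` pooling conditions on significance detected anywhere in
  the trial, which can admit a small selection bias in the pooled
  amplitude at low SNR; the spec-literal `"frame"` mode is available
  for sensitivity checks.
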