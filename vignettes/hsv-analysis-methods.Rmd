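---
title: "Methods: high-speed videoendoscopy and acoustic voice analysis with hsvoice"
author: "hsvoice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-speed videoendoscopy and acoustic voice analysis with hsvoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsvoice)
```

## The measurement problem

Laryngeal high-speed videoendoscopy (HSV) films the vocal folds at 4000
frames per second, resolving every oscillation cycle of phonation (typical
fundamental frequencies are 100-400 Hz). A paired audio interface records
the subject's voice together with the camera's per-frame synchronization
pulse at 80 kHz / 24 bit. From such a recording, clinicians want a compact
set of quantitative descriptors: how regular the oscillation is (jitter,
shimmer, perturbation quotients), how the glottis opens and closes within a
cycle (open/closing/speed quotients, speed index, glottal gap index), how
symmetric the two folds are (amplitude symmetry and phase asymmetry
indices), and how periodic the radiated sound is (HNR, cepstral peak
prominence). `hsvoice` implements this pipeline headlessly:

1. **sync** - locate the camera end trigger and per-frame pulses in the
   reference channel and map video frames onto audio samples;
2. **segmentation** - per-frame binary glottis masks (classical baseline,
   or any plug-in model that maps a frame to a probability map);
3. **waveform** - the glottal area waveform (GAW: segmented pixels per
   frame), cycle detection, phase decomposition;
4. **midline / hemi-GAW** - the glottal symmetry axis, anterior/posterior
   points, and per-fold area waveforms;
5. **pvg** - the phonovibrogram, a 2-D fold-position x time image of
   lateral displacements;
6. **parameters** - 18 GAW-based and 9 audio-based clinical measures;
7. **quality** - blind image quality scoring (NIQE);
8. **synthetic** - a ground-truthed generator that emulates the whole
   acquisition, making every stage testable without hardware.

## Audio-video alignment

The camera emits one pulse per recorded frame; recording continues for
about one second after the end trigger, so the reference channel is a pulse
train followed by a quiescent tail. We compute a rolling standard deviation
with a 2.5 ms centered window (edges use shrunken windows; no padding
values are invented), z-score it, and locate the end trigger at the most
prominent peak of the z-trace's difference *across one window length*. A
single-sample difference would spread the pulsed-to-quiescent drop over the
~200-sample window and never produce a prominent peak; the lagged
difference captures the full drop. If no peak is prominent, the fallback is
the last sample above the midpoint of the z range (a fixed threshold such
as z > 1 fails whenever more than half of the recording is pulsed, which is
the norm for a 1.6 s recording with a 1 s tail). Either way a candidate
must be followed by a quiescent tail; otherwise a trigger-not-found error
is raised. Frame pulses are peaks of the raw reference before the trigger,
with auto-detected polarity, a height threshold at 50% of the
99th-percentile amplitude, and a minimum spacing of half the nominal frame
interval. A >2% disagreement between detected and nominal spacing logs a
warning, catching misconfigured frame-rate metadata.

## From masks to cycles and phases

The GAW is the per-frame count of segmented glottis pixels. Cycles are
detected by peak finding with a prominence of at least 10% of the GAW range
(rejecting segmentation flicker); cycle boundaries are the minima between
consecutive maxima, so every complete cycle runs minimum-to-minimum around
one maximum. Partial cycles at the signal edges are discarded; a signal
endpoint already at the minimum level is accepted as a boundary only when
the edge cycle it closes has at least 75% of the median cycle length -
otherwise a recording that starts inside the closed phase would contribute
a spurious half cycle.

**Closure convention.** The source platform never states how "open" versus
"closed" frames are decided. We call a frame open when its area exceeds
`closure_eps * a_max` of its cycle, with `closure_eps = 0.02` by default: a
small fraction of the cycle's *peak* area. Anchoring the threshold at the
cycle minimum instead (a_min + eps * amplitude) looks natural but makes
"never closes" unrepresentable - the minimum frame is below that threshold
by construction, so a strictly positive GAW could never reach an open
quotient of 1.000, which healthy phonation demonstrably does (it is the
cohort maximum in the validation data). With our convention a glottis whose
residual gap exceeds 2% of its peak area is open throughout and OQ is
exactly 1. The opening phase runs from the closure instant (the last closed
frame before the open run, or the cycle start if the cycle never closes) to
the cycle maximum; the closing phase from the maximum to the first closed
frame after the open run. Phase durations are frame-quantized; no sub-frame
interpolation is attempted, and all phase-quotient tests allow one frame of
quantization.

From the decomposed cycles: OQ = t_open/T, CQ = t_closing/t_open,
SQ = t_opening/t_closing, AQ = t_opening/(t_opening + t_closing),
RQ = (t_closed + t_opening)/t_closing,
SI = (t_opening - t_closing)/(t_opening + t_closing). Cycle amplitude is
`a_max - a_min` (peak-to-trough), so perturbation measures are independent
of a residual-gap offset. GGI is the mean per-cycle `a_min/a_max`; the
amplitude quotient divides the amplitude by the steepest per-frame area
decline; stiffness is the mean absolute per-frame area change normalized by
the amplitude.

**Amplitude perturbation.** APF = 100 * mean(|A_i - A_{i+1}| / A_i).
APQk = 100 * mean(|A_i - mean(k-window centered at i)|) / mean(A), the
MDVP-style definition. Under it a wider window leaves a *larger* residual
deviation on impulsive perturbations, so APQ3 < APQ5 < APQ11 on typical
material - the ordering the clinical validation data shows.

## Midline, hemi-GAWs, phonovibrogram

The glottal midline is estimated at each cycle maximum from the sum of the
masks within two frames of the maximum (temporal context suppresses
single-frame segmentation noise). Its direction is the principal axis of
the summed mask - via central image moments
(orientation = 0.5 atan2(2 mu11, mu20 - mu02)) or PCA of the weighted pixel
coordinates; the two are algebraically identical for binary masks and both
are provided. Isotropic masks (equal eigenvalues) are flagged degenerate.
The direction is normalized posterior-to-anterior; by default the image-top
extreme is posterior (the typical 70-degree rigid endoscope orientation),
and the flag is configurable because the orientation depends on endoscope
handling. Anterior/posterior points are the extreme projections of mask
pixels onto the midline. "Left" and "right" are *image* coordinates
(image-left = smaller x); the anatomical mapping is deliberately not
assumed and the convention is stamped into all metadata.

Each mask pixel is assigned to a fold by the sign of its signed
perpendicular distance to the temporally nearest midline; pixels within
half a pixel of the line are split half/half, so left + right equals the
total GAW exactly, frame by frame. Note one estimator property verified on
synthetic data: because the midline passes through the mask centroid, it
sits slightly toward the wider fold, compressing the measured left/right
amplitude ratio toward 1 by about 0.03 at a true ratio of 0.8. The
amplitude symmetry index is min/max of the per-cycle hemi amplitudes
(healthy values are near 1); the phase asymmetry index is the left/right
lag of the hemi maxima as a fraction of the period, wrapped to <= 0.5.

The phonovibrogram samples M = 64 stations between the posterior and
anterior points; at each station and frame, the lateral distance from the
midline to the farthest mask pixel within half a station spacing of the
perpendicular. Left-fold distances fill rows 1..M (posterior at row 1),
right-fold distances mirror below so the anterior ends meet at the
horizontal center - the layout of the phonovibrogram literature. Values are
raw pixel distances; no per-recording normalization is applied.

## Audio parameters

Audio cycle marks start from peaks of the waveform band-passed to 0.5-1.5
times an autocorrelation F0 prior. The period of each cycle is then
measured by waveform matching: the lag maximizing the normalized
cross-correlation of the raw waveform between consecutive marks, with
parabolic sub-sample interpolation and rejection of lags deviating more
than 30% from the prior (octave errors). Landmark-based periods (peak
positions) are deliberately avoided: a landmark at a fixed fraction of the
cycle mixes adjacent periods and attenuates measured jitter by tens of
percent, which we verified on the generator where true per-cycle periods
are known.

HNR follows the cycle-averaging construction: each detected cycle is
resampled to the mean cycle length, aligned to the first cycle by the best
integer shift, and HNR = 10 log10(N * sum(mean_waveform^2) /
sum(residual^2)), capped at 120 dB for a vanishing residual.

CPP is the smoothed-cepstral-peak variant: dB power cepstra (the log power
spectrum of the log power spectrum) of half-overlapping Hann frames are
averaged, lightly smoothed along quefrency (0.1 ms moving average), and the
peak in the 2-16.7 ms quefrency band (60-500 Hz) is measured against a
linear regression of the cepstrum on quefrency over that band. A
single-shot whole-signal cepstrum was rejected: its noise floor is an
extreme-value statistic of the ~1200 quefrency bins in the band (~16 dB for
white noise), which would make the score useless as a periodicity
indicator; frame averaging keeps white noise below ~3 dB while a synthetic
voice with realistic jitter scores 10-13 dB and a noise-free pulse train
scores ~25 dB. All samples of the segment still contribute.

## Image quality (NIQE)

Quality-aware features are the generalized-Gaussian fit of MSCN
coefficients (Gaussian-weighted 7x7 local normalization) and asymmetric-GGD
fits of their four pairwise products, per patch, at two scales - 36
features per patch. A reference multivariate Gaussian (mean, covariance) is
fitted to sharp patches of pristine images; the score is
sqrt((nu - mu)' ((Sigma + Sigma_test)/2)^-1 (nu - mu)) for the test image's
own Gaussian fit. NIQE scores are only comparable under the *same*
reference model, so the model's provenance travels with it. The packaged
default model is fitted at run time from seeded **synthetic** clean
endoscopy-like scenes; it supports relative judgments (distortion
monotonicity, ranking of recordings) but its absolute scale is not that of
models fitted to natural photographs, and published absolute scores cannot
be reproduced with it.

## The synthetic world

The generator states, once, the world the tests live in; its defaults are
the healthy phonation conditions of the validation cohort:

| parameter | default | rationale |
|---|---|---|
| `f0` | 300 Hz | cohort mean ~302, range 235-412 Hz |
| `fps` / `audio_rate` | 4000 / 80000 Hz | acquisition protocol |
| `duration` | 0.25 s | the recommended 1000-frame segment |
| `open_quotient_target` | 1 | cohort OQ 0.989-1.000: no closed phase |
| `glottal_floor` | 0.12 | cohort GGI 0.000-0.367 |
| `speed_index_target` | 0 | cohort SI ~ 0, CQ ~ 0.5 |
| `left_right_amp_ratio` | 0.97 | cohort ASI 0.932-0.993 |
| `left_right_phase_lag` | 0.03 | cohort PAI 0.006-0.258 |
| `jitter_sigma` | 150 us | cohort mean GAW jitter ~0.18 ms = 2 sigma/sqrt(pi) |
| `shimmer_sigma` | 0.002 | cohort GAW shimmer ~0.26% |
| `noise` | 5 (8-bit) | moderate sensor noise |
| `audio_snr_db` | 30 dB | clean head-mounted microphone |

A cycle is a piecewise-sinusoidal opening template. With a closed phase
(OQ < 1) the edges take off linearly - vocal-fold collision ends the cycle
abruptly - so the rasterized closure instant is sharp. Without one (OQ = 1)
the folds never collide and the waveform touches its minimum with zero
derivative, so the sampled minimum reflects the glottal floor rather than
the sampling phase. The video renders a dark lens (two opposed parabolic
edges about the midline, zero displacement at the commissures) on bright
textured tissue with Gaussian pixel noise; exact rasterized masks are
returned as ground truth, along with the true midline geometry. The audio
channel is the time derivative of a Rosenberg glottal flow pulse train (the
radiated pressure is proportional to the flow derivative) whose pulse
durations are fixed fractions of the *nominal* period: period jitter is
realized as onset timing with a stable intra-cycle shape, so a cycle-locked
landmark carries the full injected perturbation and both waveform
excursions scale with the cycle amplitude. The reference channel carries
one unit pulse per frame and 1 s of quiet tail after the trigger, as in the
acquisition protocol.

What the generator does **not** emulate: mucosal-wave propagation and
tissue biomechanics (no two-mass model), vocal-tract filtering and
formants, camera motion, specular reflections, irregular pathological
regimes (subharmonics, biphonation), and real endoscopic texture. A green
test therefore establishes that the *measurement chain* is faithful on
signals with known structure - not that the segmentation model generalizes
to clinical images, nor that parameter norms transfer to patients.

## File formats

Recording bundles are directories: `frames/` and `masks/` as lossless
binary PGM stacks, `audio.wav` (two-channel integer PCM; a hand-rolled
RIFF reader/writer supports 16/24/32-bit and float), `metadata.json`
(acquisition metadata, alignment, coordinate and left/right conventions),
`parameters.csv` (one row per parameter with name, value, unit, source
signal, formula id) and `pvg.csv`. The clinical mp4/h264 and HDF5
containers of the original platform have no offline R support in this
environment; PGM directories are the lossless interchange path (mp4
decoding is external, e.g. `ffmpeg -i video.mp4 frames/frame_%05d.pgm`),
and all round-trip guarantees are stated on them. Pixel coordinates are
0-based, x right, y down, stamped in every metadata file.

## Numerical choices and degenerate inputs

* Rolling statistics subtract the signal mean before forming cumulative
  sums (catastrophic cancellation otherwise leaves ~1e-7 residuals on
  constant signals).
* Peak prominence is computed only for candidates whose height above the
  global minimum already reaches the threshold; the full base scan is
  O(n) per peak and would dominate on 100k-sample references.
* Otsu thresholding runs on a 256-bin histogram; frames with an intensity
  range below 30 (featureless, e.g. fully closed glottis) yield empty
  masks rather than noise.
* Empty masks: GAW frames of 0; PVG columns of 0; midline-undefined errors
  only when *all* cycle anchors are empty.
* The NIQE combined covariance falls back to a ridge-regularized inverse
  (with a logged warning) when singular.
* HNR returns the 120 dB cap (configurable) for a zero residual instead of
  infinity.
* All generator randomness derives from one integer seed; schedules are
  bit-identical across runs.

## Known limitations

* Phase timings are frame-quantized; at 4000 fps and F0 400 Hz a cycle has
  only 10 frames, so quotients carry ~0.1 quantization noise per cycle
  (averaging over >= 20 cycles is the recommended practice for a reason).
* GAW-side jitter at healthy magnitudes (~0.2 ms) sits below the 0.25 ms
  frame duration; the audio channel is the reliable perturbation source,
  and the package measures it there.
* The centroid-anchored midline slightly compresses left/right asymmetry
  (see above); strongly lateralized pathologies would need an
  anatomically anchored midline.
* The classical threshold segmenter assumes the glottis is the darkest
  central structure; clinical use should plug in a trained model via
  `segment_model()`.
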