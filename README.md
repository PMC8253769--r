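# hsvoice

Headless analysis of laryngeal high-speed videoendoscopy (HSV) paired with
acoustic voice recordings, in R.

HSV films the vocal folds at 4000 fps, resolving every oscillation cycle of
phonation; a paired audio interface records the subject's voice together
with the camera's per-frame synchronization pulse at 80 kHz. `hsvoice`
turns such a recording into clinically interpretable numbers:

* **Audio-video alignment** — rolling standard deviation (2.5 ms window) of
  the reference channel, z-scoring, end-trigger localization at the
  pulsed-to-quiescent edge, per-frame pulse detection, and extraction of
  the audio segment matching a chosen frame range.
* **Glottis segmentation** — per-frame binary masks via a classical
  baseline (inversion + Otsu + largest central component) or any plug-in
  model that maps a frame to a probability map (e.g. a trained
  encoder-decoder network).
* **Glottal area waveform (GAW)** — A(t) = segmented pixels per frame;
  cycle detection by prominence-filtered peak finding with
  minimum-to-minimum cycle boundaries; phase decomposition into opening,
  closing and closed phases relative to a closure threshold
  (`closure_eps * a_max`, default 2% of the cycle peak area).
* **Midline, hemi-GAWs, phonovibrogram** — the glottal symmetry axis from
  image moments or PCA of the mask (temporal context summed over ±2
  frames), anterior/posterior commissure points, per-fold area waveforms
  (left + right = total, exactly), and the 2M × T phonovibrogram of
  lateral fold displacements.
* **Clinical parameters** — 18 GAW-based and 9 audio-based measures:
  mean jitter and jitter% (period perturbation), mean shimmer (dB) and
  shimmer% (amplitude perturbation), F0 = 1/mean(T_i),
  OQ = t_open/T, CQ = t_closing/t_open, SQ = t_opening/t_closing,
  AQ = t_opening/(t_opening+t_closing), RQ = (t_closed+t_opening)/t_closing,
  SI = (t_opening−t_closing)/(t_opening+t_closing),
  GGI = mean(a_min/a_max), amplitude quotient, stiffness, APF, APQ3/5/11,
  ASI = min(A_L,A_R)/max(A_L,A_R), PAI = |t_L−t_R|/T;
  audio-side HNR (cycle-averaging construction) and smoothed cepstral peak
  prominence (CPP).
* **Image quality** — NIQE: multivariate-Gaussian distance of GGD/AGGD
  features of MSCN coefficients against a pristine-image reference model
  (the packaged default model is fitted from synthetic clean scenes and
  supports relative comparisons only).
* **Synthetic generator** — seeded, fully ground-truthed phonation
  recordings (video + masks + paired audio + reference pulses) emulating
  the acquisition, so the entire pipeline is testable without hardware.

## Worked example

```r
library(hsvoice)

spec <- phonation_spec(f0 = 300, duration = 0.25, seed = 11)  # healthy defaults
rec  <- synth_recording(spec)       # video + ground-truth masks + audio
out  <- run_pipeline(rec, verbose = FALSE)
print(out$report)
```

```
Clinical parameter report
  mean_jitter_ms                 0.1520 ms  [GAW]
  jitter_pct                     4.5654 %   [GAW]
  mean_shimmer_db                0.0557 dB  [GAW]
  shimmer_pct                    0.6410 %   [GAW]
  f0_hz                        300.3003 Hz  [GAW]
  open_quotient                  1.0000 au  [GAW]
  closing_quotient               0.4926 au  [GAW]
  speed_quotient                 1.0381 au  [GAW]
  asymmetry_quotient             0.5074 au  [GAW]
  rate_quotient                  1.0381 au  [GAW]
  speed_index                    0.0148 au  [GAW]
  glottal_gap_index              0.1302 au  [GAW]
  amplitude_quotient             4.2302 au  [GAW]
  stiffness                      0.1503 au  [GAW]
  apf                            0.6414 au  [GAW]
  apq3                           0.3461 au  [GAW]
  apq5                           0.4266 au  [GAW]
  apq11                          0.4394 au  [GAW]
  amplitude_symmetry_index       0.9896 au  [GAW]
  phase_asymmetry_index          0.0353 au  [GAW]
  mean_jitter_ms                 0.1467 ms  [Audio]
  jitter_pct                     4.4061 %   [Audio]
  mean_shimmer_db                0.0728 dB  [Audio]
  shimmer_pct                    0.8385 %   [Audio]
  f0_hz                        300.3241 Hz  [Audio]
  hnr_db                        12.7309 dB  [Audio]
  cpp_db                        11.2298 dB  [Audio]
  apf                            0.8394 au  [Audio]
  apq3                           0.4809 au  [Audio]
  apq5                           0.5144 au  [Audio]
  apq11                          0.5434 au  [Audio]
```

Reading it: the glottis never fully closes (OQ 1.0, with a residual gap of
13% of the peak area, GGI), cycles are time-symmetric (CQ ≈ 0.5, SI ≈ 0),
the folds oscillate almost symmetrically (ASI 0.99, PAI 0.035), the
audio- and GAW-derived fundamental frequencies agree to a fraction of a Hz
(the synchronization check), and HNR/CPP above ~11/10 dB indicate clean
periodic phonation. `plot(out$gaw)` draws the area waveform and
`plot(out$pvg)` the phonovibrogram.

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic anchors from
scratch against the installed package: the median audio-vs-GAW F0
difference over 20 freshly generated paired synthetic recordings
(F0 100-400 Hz), and the closing quotient and speed index of an exactly
time-symmetric synthetic GAW. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It prints the three values and writes them as JSON.

## Vignette

`vignettes/hsv-analysis-methods.Rmd` documents the models and conventions:
the closure threshold and phase definitions, the midline and left/right
conventions, the audio period estimator, the HNR/CPP constructions, the
NIQE reference-model caveats, what the synthetic world does and does not
emulate, and known limitations.
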