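---
title: "Heart-sound segmentation and Mahalanobis-distance diagnosis: methods"
author: "pcgmdc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound segmentation and Mahalanobis-distance diagnosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgmdc)
```

This vignette documents the model underlying `pcgmdc`, the parameters a
user can tune, the numerical decisions taken where the mathematics leaves
room, what the synthetic simulator does and does not emulate, and the
known limitations.

## The three-stage model

A phonocardiogram (PCG) records the valve-closure transients S1 and S2
plus, in disease, murmur noise between them. The pipeline assumes:

* heart sounds carry their energy in roughly 20–700 Hz;
* each cardiac cycle contains exactly one S1 and one S2 burst;
* diastole (S2 → next S1) is longer than systole (S1 → S2).

**Stage 1** extracts the *complex sounds*. The preprocessed trace (db10
wavelet band-pass to ≈21.5–689 Hz, unit peak) is turned into a
Viola-integral envelope — the windowed local variance over a 50 ms
half-window — and the envelope is swept with an antisymmetric ~1 s kernel
(the short-time modified Hilbert transform, STMHT). Because the kernel is
odd, it responds to envelope asymmetry: its signed zero crossings fall on
envelope mass centers (negative-to-positive, N2P, at S1/S2 burst centers)
and on the centers of the gaps (positive-to-negative, P2N). The
diastole > systole premise disambiguates which N2P is S1, and the P2N
midpoints become cycle boundaries: CS1 runs from a diastolic midpoint
through S1 to the following systolic midpoint; CS2 is the complement of
the cycle. CS1/CS2 segmentation avoids the harder four-state
(S1/systole/S2/diastole) problem while still splitting each cycle into
two windows with distinct diagnostic content.

**Stage 2** computes, per segment, the magnitude DFT restricted to the
half spectrum (the magnitude of a real signal's DFT is symmetric; the
Hz-valued features below are only meaningful there), smooths it with a
double-window operator into a unit-maximum *secondary envelope*, and reads
off four features: the widths between the outermost crossings of the 0.3,
0.5 and 0.8 threshold lines, and the spectral gravity center. Eight
features per cycle (four per segment) are standardized and projected onto
the leading three principal components.

**Stage 3** models the projected features with a seven-component
full-covariance Gaussian mixture, one component per diagnostic class
(MR, MS, ASD, NM, AS, AR, VSD). Under component k the squared Mahalanobis
distance is χ²(3)-distributed, so a confidence level β_k defines an
ellipsoidal decision region with threshold `qchisq(beta_k, 3)`. A point
inside no ellipsoid is `"unknown"`; inside several, the class minimizing
`d²_k / MDC_k` wins — the normalization respects the differing per-class
confidence levels, and the fitted ellipsoids barely overlap, so the
tie-break is rarely exercised.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `low`, `high` | 21.5, 689 Hz | wavelet band-pass edges |
| `half_width` | `round(0.05 * fs)` (2205 at 44.1 kHz) | envelope half-window; a 50 ms time constant |
| `window_length` | nearest odd to `fs` (44101 at 44.1 kHz) | STMHT window; ~1 s, the cardiac-cycle scale |
| `min_event_gap` | 0.05 s | refractory gap below which opposite crossings are treated as noise blips |
| `L1`, `L2` | 9, 17 bins | secondary-envelope smoothing half-widths |
| `thv_list` | 0.3, 0.5, 0.8 | width threshold lines on the unit envelope |
| `m` | 3 | retained principal components (86.73 % variance for the bundled constants) |
| `K` | 7 | mixture components, one per class |
| `regularization` | 0.01 | added to covariance diagonals each M-step |
| `beta` grid | 0.63–0.97 step 0.02 | candidate confidence levels |

The window constants are *time* constants: recordings are resampled to
44.1 kHz by default (`load_recording(fs_target = 44100)`), and when
resampling is disabled the windows scale with the native rate. All
examples and tests in this package run the simulator at 4 kHz — everything
in the 20–700 Hz band is representable there and the ~1 s STMHT
convolutions stay cheap — with window lengths scaled accordingly.

## Numerical decisions

* **Envelope borders.** The windowed variance is defined on
  `[W, M-1-W]`; the border is filled by edge replication rather than
  truncation so all derived traces stay index-aligned with the recording.
  The running-sum implementation centers the signal globally first
  (variance is shift-invariant) to avoid catastrophic cancellation.
* **STMHT borders** are zero-padded; events within about half a window of
  either end are therefore unobservable, and a 10-cycle recording
  typically yields 7–9 complete cycles rather than 9.
* **Zero dwells.** The signum difference test (±2) silently assumes the
  curve never rests at exactly zero; exact zeros carry the neighbouring
  nonzero sign so a `-, 0, +` run produces exactly one crossing.
* **Refractory filter.** Genuine N2P/P2N events are separated by a
  quarter cycle or more; murmur noise makes the STMHT wobble across zero
  on near-flat stretches, producing crossing pairs milliseconds apart.
  Adjacent opposite crossings closer than 50 ms (the envelope time
  constant) are removed, shortest pair first. `min_event_gap = 0`
  restores the raw crossing set.
* **Event alignment.** The cycle-pairing recurrence indexes the two event
  streams with the P2N stream leading — the i-th P2N is the midpoint just
  before the i-th N2P — which is the phase that makes CS1 contain S1.
  Leading N2P events before the first P2N are dropped; duplicate boundary
  candidates produced by the recurrence's two branches are deduplicated;
  pairing stops where the recurrence would index past either array.
* **Half-open spans.** CS1 = `[cs21, cs12)`, CS2 = `[cs12, cs21_next)` in
  sample indices, so adjacent segments never share a sample and their
  concatenation reproduces the cycle exactly. Incomplete trailing cycles
  are dropped; the feature stage needs complete segments.
* **Secondary envelope.** With the default `(L1, L2) = (9, 17)` the inner
  window range of the printed operator is empty and the smoother is
  purely triangular; the `swap_windows` switch implements the other
  reading (roles exchanged), since the printed setting is ambiguous about
  which width is "first". Edges use reflected padding. For some
  `(L1, L2)` the operator can dip below zero on sharp spectra; values are
  clamped at zero before normalization so gravity and widths stay
  well defined.
* **Widths** use integer-bin outermost crossings (first and last bin
  strictly above the threshold), no interpolation, and a width of 0 when
  a threshold is never exceeded — sounds with missing spectral components
  still yield a complete feature vector.
* **PCA.** Columns are standardized by mean and SD; the eigenvalues of
  the standardized covariance then sum to the feature count (8), which the
  tests assert. Eigenvector signs are fixed so the largest-magnitude
  loading is positive — classification is otherwise sign-ambiguous.
* **EM.** With labelled training data the responsibilities are held at
  the one-hot labels: this complete-data EM converges in one M-step to
  the class-conditional moments and keeps a strict one-to-one
  component–class correspondence. Running free EM from a labelled start
  was observed to let diffuse components absorb or swap with compact
  neighbouring classes whenever clusters overlap, silently corrupting the
  correspondence. Unsupervised fits use a seeded k-means start and free
  EM; their components are matched to classes afterwards by maximizing
  the label/component contingency over all one-to-one assignments
  (`match_components()`), which unlike a per-component majority vote
  cannot assign one label twice.
* **β selection** sweeps a common confidence level over the grid,
  computes each class's one-vs-rest accuracy, and returns per class the
  *largest* level within 1e-9 of that class's maximum — the largest
  admissible ellipsoid at the best accuracy.
* **Serialization.** Classifier JSON writes doubles with 17 significant
  digits, which re-parse to identical bit patterns; the general-purpose
  JSON writers cap at 15 and lose ulps.
* **Bundled constants.** The packaged PCA loadings reproduce their
  published source, whose printed eigenvectors are mutually orthogonal
  only approximately (ξ₁·ξ₂ ≈ −0.14 at the printed precision, unit norms
  hold to ~1e-4). Projections with the bundled model therefore mix a
  small amount of the leading component into γ₂; models fitted with
  `fit_pca()` are orthonormal to machine precision.

## The synthetic PCG simulator

`generate_recording()` builds cycles of Gaussian-windowed tone bursts
(S1 at 70 Hz, S2 at 120 Hz by default — inside the 30–100 / 50–150 Hz
bands where these sounds live), with systole 0.3 s, diastole 0.5 s,
mild heart-rate variability (3 % SD on interval durations, truncated so
diastole always exceeds systole), 10 % SD amplitude jitter on bursts and
murmurs, and additive white noise (SD 0.02 relative to unit burst peak).
Murmurs are *random-phase multisines* — one sinusoid every ~4 Hz across
the band with uniform phases — i.e. spectrally flat band-limited
pseudo-noise. A filtered-white-noise murmur has Rayleigh-fluctuating
per-cycle spectra, which makes threshold-crossing widths bimodal no matter
how distinct the classes are; the multisine keeps the spectral plateau
stable while still sounding noise-like. Murmur envelopes are
crescendo–decrescendo (cosine-tapered over 35 % of the interval), as
ejection and regurgitant murmurs are.

The seven presets encode auscultatory signatures: MS a low diastolic
rumble (40–90 Hz) with the loud S1 of mitral stenosis; ASD a soft mid-band
flow murmur; MR, VSD, AR, AS murmurs in successively higher bands
(150–350, 250–430, 300–500, 480–680 Hz), VSD with the accentuated P2 of
pulmonary hypertension and AS with a diminished A2. The pathological
presets other than MS place murmur energy in both systole and diastole —
each has a documented diastolic counterpart in severe disease (flow
rumbles across the mitral valve, mixed aortic disease) — which also makes
the extracted widths insensitive to exactly where a cycle boundary cuts
the murmur. All murmur amplitudes are 0.35 relative to the S1 peak: loud
enough that every murmur plateau sits decisively between the 0.3 and 0.5
threshold lines of the normalized secondary envelope, quiet enough that
the envelope between bursts still dips — a sustained loud systolic murmur
merges the S1 and S2 envelope humps and defeats STMHT segmentation
entirely, which is the method's own documented failure mode, not a
simulator artefact.

What the simulator does **not** emulate: real murmur stochasticity
(multisines have stationary spectra), respiratory modulation and splitting
of S2, extra sounds (S3, S4, clicks), background/contact noise bursts,
recording-channel variation, and pathological waveform morphology beyond
band-limited noise. Passing the end-to-end tests therefore demonstrates
that the pipeline's machinery is correct and internally consistent under
the method's structural assumptions — not that the published clinical
accuracies transfer to real stethoscope data.

## Problem sizes used in the tests

Oracle-equivalence tests transcribe every defining equation as literal
nested loops and compare on inputs of a few hundred samples. Statistical
checks use: 100 000 draws per component for the χ² coverage calibration
(tolerance ±0.005), 2 000 draws per component for unsupervised EM
parameter recovery (means within 0.1 after matching), 50 simulated
recordings for segmentation ground-truth recovery (≥95 % of cycles must
contain their S1/S2 centers), and a trained pipeline (14 training and 5–8
held-out recordings per class at 4 kHz) whose per-class one-vs-rest
accuracy on held-out *recordings* — each recording receives the majority
vote of its cycle labels, as a patient receives one diagnosis — must reach
90 %. Per-cycle accuracies for the adjacent-band classes are a few points
lower and noisier; the recording level is the clinically meaningful unit.

## Limitations

* Recordings whose STMHT produces too few usable crossings (loud
  holosystolic murmurs, heavy noise) raise a segmentation error rather
  than a diagnosis — by design.
* The classifier assumes one Gaussian per class in γ space; compound
  valve disease violating unimodality is outside its scope.
* The bundled published model is calibrated to its own clinical feature
  scale; synthetic or otherwise out-of-distribution recordings correctly
  score `"unknown"` against it, and a new model should be trained with
  `cmd_train()` for any new acquisition setup.
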