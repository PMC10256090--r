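---
title: "Methods: simulating and classifying hive-entrance radar signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying hive-entrance radar signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A 5.8 GHz continuous-wave Doppler radar pointed at a beehive entrance records
a two-channel (I/Q) baseband signal through a 408 Hz first-order IF low-pass
and a 44.1 kHz sound card. Honeybee flights appear as micro-Doppler
signatures: a body line at the radial Doppler shift `2v/λ` (λ ≈ 5.17 cm, so
7.7–77 Hz for 0.2–2 m/s) surrounded by wingbeat phase-modulation sidebands at
multiples of the 150–230 Hz wingbeat frequency. `beedar` simulates such
recordings, segments them into 0.4 s windows, encodes each window as Log Area
Ratios (LARs) from linear predictive coding (LPC), and classifies activity as
`inward`, `outward`, `hover` or `background` with cascaded RBF-kernel SVMs.

## Signal model

A single bee is modelled as a body scatterer plus a harmonically oscillating
wing scatterer:

x(t) = A₁·exp(−j·4π/λ·R(t)) + A₂·exp(−j·4π/λ·[R(t) + A_H·cos(ω_H t)])

with I = Re x, Q = Im x. The I channel alone equals the classical real-valued
return `A₁cos(4πR/λ) + A₂cos(4π[R + A_H cos(ω_H t)]/λ)`. The *negative* phase
sign makes an approaching target (decreasing R) land at positive frequencies
of the complex spectrum — the physical point of an IQ mixer. Defaults follow
the field calibration A₂ = A₁/5 = 0.2, A_H ≈ 1 cm, R ∈ 0.1–2 m. With A₁ = 0
and the range harmonically modulated the same law yields clutter: wind shake
(≤ 5 Hz) and 50 Hz vibration coupling. The receiver chain applies a
bilinear-transform first-order IIR at 408 Hz (prewarped, so the −3 dB point
is exact), additive white Gaussian noise, and optionally a faint ~1 kHz
equipment tone. The default `noise_rms = 0.07` gives ≈ 20 dB SNR per channel
for a unit-amplitude body return.

Static phase-modulation spectra follow the Bessel series: line n carries
amplitude |Jₙ(β)| with modulation index β = 4πA_H/λ ≈ 2.43 at A_H = 1 cm.
The test suite checks simulated lines against this closed form to 2%.

## Class kinematics

The source description gives only speed ranges and verbal behaviour; the
generator fixes them as:

* **outward** — speed ramps from ≈0 to a cruise v_max ∈ [1.1, 1.9] m/s
  (within the published 1–2 m/s band, kept off the edges so the realised
  *radial* speed stays inside it), along a straight path that passes the
  radar at 0.10–0.20 m lateral offset just before the event ends.
* **inward** — arrival at v₀ ∈ [0.5, 1.5] m/s moving away from the radar
  toward the hive stand-off (1–2 m), linear deceleration completing at 93% of
  the event. An inward event is taken to end when the bee enters the hive, so
  the at-rest tail is minimal. This matters: with long at-rest tails and
  uniformly random window picking, many "inward" windows contain an
  essentially stationary bee and are genuinely hover-like; four-way accuracy
  then saturates near 0.79 rather than >0.9.
* **hover** — two incommensurate slow sinusoids (0.5–2.5 Hz and 2.5–5 Hz)
  around a 0.5–1.5 m stand-off with peak radial speed ≤ 0.4 m/s.

Durations are drawn from 0.8–1.4 s. `simulate_window_dataset` composes one
scene per sample (event + wind-shake bed, background = clutter only with a
50% chance of vibration), passes it through the receiver chain, segments it,
and keeps the matching-label window that best overlaps the flight's *moving*
phase (|dR/dt| > 0.05 m/s). This emulates manually curated event samples; it
does **not** emulate full-recording breakdowns with truncated, overlapping or
multi-bee windows, which is why a green classification test here does not
predict field accuracy. The published headline figures (75.12% preliminary
four-way, 70% on a new recording, etc.) come from field data that is not
packaged and are context only.

## Segmentation and labelling

Windows are 0.4 s with 0.1 s nominal overlap; the final window is anchored to
the recording end so no data are discarded (a 0.6 s recording yields two
windows overlapping 0.2 s). Placement is done in sample indices with
half-open spans. A window overlapping no event is `background`; otherwise the
highest-priority overlapping event labels it (inward = outward > hover, ties
by larger overlap then earlier start). The priority rule is this package's
construction — the source flags dual in/out windows (4.4% of samples) as a
limitation without stating its rule.

## Features

Each channel of a window is split into non-overlapping sub-windows (default:
the full window), Hamming-tapered, and fitted with an autocorrelation-method
LPC via Levinson–Durbin; reflection coefficients are clamped to |k| ≤ 1−1e−6
and mapped to LARs log((1−k)/(1+k)). Zero-energy input maps to k = 0. The
feature vector is channel-major: `n_channels × n_sub_windows × order` values,
matching the published per-channel budgets (e.g. 110 coefficients × 2
sub-windows = 220). Sub-windows must tile the window exactly, forced by the
budget arithmetic (0.4 s / 40 ms × 76 = 760). Per-channel LPC of the real I
and Q channels is used (not complex LPC); note this makes the features blind
to Doppler *sign* — each real channel has a mirror-symmetric spectrum — so
in/out discrimination rests on speed-profile differences, and the IQ benefit
over a single channel is noise diversity. No pre-emphasis is applied; the
signals are low-frequency dominated. Resampling (e.g. 44.1 kHz → 3.5 kHz, the
reduced ratio 5/63) uses a windowed-sinc polyphase filter with 20·max(p,q)+1
taps; passband fidelity and stopband rejection are oracle-tested.

## Classification

Three pathways map features to the four labels: P1 (one four-way model), P2
(background-vs-rest → hover-vs-{in,out} → in-vs-out), P3 (background-vs-rest
→ three-way). Stages are RBF C-SVCs trained by SMO (duality-gap tolerance
1e−3); multiclass stages use one-vs-one voting with margin tie-breaks.
Features are standardized per stage on training data only. `C` and `γ` are
chosen by Bayesian optimization — a Gaussian-process surrogate with expected
improvement — over log₁₀C ∈ [−3, 3], log₁₀γ ∈ [−4, 1], default budget 30
evaluations scoring internal stratified CV accuracy. Cross-validation is
stratified (the class imbalance of field data motivates this; folds default
to 10) and re-runs standardization and the hyperparameter search inside every
fold. Reported metrics: accuracy, support-weighted precision and recall
(weighted because the source attributes its precision/recall gap to class
imbalance), macro-F1, and a summed confusion matrix.

## Benchmarks and what the synthetic world can and cannot reproduce

`sweep_sampling_rate`, `sweep_coefficients` and `sweep_subwindow` grid
cross-validated accuracy over rates, LPC orders and sub-window lengths, with
infeasible cells (order ≥ samples) marked rather than fatal; the default
order rule scales order ∝ rate, capped at 240 (100 at 3.5 kHz).
`class_envelope_std` computes the pointwise standard deviation of LPC
spectral envelopes per class up to 1.5 kHz.

Findings that reproduce on simulator data (seed-majority over 5 seeds):

* sub-dividing the 0.4 s window at a matched coefficient budget lowers
  accuracy;
* dual-channel IQ features beat the I channel alone on the in/out binary at
  the 200-per-class scale (at much smaller n the doubled dimensionality can
  invert this);
* no accuracy gain above ~3 kHz sampling (the plateau);
* envelope-deviation peaks of the bee classes sit below 150 Hz, with the
  outward peak above the inward peak (outward bees reach their highest radial
  speeds near the radar; inward bees decelerate), and a jittered 1 kHz
  equipment tone puts the background deviation peak at ~1 kHz. Peak locations
  are read off the grid restricted to ≥ 8 Hz — the body Doppler of the
  slowest 0.2 m/s bee — because below that wind shake dominates every class.

One finding deliberately does *not* reproduce: the accuracy **rise** below
3 kHz. The simulated world is band-limited by the modelled 408 Hz first-order
IF filter, so nearly all discriminative content survives even a 1 kHz
sampling rate and accuracy is flat from low rates upward. The field
recordings evidently carried weak high-frequency components (the source
reports them as crucial and easily obscured); the generator does not invent
content it cannot justify, so the plateau is reproduced but not the climb.

## Numerical choices

* Reflection-coefficient clamp 1−1e−6 before the log; LAR round-trips to
  1e−9.
* The IF low-pass is prewarped so the digital −3 dB point is exactly 408 Hz;
  its magnitude matches the analog law within 1% over 10–1000 Hz (bilinear
  warping grows above ~10% of the sampling rate).
* The Doppler sign convention: `exp(−j·4π R/λ)` (approach → positive
  frequency). The printed real-form model is recovered on the I channel
  either way since cosine is even.
* All randomness flows through explicit integer seeds; per-component
  sub-seeds are derived arithmetically and stay below 2³¹. Identical seeds
  give bit-identical recordings, datasets, searches and metrics.
* Degenerate inputs are total: zero-energy LPC input → zero model; a
  single-class training stage → constant predictor with a warning; sweep
  cells with order ≥ window samples → `feasible = FALSE`.

## Known limitations

* Scalar amplitudes only — no range-dependent power law, antenna pattern or
  RCS model, so simulated amplitudes do not decay with distance.
* One scatterer per bee plus one wing term; no multi-bee interference within
  a single labelled event (scenes can overlap events, but the dataset
  generator uses one event per scene).
* Per-channel real LPC discards Doppler sign; a complex-LPC variant would
  change the in/out story and is out of scope.
* The SVM is a plain C-SVC without probability calibration or class weights,
  by design (the source used none).
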