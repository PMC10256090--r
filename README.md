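# beedar

Doppler radar simulation and classification of honeybee hive-entrance
activity.

Beekeepers and ecologists want continuous, non-invasive counts of bees
entering, leaving and hovering at a hive entrance. A 5.8 GHz continuous-wave
radar with an I/Q mixer, placed 1–2 m from the hive, records such activity as
two-channel audio-rate baseband signals: each flight leaves a micro-Doppler
signature — a body line at `f = 2v/λ` (λ ≈ 5.17 cm, so ≈ 7.7–77 Hz for bee
speeds 0.2–2 m/s) surrounded by wingbeat phase-modulation sidebands at
multiples of the 150–230 Hz wingbeat frequency, with amplitudes following the
Bessel series |Jₙ(4πA_H/λ)|. `beedar` provides the full analysis pipeline for
this setting, plus a physics-based simulator so that every stage is testable
without field recordings:

* **sim** — complex-baseband synthesis of bee flights
  `x(t) = A₁e^{−j4πR(t)/λ} + A₂e^{−j4π[R(t)+A_H cos ω_H t]/λ}` (I = Re,
  Q = Im), wind-shake and 50 Hz vibration clutter, and a modelled receiver
  chain (408 Hz first-order IF low-pass, white noise, optional 1 kHz
  equipment tone).
* **segmentation** — 0.4 s windows with 0.1 s nominal overlap and a flexible
  final overlap so no data are discarded; single-label assignment from a
  ground-truth timeline.
* **features** — Log Area Ratios from autocorrelation-method LPC
  (Levinson–Durbin), per channel and per sub-window; rational resampling;
  spectral envelopes and spectrograms.
* **classify** — RBF-kernel SVMs (SMO, one-vs-one) over three prediction
  pathways (four-way; background → hover → in/out cascade; background →
  three-way), hyperparameters tuned by Bayesian (GP expected-improvement)
  optimization, stratified 10-fold cross-validation, accuracy / weighted
  precision / weighted recall / macro-F1.
* **benchmarks** — accuracy sweeps over sampling rate, coefficient count and
  sub-window size; per-class spectral-envelope standard-deviation curves.
* **io/cli** — two-channel IQ WAV and CSV timeline/manifest/feature formats,
  JSON metrics, and a `beedar_cli()` entry point
  (`simulate`, `segment`, `extract`, `train`, `evaluate`, `sweep`).

## Worked example

```r
library(beedar)

rc <- radar_config()                      # 5.8 GHz, 408 Hz IF LP, 44.1 kHz
tl <- random_timeline(total_duration = 8, n_events = 5, seed = 42)
tl
#> <event_timeline> 8.00 s, 5 events, 1 clutter sources
#>   hover      0.814 -   1.888 s
#>   outward    4.526 -   5.637 s
#>   inward     5.523 -   6.872 s
#>   outward    6.477 -   7.326 s
#>   inward     6.788 -   7.924 s

scene <- compose_scene(tl, rc, seed = 42)
windows <- segment_and_label(scene$recording, tl)
table(vapply(windows, `[[`, character(1), "label"))
#> background      hover     inward    outward
#>          9          5          7          6
```

The 8 s recording yields 27 windows on the 0.3 s step grid; each gets the
label of its highest-priority overlapping event (inward/outward over hover),
or `background` where only the wind-shake clutter is present.

```r
ds <- simulate_window_dataset(n_per_class = 40, seed = 42)
ft <- dataset_features(ds, feature_spec(sample_rate = 3500, order = 100))
cross_validate(ft$x, ft$labels, pathway_spec("P1"), folds = 5,
               seed = 1, hyperopt_budget = 8, inner_folds = 2)
#> <pathway_metrics> accuracy 0.9062  precision 0.9187  recall 0.9062  F1-macro 0.9050
#>             predicted
#> true         background hover inward outward
#>   background         40     0      0       0
#>   hover               0    38      2       0
#>   inward              0     2     33       5
#>   outward             0     0      6     34
```

160 windows (40 per class) are simulated, encoded as 200 LARs each (100 per
channel at the down-sampled 3.5 kHz rate), and cross-validated with the
four-way pathway: ~0.91 accuracy, with the residual confusion exactly where
the physics puts it — inward vs outward (per-channel LPC features are blind
to Doppler sign, so the separation rests on accelerating-vs-decelerating
speed profiles) and inward vs hover (a decelerating bee resembles a slow
hovering one).

## Documentation

`vignettes/beedar-methods.Rmd` describes the signal model and its
assumptions, the class kinematics the generator states, the feature and
classifier choices, what the synthetic world reproduces of the field
behaviour and what it deliberately does not.
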