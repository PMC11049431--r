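---
title: "Methods: simulated avocado ripening cohorts, stage classification and shelf-life estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated avocado ripening cohorts, stage classification and shelf-life estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`avoripen` models a post-harvest monitoring workflow for 'Hass' avocado:
fruit are stored under one of three regimes, photographed from two sides
daily, classified on an ordinal Ripening Index, and their remaining
shelf-life is estimated from the stage. This vignette documents the models
and the design choices, so that what the package's tests do — and do not —
demonstrate is explicit.

## The Ripening Index and Days Left

The 5-stage index spans unripe (1), breaking (2), ripe first and second
phase (3, 4) and overripe (5). The 10-stage index halves each stage;
end of shelf-life is stage 9 of 10 (or 5 of 5), and stage 10 marks visible
contamination. The two systems are locked together by
`ri5 = ceiling(ri10 / 2)`.

**Days Left** for a photograph is the number of days from that photograph
until the *first* day the same fruit is classified at the endpoint stage.
It is 0 on the endpoint day, undefined for photographs taken after it, and
undefined (with a censoring flag) for fruit that never reach the endpoint
within the observation window. Censored fruit keep valid stage labels for
classification but are excluded from shelf-life regression, where the
response does not exist.

## The generative ripening model

Each simulated fruit carries:

- a storage group (`T10` 10 °C, `T20` 20 °C, `Tamb` fluctuating room
  temperature, mean 18.7 °C, sd 1.2 °C — the oscillation is metadata only;
  ripening speed is governed by the group's slope preset);
- a starting 10-stage index drawn from `start_probs` (default
  0.55/0.30/0.15 over stages 1–3: fruit arrive mature but mostly unripe,
  some already breaking);
- a uniform phase within the starting stage (the fruit is already partway
  through it on day 0);
- a mean-one lognormal **speed factor** (`speed_sd = 0.15` by default),
  the well-documented fruit-to-fruit heterogeneity of avocado ripening;
- per-stage dwell times drawn from a gamma distribution with common mean
  (group dwell scale × speed factor) and coefficient of variation
  `dwell_cv = 0.25`. The gamma is positive and unimodal and collapses to
  deterministic dwells at CV 0. The defaults are round values chosen once
  as a realistic amount of within-fruit irregularity; nothing in the
  package is sensitive to their exact values.

Stages advance one at a time; photographs are taken on integer days from
day 0 until the first day at stage 10; every observed day yields a front
and a back record.

### Calibration of the dwell scale

The storage-group presets are the empirical Days-Left-per-stage slopes of
the forced-endpoint regressions (5-stage: −4.390/−2.116/−1.929 days per
stage for T10/T20/Tamb; 10-stage: −2.392/−1.156/−1.045). A subtlety makes
the naive choice *dwell = |α|* wrong: Days Left counts to the **first** day
classified at the endpoint, while photographs are spread uniformly across
each stage's dwell window. For a mean dwell of `D` days per stage the
expected Days Left at stage `s` is `D(9 − s) − (D − 1)/2`, so a
through-origin fit of data generated with `D = |α|` recovers a slope
biased by roughly 5–13% depending on the group. The generator therefore
**calibrates** its dwell scale: `calibrate_dwell()` solves (by root
finding on a large fixed-seed reference cohort with common random numbers)
for the `D` at which the annotated Days-Left law has exactly the preset
slope. Calibration is per storage group and per index system
(`index_target`), because the published 5-stage slopes are consistently
about 8% shallower than twice the 10-stage slopes — itself a footprint of
the same first-classification convention — so a single ensemble cannot
carry both slopes at once. The reference cohort (30 000 fruits) makes the
solver's own Monte-Carlo error small against the spread of study-scale
cohorts. With this calibration, fitting simulated cohorts of a few hundred
fruits recovers every preset within Monte-Carlo error, which is exactly
what the parameter-recovery tests assert.

### The renderer

Images are deliberately minimal: an ellipse on a near-white backdrop whose
base colour interpolates a 10-anchor CIELAB palette (lightness strictly
decreasing over stages 1–8, as the skin darkens), with stage-dependent
scattered purple patches (peaking while purple spreads, stages 5–6, and
vanishing once the skin is homogeneously purple, stages 7–8), dark mold
spots only from stage 9, an optional one-sided blemish emulating wind rub
or sunburn, Gaussian pixel noise, and 8-bit sRGB quantization. The default
palette anchors are package-chosen values consistent with the stage
phenotypes; they are configuration, not measured ground truth. The
renderer reproduces the statistical structure the analysis relies on
(ordinal colour progression, side asymmetry, within-stage variability) but
none of the optics of a real photographic rig — no shading, no specular
highlights, no camera response. Tests passing on these renders therefore
demonstrate the correctness of the pipeline's logic and its ability to
exploit colour-separable stages; they say nothing about accuracy on real
photographs.

## Splitting and oversampling

Samples (every photograph of one fruit) are assigned whole to train /
validation / test — the leakage control. Because each fruit traverses many
stages, exact stratification is impossible; assignment is greedy in a
seeded random order, each sample going to the subset that most reduces a
squared deviation between running per-stage record counts and the subset's
target share (the first three samples seed the three subsets so none is
empty). Random oversampling duplicates randomly chosen *training records*
per stage until all stages match the largest stage count; records are the
unit the training loop consumes. Validation and test sets are never
altered.

## Colour characterization

sRGB ↔ CIELAB conversions use the D65 2° observer
(`grDevices::convertColor`). The colorimeter-style calibration is a
least-squares map from device Lab to reference Lab, affine by default with
a full degree-2 polynomial as a configuration switch. Per-image palettes
are plain k-means (`stats::kmeans`, seeded) over masked calibrated Lab
pixels with pixel-fraction weights. The cohort-level predominance palette
aggregates all per-image entries by *weighted* k-means (weighted Lloyd
iterations with k-means++ seeding, written in the package because no
installed implementation takes weights); weighted clustering of the
palette entries is the most defensible reading of "most predominant
colours", and the companion sRGB values are weighted means of the member
entries.

## The stage classifier

The default backbone is a compact pooled-CIELAB feature extractor (a
`grid × grid` average-pooled mosaic converted to Lab, 48 features at the
default grid 4) with a small tanh MLP head, trained by momentum SGD
(momentum 0.9, weight decay 1e-4 — the classical choices; the study
protocol leaves the optimizer open). Deeper pretrained backbones can be
plugged in behind the same `featurize` interface, but no test requires
one: the package's scope is the training *protocol*, which is implemented
in full — cross-entropy over stages, mini-batches (default 128, 30
epochs), a step learning-rate schedule (`lr_init × 0.1^floor(epoch/10)`,
0.01 for the deeper preset and 0.001 for shallow nets), one random
geometric augmentation of each training image per epoch (reflection,
rotation ±10°, rescaling 0.95–1.05, translation ±10 px), validation every
10 iterations, early stopping after 150 iterations without improvement,
and selection of the checkpoint with the best validation accuracy
(validation loss breaks ties, then earliness). A final validation closes
training runs that end between checks.

One practical note: the ±10 px translation is calibrated to high-resolution
photographs. On the package's small synthetic renders (48–64 px) the same
displacement moves the fruit by a fifth of the frame and destroys the
pooled-colour signal, so configurations for small renders should scale the
translation down (±2 px at 48 px); the package's tests do exactly that.

## Shelf-life regression and loss analysis

The forced-endpoint model `Days Left = α (RI − E)` is a through-origin OLS
in `x = RI − E`: `α̂ = Σxy/Σx²`, `SE = sqrt(RSS/((n−1)Σx²))`, 95% CI via
Student-t with `n − 1` degrees of freedom (one fitted parameter), and the
**uncentered** R² `1 − RSS/Σy²` — the standard choice for through-origin
fits, where the centered definition is not meaningful. Estimates are
clipped at 0 beyond the endpoint stage: a fruit past end of shelf-life has
no days left. Losses are kept signed per record
(`loss = estimated − actual`) — their distribution is what the KDE plots
show — while reported averages are means of |loss|, per storage group and
overall with equal group weights. Sample-level aggregation keeps, per
(sample, day), the side with the smallest absolute loss, the "best side"
convention. The KDE uses a Gaussian kernel with a fixed 1-day bandwidth
(`stats::density`, `bw = 1`).

Whether the original regressions were fitted per photograph or per
sample-day is not determinable from the published tables; the package fits
per photograph (both sides), which only reweights identical sample-day
stage histories.

## Determinism and numerical conventions

Every stochastic component draws from an explicit seed through one hash
(`derive_seed`), so cohorts, splits, oversampling, training and rendering
are bit-reproducible for equal seeds, and per-record render seeds make
image providers pure functions. Day indexing is 0-based from the first
photographed day; date stamps are ISO-8601. Degenerate inputs are defined,
not accidental: zero-width augmentation ranges give the identity
transform; CV-0 dwells are deterministic; palettes with fewer distinct
colours than `k` return the distinct colours with merged weights; a stage
absent from training is reported and left at zero; fits with all points at
the endpoint stage are an error; per-stage accuracies for absent stages
are reported as missing, never as 0 or 1.

## Problem sizes used by the tests

The test suite runs cohorts of 26–500 fruits (the full 478-fruit study
design is simulated once, metadata only), 48-px renders, and training runs
of 1–10 epochs on a few hundred records; the parameter-recovery checks use
12 replicate cohorts of 220 fruits per preset and the acceptance script
one 600-fruit cohort per preset. These sizes were chosen so the whole
suite exercises every module at Monte-Carlo tolerances appropriate for the
assertions being made.

## Limitations

- The renderer is a statistical emulator, not a photorealistic one;
  results on it bound nothing about real photographs.
- The classifier backbone is intentionally small; the package ships the
  training protocol, not a deep-learning framework.
- Shelf-life modelling is the published linear forced-endpoint form; no
  censoring-aware survival model is attempted.
- The storage experiment itself (temperature control, humidity, camera
  rig) is out of scope; its parameters enter only as presets and metadata.
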