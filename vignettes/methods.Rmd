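---
title: "Spatiotemporal window-vote classification of 4D fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal window-vote classification of 4D fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

fmriSTC classifies subjects from raw 4D resting-state fMRI by combining
three learned components. Per time point, a multi-scale 3D convolutional
encoder turns the volume into a spatial feature vector $F_{sp,i} \in
\mathbb{R}^{d_1}$: two stages, each applying parallel same-padded cubic
convolutions (kernels 3, 5, 7), channel concatenation, a rectifier and
$2^3$ max-pooling with stride 2, followed by a flatten and one fully
connected map. Per sliding window $j$ of length $w$ and stride $s$
(count $k = \lfloor (t-w)/s \rfloor + 1$), an LSTM consumes the window's
frames in temporal order and its final hidden state is the temporal
feature $F_{tem,j} \in \mathbb{R}^{d_2}$. The fused vector
$F_{comb,j} = [F_{tem,j} \,\|\, F_{sp,(j-1)s}]$ pairs each window with the
spatial feature of its first frame. Gradient-boosted decision trees
classify each window under the binary cross-entropy loss, and the subject
decision is the strict majority of the $k$ window votes; $k$ is kept odd
(by dropping the last window when the count comes out even) so that ties
cannot occur. An even vote at decision time is treated as a hard error
rather than tie-broken, because upstream enforcement guarantees oddness
and an even count indicates a windowing bug.

The assumptions are those of the architecture: class-relevant information
is present in single-volume spatial patterns and/or in short-range
temporal dynamics within windows of $w$ frames; subjects are exchangeable
within class; volumes are spatially aligned before entry (registration,
slice timing and motion correction are upstream of this package).

## Training regime

How the encoders should be trained relative to the boosted trees is
genuinely open: trees admit no gradient, so a single end-to-end objective
does not exist. The package trains in stages. Stage 1 jointly optimizes
both encoders with a temporary linear head on window-level binary
cross-entropy — every window inherits its subject's label — using Adam
(learning rate 0.001, batch 32 windows; both configurable). Stage 2
freezes the encoders, extracts fused features for all training windows and
fits the GBDT (default 100 trees, depth 3, shrinkage 0.1, logistic loss,
single-threaded and seeded; tree hyperparameters are this package's
defaults, exposed in `gbdtConfig()`). Stage 3 packages the result. All
windows of a subject always stay on one side of any train/test split;
window-level splitting would leak subject identity.

A `variant = "spatial"` ablation drops the temporal pathway (3D-CNN +
GBDT only), which is the natural contrast for showing that temporal
features carry information that spatial features alone do not.

Voting is unweighted majority. A probability-weighted alternative (mean
window probability against 0.5) exists behind `weighted_vote = TRUE` and
is off by default: the unweighted rule is the stated decision formula, and
the weighted mode is provided only as a sensitivity check.

## Tunable parameters

| parameter | default (full / toy) | meaning |
|---|---|---|
| `t`, `w`, `s` | 50, 10, 1 | series length, window length, stride (frames); defaults give k = 41 |
| kernel sizes | 3, 5, 7 | multi-scale conv kernel edges (voxels) |
| channels/kernel | 8 / 4 | conv channels per parallel kernel |
| `d1` | 128 / 16 | spatial feature dimension |
| hidden units (`d2`) | 500 / 32 | LSTM state size = temporal feature dimension |
| `input_projection_dim` | none | optional learned linear input reduction for the LSTM |
| band | 0.01–0.1 Hz | Butterworth pass-band |
| FD threshold | 0.2 mm | mean-FD exclusion (strict >) |
| head radius | 50 mm | rotation-to-displacement conversion |
| lr / batch / epochs | 0.001 / 32 / 50 (toy 2) | stage-1 Adam regime |
| trees / depth / shrinkage | 100 / 3 / 0.1 | GBDT |

At full scale the LSTM cannot consume raw voxel vectors (V would be
~1.1M per step); the configurable input projection is this package's
explicit answer, trained jointly and recorded in model metadata. The toy
profile feeds the small synthetic volumes' raw flatten directly. `d1`,
channel counts, activation and padding are not dictated by the method
itself; the defaults above are recorded in run metadata so any run is
reconstructible.

Odd-window enforcement drops the *last* window so that every retained
window keeps the canonical start formula $(j-1)s$; with the default
(50, 10, 1) profile k = 41 is already odd and nothing is dropped.

## Preprocessing choices

Framewise displacement uses the field-standard sum of absolute backward
differences with rotations converted to arc length on a 50 mm sphere; the
head radius is configurable. Exclusion is strictly above the threshold, so
a subject at exactly 0.2 mm mean FD is retained. The band-pass is a
4th-order Butterworth applied forward-backward (zero phase) per voxel;
the series must exceed three times the filter length (t ≥ 25). Intensity
normalization z-scores globally over the in-mask 4D grid by default —
the intent is to remove scanner-level scale/offset — with per-voxel
temporal z-scoring available as a flag. Global signal regression removes
an intercept and the mean in-mask series by least squares; motion
parameters are deliberately not added as nuisance regressors, since only
the global signal is in scope. No scrubbing, smoothing or interpolation of
individual high-FD frames is performed.

## The synthetic cohort generator

The generator emulates the structure of a multi-site case/control rs-fMRI
collection: balanced classes interleaved across round-robin sites, one
4D NIfTI volume and one 6-column motion trace per subject, and a phenotype
table. Inside an ellipsoidal "brain" mask, a spherical blob carries a
sinusoid at a class-specific frequency (defaults 0.03 Hz for controls,
0.08 Hz for cases, amplitude 1); all in-brain voxels carry white noise
(sd 0.5) and a shared low-frequency drift (linear + half-cosine below
0.01 Hz, amplitude 1). The defaults were fixed once as the package's
study conditions: amplitude 1 with noise sd 0.5 is a moderate
signal-to-noise ratio of 2 per voxel before band-passing, and the drift
amplitude makes drift dominate the global signal so that global signal
regression removes drift rather than the class signal — mirroring real
data, where the global signal is dominated by global fluctuations rather
than any focal effect. Classes differ in *frequency*, not amplitude, so
they are temporally rather than statically separable: a per-frame spatial
encoder cannot distinguish them, and only the temporal pathway can — this
is what makes the spatial-only ablation meaningful. An amplitude-coded
mode exists behind `mode = "amplitude"`.

Motion is a seeded random walk over 3 translations (mm) and 3 rotations
(radians), applied to the frames exactly: rigid rotation about the volume
centre with nearest-neighbour resampling, plus nearest-voxel translation.
The first frame is never moved. Per-subject seeds derive from the master
seed by a fixed integer hash, so cohorts are bit-reproducible.

What the generator does *not* emulate: hemodynamics, spatial
autocorrelation of real BOLD noise, site-dependent scanner effects, EPI
distortion, or any claim about which spatiotemporal properties distinguish
real clinical classes — the frequency-coded blob is an explicit stand-in.
Consequently, passing tests demonstrate that the implementation recovers a
known planted spatiotemporal class difference end to end; they do not
certify performance on real cohorts.

## Numerical choices

The convolution, pooling and LSTM forward/backward passes are implemented
directly (compiled kernels for the 3D convolution and pooling; batched
matrix algebra for the recurrence) and verified against finite-difference
gradients and an independent im2col-times-GEMM convolution route in the
test suite. Weight initialization is He-normal for convolutions and the
fully connected map (biases zero) and scaled-uniform for the LSTM with
forget-gate bias 1. Max-pooling uses floor-division output shapes and
breaks ties by first occurrence. Undefined evaluation metrics
(zero-denominator folds) are flagged `NA` and excluded from fold averages
instead of being coerced to zero. The confidence half-width reported with
fold means is the 95% t-interval. t-SNE is the exact $O(n^2)$ algorithm
(perplexity-calibrated Gaussian affinities, early exaggeration, momentum
gradient descent), adequate for the feature-set sizes the package
produces, and seeded.

Determinism: every stochastic step (generation, initialization, batch
shuffling, fold assignment, boosting, t-SNE) derives its seed from the
user's master seed through a fixed hash, and the boosted trees run
single-threaded, so identical seeds give byte-identical reports.

## Problem sizes

The packaged study profile is deliberately desk-scale, chosen so the full
pipeline trains in minutes on one CPU: 16×16×12 voxel volumes, 50 time
points at TR 2 s, 40 subjects, toy encoder sizes (4 channels per kernel,
d1 = 16, 32 hidden units) and 2 stage-1 epochs — the small planted-signal
task converges within them. The full-scale spatial dimensions (99×117×95)
are available as a configuration preset for shape bookkeeping, and all
full-scale hyperparameters (500 hidden units, 50 epochs, d1 = 128) remain
selectable through the config objects. Ablation and determinism checks in
the test suite use further scaled-down cohorts, since they compare
configurations rather than absolute performance.

## Known limitations

Registration, slice-timing and motion *correction* are out of scope (the
QC stage only excludes). The GBDT stage receives features from encoders
trained with a surrogate head, not from a joint objective — an inherent
limitation of tree ensembles. Per-site models, probability calibration and
batch-effect harmonization are not provided. The window-level training set
treats overlapping windows of one subject as independent samples, which
overstates the effective sample size within stage 1; subject-level
cross-validation keeps the reported metrics honest regardless.
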