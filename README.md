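# fmriSTC

Spatiotemporal window-vote classification of subjects from 4D resting-state
fMRI. The package is aimed at neuroimaging methodologists who want a fully
inspectable, desk-scale implementation of a common deep-learning recipe for
case/control classification from raw 4D volumes — for example autism-vs-
control classification on multi-site resting-state cohorts — together with a
seeded synthetic cohort generator so every stage can be exercised and tested
without any data download.

## The method

A subject is a 4D volume series `X ∈ R^{V×T}` (V voxels, T time points,
sampled every TR seconds). The pipeline is:

1. **Preprocessing** — intensity normalization (z-scoring within the brain
   mask), global signal regression (per-voxel least-squares residual
   against the mean in-brain series), and a 0.01–0.1 Hz zero-phase 4th-order
   Butterworth band-pass. Motion quality control computes per-transition
   framewise displacement `FD_i = |Δdx|+|Δdy|+|Δdz| + r·(|Δα|+|Δβ|+|Δγ|)`
   (head radius r = 50 mm) and excludes subjects whose mean FD exceeds
   0.2 mm. Spatial registration and motion correction are delegated to
   upstream tools; the package consumes aligned volumes.
2. **Spatial features** — a two-layer multi-scale 3D convolutional encoder.
   Each layer applies parallel same-padded convolutions with kernels
   3³/5³/7³, concatenates their channels, applies a rectifier and 2×2×2
   max-pooling; the final map is flattened and linearly projected to
   `F_sp,i ∈ R^{d1}`, independently for every time point i.
3. **Temporal features** — the series is cut into k sliding windows of
   length w and stride s, `k = ⌊(t−w)/s⌋ + 1` (the last window is dropped
   if k is even, so votes cannot tie). An LSTM consumes each window's
   frames in order; its final hidden state is `F_tem,j ∈ R^{d2}`.
4. **Fusion + GBDT** — each window's temporal feature is concatenated with
   the spatial feature of the window's first time point, and gradient-
   boosted decision trees classify the fused vector under the binary
   cross-entropy loss; windows inherit their subject's label.
5. **Decision** — the subject label is the strict majority of the k window
   votes (`ŷ_final = 1` iff `Σ ŷ_j > k/2`; 1 = case, 0 = control).

Training is staged: the two encoders are first trained jointly with a
temporary linear head on window-level cross-entropy (Adam, lr 0.001), then
frozen while the GBDT is fitted on the extracted fused features.

Evaluation is subject-level stratified K-fold cross-validation reporting
accuracy, precision, recall, F1 and specificity per fold with mean ± 95%
t-interval, optionally per site, plus t-SNE visualization of the fused
features.

## Worked example

```r
library(fmriSTC)

dir <- tempfile()
generateCohort(acquisitionSpec(), classSignalSpec(), noiseSpec(),
               n_per_class = 20, sites = c("A", "B"), seed = 42, dir = dir)
msk <- with(list(s = c(16, 16, 12)),
            fmriSTC:::ellipsoidMask(s) | fmriSTC:::blobMask(s, c(8, 8, 6), 3))
cohort  <- preprocessCohort(loadCohort(dir, mask = msk))
report  <- crossValidate(cohort, toyPipelineConfig(), K = 5, seed = 1)
report$mean$accuracy
#> [1] 0.95
report$folds$accuracy
#> [1] 1.000 0.875 1.000 1.000 0.875
```

The synthetic cohort hides a frequency-coded signal blob (0.03 Hz for
controls, 0.08 Hz for cases) inside a noisy brain-shaped volume; a mean
held-out accuracy of 0.95 says the trained pipeline recovers that
temporal class difference almost perfectly from held-out subjects, while
the same cohort with permuted labels drops to chance (≈ 0.5).

A thin CLI over the same functions is installed at `inst/cli/fmristc`
(subcommands `simulate`, `preprocess`, `train`, `predict`, `evaluate`).

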