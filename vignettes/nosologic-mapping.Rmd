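---
title: "Nosologic mapping of MRSI therapy response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nosologic mapping of MRSI therapy response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrsinet)
```

# The model

`mrsinet` assigns one of three tissue classes to every voxel of an MR
spectroscopic imaging (MRSI) grid — normal parenchyma (N), unresponsive or
control tumour (T), tumour responding to temozolomide (R) — from the
voxel's proton spectrum alone.  The input is the 692-point spectral window
between 0 and 4.5 ppm; each spectrum is scaled to unit Euclidean length
(UL2) so that only spectral shape carries information.  Classification is
a two-stage cascade of binary 1D convolutional networks rather than one
three-class model: N vs (R+T) is an easy, large-contrast problem (creatine
and NAA versus mobile lipids/lactate), while R vs T hinges on subtle
shifts (lactate/lipid positions, myo-inositol, PUFA), and separating the
two problems lets the second model concentrate its capacity on the hard
contrast.

Each stage network is: two to four blocks of length-preserving
(same-padding, stride-1) 1D convolution + LeakyReLU (negative slope 0.01)
+ max-pooling of size 2; flatten; dropout 0.5; one LeakyReLU dense layer;
dropout 0.5; one sigmoid unit.  With three blocks the positions go
692 → 346 → 173 → 86 (pooling floors odd lengths), so with a final filter
count of 112 the flattened vector has 86 × 112 = 9632 entries.  The
defaults `stage1_architecture()` (80/k12, 112/k9, 112/k3, dense 192, Adam
learning rate 0.00081) and `stage2_architecture()` (144/k9, 48/k6,
112/k3, dense 448, learning rate 0.00075) are the tuned configurations;
`search_space()`/`random_search()` reproduce the tuning protocol (filters
16–144 in steps of 32, kernels 3–12 in steps of 3, dense 64–512 in steps
of 64, learning rate log-uniform on [1e-4, 1e-2], selection by validation
F1).

The map construction applies stage 1 to *all* voxels, including
unknown-labelled ones (maps colour the full grid); voxels below 0.5
tumour probability are finalised blue (N) and never receive a stage-2
score.  Stage 2 colours the remainder red (T) or green (R).  Ties at
exactly 0.5 go to the positive class at both stages (tumour, then
responding) — exercised by a dedicated test.  Expert labels enter only
training and evaluation; unknown voxels are excluded from every metric
and from Dice masks.

# Training protocol

*Splitting.* All of a subject's grids and voxels land on one side of the
train/test divide (`split_cohort()`, fraction rounded to the nearest
subject count), because voxels of one animal are strongly correlated and
would otherwise leak.  For hyperparameter selection and early stopping a
further subject-level 20% validation split is taken from the training
side; the held-out test subjects are never touched during fitting.  The
bundled end-to-end runs hold out one control and one treated subject
deliberately so both stages see both of their classes at test time,
mirroring how a therapy-response test set is composed.

*Balancing.* Class imbalance is handled with SMOTE on the training
portion only, after the validation split (so no synthetic row can sit in
the validation set).  Synthetic rows are convex combinations
`x + u (x_nn − x)`, `u ~ U[0, 1)`, of a minority row and one of its
`k = 5` nearest minority neighbours (Euclidean; k is the conventional
SMOTE default).  Because the models consume unit-norm spectra, synthetic
rows are re-normalised to unit length by default; `renormalize = FALSE`
yields the raw convex combinations (used by the envelope property test).
Each cascade stage is balanced independently.

*Optimisation.* Binary cross-entropy (the standard objective for a
sigmoid head) with Adam, batch size 32, at most 100 epochs by default
(the bundled runs cap at 30), early stopping on validation loss with
patience 10 (bundled runs: 5).  A new best checkpoint is recorded only
when validation loss improves by more than `min_delta` (1e-4), matching
the Keras convention, and best weights are restored.  The `min_delta`
gate matters beyond runtime: on cleanly separable data the loss keeps
shrinking indefinitely, and letting Adam run far past separation pushes
weights into extreme-margin configurations whose relevance maps degrade;
the plateau checkpoint keeps the restored model in the regime where its
decisions are driven by the class-contrast features.  Weights use
He-normal initialisation; all randomness (initialisation, shuffling,
dropout, SMOTE, splits, phantoms) flows from explicit seeds through a
splittable child-seed scheme, so identical configs reproduce identical
artefacts on one thread.

*Baselines.* The four comparison families use the established fitters
with the tuned settings: glmnet (elastic-net α = 0.5, λ = 1/(nC) with
C = 545.6, fitted along a short warm-start path), e1071 SVM (RBF, C = 10,
γ = 0.5 applied to the unscaled UL2 features), ranger (1000 trees, depth
≤ 40), xgboost (100 rounds, η = 0.1, column subsample 0.75, depth 12).  A
nearest-centroid classifier serves as the transparent reference method in
map comparisons, standing in for the earlier semi-supervised
source-extraction approach, which is out of scope here.

# Explainability

`grad_cam()` explains a decision by the gradient of the class score with
respect to the final convolution block's pooled activations (86
positions).  For the single-sigmoid head the positive-class score is the
pre-sigmoid logit and the negative-class score its negation.  Two
combination rules are provided.  The default, `gradient_x_activation`,
rectifies the elementwise gradient–activation product summed over
filters.  The original recipe (`average_gradient`: per-filter weights as
position-averaged gradients, then a rectified weighted activation sum) is
equivalent to it when the head global-average-pools, but for a
flatten+dense head the averaging discards the position structure of the
gradient and can misattribute relevance: on phantom-trained stage-2
models we observed the averaged contributions to be negative at every
position for the predicted class, so rectification zeroed the map and
residual blips at the zero-padded spectrum edge dominated after min–max
scaling.  The elementwise rule localises on the discriminative metabolite
peaks and is therefore the default; the averaged variant remains
available for comparison.  Maps are upsampled from 86 to 692 points by
linear interpolation (nearest-neighbour optional), min–max scaled to
[0, 1], and an all-zero raw map is returned as all-zero rather than
rescaled.  `gradcam_class_average()` averages spectra and maps of one
class, the overlay used to read off which ppm regions drive a model.

# Evaluation

Binary metrics come from the 2×2 confusion matrix at threshold 0.5 on
labelled voxels only; with a single-class truth the undefined entries are
reported `NA`, never zero.  F1 is reported twice — the binary harmonic
mean for the positive class and the macro average over both classes —
because published per-model tables are not always consistent with one
single variant; both are labelled in the output.

Dice is `2|A∩B| / (|A|+|B|)` at voxel level.  `evaluate_map()` scores one
binary mask per class *present in the ground truth* (control grids
contribute N and T, treated grids N and R) and averages them unweighted
into the multiclass score.  A class absent from both truth and prediction
is excluded rather than scored 1, which would inflate averages; two empty
masks give `NA`.  `compare_methods()` summarises per-case scores per
class as mean ± 1.96·sd/√n; the half-width is labelled as a
normal-approximation 95% interval since the reference tables print
"± CI" without defining it.

# The phantom

The generator emulates the statistical structure the classifiers assume,
not MR physics.  Spectra are sums of Lorentzian lines (Gaussian
selectable) with fixed centres and FWHM 0.06 ppm (0.20 ppm for the broad
PUFA feature), a smooth low broad baseline hump (amplitude 0.05), and
i.i.d. zero-mean Gaussian noise (SD 0.02 against peak amplitudes of order
1, i.e. a comfortably clean in-vivo-like SNR).  Between-voxel biological
variability is an 8% amplitude spread per peak, truncated at zero.  Class
signatures encode the qualitative contrasts described above; absolute
amplitudes are arbitrary because UL2 removes scale.  Grids are 10×10 with
a one-voxel unknown border rim (peritumoural: generated as random blends
of neighbouring class profiles), a central tumour disc (radius 2.5
voxels), optionally fully responding or containing a responding
sub-disc.  Longitudinal subjects traverse T → R → mixed layouts over
timepoints two days apart from day 10, echoing a transient response and
relapse.  Storage is always ascending in ppm (index i ↦
`ppm_min + i·Δ`); display may reverse the axis but no code path depends
on display order.

What the phantom does *not* model: peak overlap congestion at clinical
field strengths, baseline distortions and phase errors, frequency
misalignment (real pipelines align spectra first; the package exposes a
no-op `align_spectra()` hook), water residuals, chemical-shift
displacement, spatial intra-class correlation beyond the rim blend, and
scanner drift.  Tests passing on phantoms therefore demonstrate that the
pipeline recovers structure it is designed for — not clinical
performance.  The defaults make the three classes cleanly separable
(a nearest-centroid classifier already attains 100% on noiseless draws);
recovery checks are accordingly strict (≥ 0.95 held-out accuracy, exact
map colouring on tumour-free grids).

# Numerical and interface choices

- Windowing (`window_spectrum()`) takes the closed ppm interval and
  resamples by linear interpolation; the canonical 2048-point/13.3-ppm
  acquisition windows to exactly 692 points on [0, 4.5].
- UL2 rejects all-zero spectra with a typed error instead of returning
  NaN; normalisation is idempotent and scale-invariant to 1e-12 (tested).
- ASCII grid files store 9 significant digits, row-major, 0-based
  (row, col) with row 0 at the top — one fixed convention shared by label
  tables, maps and Dice so coordinates cannot drift.
- Same-padding uses `pad_left = floor((k−1)/2)`; pooling drops a trailing
  odd element (so 173 → 86); pooling ties keep the first element.
- The compiled convolution forward/backward passes are verified against a
  direct-summation oracle and central finite differences in the test
  suite; the Monte-Carlo phantom check uses a per-point three-standard-
  error band with a five-standard-error envelope for the maximum, the
  statistically meaningful version of a pointwise bound across 692
  points.
- Problem sizes in the bundled runs (chosen as the package's scaled-down
  study design): cohorts of 3 control + 3 treated + 1 longitudinal
  subject with 3 timepoints, 10×10 grids, ~450–580 balanced training
  rows for stage 1 and ~60–160 for stage 2; recovery is replicated at
  three seeds.

# Known limitations

The CNN engine is single-threaded CPU code adequate for 692-point spectra
and hundreds of training rows, not a general deep-learning framework; no
GPU, no multi-class heads, no ensembling.  Spectral alignment is a no-op
hook.  The nearest-centroid reference is deliberately simple and will tie
with the CNN on cleanly separable phantoms; differences between mapping
methods only emerge on harder (noisier, more heterogeneous) phantoms.
Real-acquisition vendor formats are out of scope; the ASCII dialect plus
label tables and JSON manifests are the interchange formats.
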