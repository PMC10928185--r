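---
title: "Methods: deep feature fusion and hybrid Grey Wolf–Jaya selection for multimodal brain-tumor MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep feature fusion and hybrid Grey Wolf-Jaya selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `neurofusion`
implements, the parameters that matter, the numerical choices behind
them, the design decisions that were genuinely open, and what the
synthetic test bed does and does not demonstrate.

## The pipeline

The package classifies 2-D brain-MRI slices into the four structural
modalities (FLAIR, T1, T1CE, T2). Two networks produce deep features,
which are fused, pruned by a metaheuristic wrapper selector, and
classified by preset neural networks; Grad-CAM maps explain the CNN's
decisions, and a paired Student's-t procedure compares classifiers
across pipeline stages.

## The two extractor networks

### Modified ResNet-50

`build_modified_resnet50()` constructs the standard ResNet-50
backbone — a 7×7 stride-2 stem with 3×3 max pooling and four
bottleneck stages of 3/4/6/3 blocks — followed by three appended
residual blocks, one extra 3×3 stride-1 convolution after the first of
them, a global-average-pooling (GAP) tap, and a softmax head. Each
appended block is four stride-1 convolutions alternating 1×1 and 3×3
kernels with batch normalization and ReLU after every convolution and
an identity skip (a 1×1 projection whenever the channel count
changes).

One architectural choice was genuinely open: where the appended blocks
sit and how the 1024-wide GAP tap arises, given that a vanilla
ResNet-50 pools 2048 channels. We append the blocks after stage 4 and
taper the channel plan 2048 → 1536 → 1280 → 1024, so the GAP tap
emits exactly 1024 features; this is the single free choice that
reconciles the backbone with the published feature width, and it is
scaled uniformly by `width_scale` (a 0.125 scale gives a 128-wide tap
for desk-size experiments).

### Stacked convolutional autoencoder

`build_stacked_autoencoder()` uses five stride-2 3×3 encoder
convolutions, dense sigmoid bottlenecks (defaults 100 then 50 — the
reading of "two stacks of autoencoders" consistent with the stated
hidden sizes), mirrored dense decoding, and five decoder stages of
nearest-neighbour 2× upsampling followed by a stride-1 3×3
convolution. Upsampling+convolution is used in place of transposed
convolution: it is the same operator family with a simpler adjoint and
avoids checkerboard artefacts.

The 1236-wide feature tap is not derivable from any stated layer
arithmetic, so the tap width is a constructor argument
(`feature_dim`, default 1236). Mechanically, the fifth decoder
convolution carries `feature_dim/4` channels and the tap adaptively
average-pools its output to a 2×2 grid before flattening
(`309 × 4 = 1236`); a separate 1×1 output-projection convolution
(sigmoid) then maps that layer to the reconstruction, which always has
the input's shape. The projection is the network's output layer, not
one of the five decoder convolutions. `feature_dim` not divisible by 4
falls back to a 1×1 pooling grid with `feature_dim` channels.

### Training

Both networks are trained by the package's own numeric engine
(convolution as shifted-slice matrix products, exact adjoint backward
passes; each layer's gradients are verified against central
differences in the test suite). The classifier minimizes softmax
cross-entropy; the autoencoder is trained greedily first — each dense
bottleneck is pretrained as a sparse autoencoder on the codes of the
previous stage, with per-stack L2 weight penalties (0.004, 0.002), KL
sparsity regularization (weight 4) toward target activations (0.15,
0.10), and 5 pretraining epochs — then fine-tuned jointly on
`L = ||I - dOUT||^2 / (2N)` plus weight decay.

`train_config()` defaults mirror the study configuration: SGDM,
100 epochs, minibatch 256, initial learning rate 0.001 (the
configuration table's value; a different section quotes 0.0001, and we
follow the table), 10 folds, 50:50 split. Tests and the demo pipeline
use Adam with 1–12 epochs at 32×32 resolution and width scale 0.125 —
the package's chosen desk-scale problem size — because from-scratch
training replaces transfer learning here (no pretrained weights are
downloaded; externally supplied weights can be injected through the
`params` of a `trained_network`).

Hyperparameter initialization is automated by
`tune_hyperparameters_jaya()`: candidates live in the unit hypercube,
are decoded per dimension (log-scale interpolation for learning
rates, nearest-choice rounding for categorical dimensions), and move
by the Jaya update with greedy acceptance. The default space brackets
the study configuration: optimizer {sgdm, adam}, learning rate
log-uniform [1e-4, 1e-2], momentum [0.8, 0.99], minibatch
{32, 64, 128, 256}.

## Feature extraction and fusion

`extract_features()` returns one row per sample in dataset order. The
GAP tap is already a vector; spatial taps are reduced by the tap's
pooling plan (adaptive average pooling then flattening), which makes
the feature width independent of input resolution.

`fuse_features()` pools each row of both matrices independently
(window 2, stride 2 by default) and concatenates extractor 1 first:
1024 → 512, 1236 → 618, fused 1130. Three decisions here:

* The printed "stride 1" cannot produce the printed halved widths;
  only non-overlapping windows (stride = window = 2) reproduce
  512/618/1130, so stride 2 is the default and stride remains
  configurable.
* The pooling operator is never named; `max` is the default
  (salience-preserving), `mean` is available.
* A sentence requiring both vectors to be padded to equal length
  before pooling contradicts the unequal pooled widths that are
  printed; mean padding is therefore used only to align a vector's
  length to the window/stride grid (`mean_pad()` appends the vector's
  own mean), never to equalize the two extractors.

## The wrapper selector

Positions live in [0,1]^d. A position is binarized at threshold 0.5
into a feature mask (the largest component is kept if the threshold
selects nothing); this hard-threshold transfer is standard wrapper-GWO
practice and leaves the leader-averaging update untouched. Fitness is
the hold-out accuracy of an extreme learning machine on the masked
columns: seeded stratified 70:30 split, 100 sigmoid hidden units with
fixed Gaussian weights, output weights solved from ridge-regularized
normal equations (ridge 1e-6 for conditioning; both configurable).
Fitness is pure accuracy — no subset-size penalty — because accuracy
is the stated fitness; one fixed split per selection run keeps
candidate scores comparable, and scores are memoized per mask.

Phase 1 (GWO) moves every wolf toward the three best solutions with
the control scalar decaying linearly 2 → 0. Phase 2 (Jaya, default
100 iterations) refines the final pack against the current best and
worst candidates with greedy acceptance, so the best-so-far trace is
non-decreasing by construction. The absolute value in the Jaya update
is applied exactly as specified even though clipped positions make it
a no-op. Ties in the leader ranking resolve to the lower wolf index.

## Classifiers, metrics, statistics, explanations

The five preset names map to the MATLAB Classification Learner
layouts they come from: narrow [10], medium [25], wide [100],
bi-layered [10,10], tri-layered [10,10,10]; ReLU hidden units, softmax
output, Adam training on standardized features. The published metric
table swaps the conventional sensitivity and precision formulas; the
standard definitions (sensitivity = TP/(TP+FN)) are implemented, since
only they satisfy the FNR = 100% − sensitivity pattern the published
results obey. Multi-class AUC is macro one-vs-rest by the rank
statistic (cross-checked against pROC in the tests). The default
protocol is the 50:50 stratified holdout; k-fold (default k = 10) is
available, averaging metrics over folds.

`paired_difference_test()` takes absolute accuracy differences across
N stages, their mean and *standard* sample deviation (the printed
formula for the deviation is dimensionally inconsistent and does not
reproduce its own published value, 3.065; the standard form yields
3.068), the statistic `T = sqrt(N) mean / sd`, and the two-tailed
Student-t interval. The decision text mirrors the source's reading —
inside the interval means no significant difference — while the
boolean `within_interval` carries the testable content.

Grad-CAM (`explain_image()`) differentiates the pre-softmax class
score with respect to a convolutional tap (default: the output of the
third appended block, the deepest spatial activation before GAP),
averages the gradients spatially into channel weights, and rectifies
the weighted activation sum. Min-max normalization is applied only to
the bilinearly upsampled display copy, never to the raw map used in
tests.

## The synthetic test bed

`make_feature_dataset()` emulates the structure selection must cope
with: informative columns are class-conditional Gaussians whose means
sit at ±`class_sep`/2 by a per-column non-constant sign pattern (unit
within-class variance, so `class_sep` is the separation in standard
deviations); redundant columns are unit-variance linear combinations
of the informative block plus unit-variance noise — attenuated,
genuinely degraded copies of the signal, so informative-column
recovery is measurable; noise columns are class-independent standard
Gaussians. `make_modality_images()` places class-specific sinusoidal
gratings (distinct frequency and orientation) and radial intensity
profiles on an elliptical brain-like mask with seeded pixel noise.

What passing tests show: the optimizer recovers planted structure,
the arithmetic of every published dimension is reproduced, the
learners behave correctly at chance and at separation, and the whole
pipeline is deterministic in its seed. What they do not show: anything
about real MRI — no anatomy, no scanner physics, no intensity
calibration, no class imbalance, and no claim that the published
real-data accuracies are reproduced; those require full-scale training
on external data, which is out of scope by design.

The NIfTI adapter (`nifti_to_image_dir()`) min-max scales each axial
slice independently, because no volume-level intensity calibration is
specified for the source data; it runs only on user-supplied files.

## Problem sizes and determinism

The test suite and demo pipeline use 32×32 grayscale images, width
scale 0.125, a 64-wide autoencoder tap, 1–12 training epochs, and a
selector budget of 8–15 wolves with 10–30 GWO plus 5–20 Jaya
iterations; the standard selection matrix is 300×50 with separation 3.
These are the package's chosen desk-scale study conditions. Every
random draw flows from one root seed through fixed per-stage
substreams, so identical configurations give identical reports,
byte-identical selection masks included. Batch normalization requires
at least two samples per minibatch; training aborts with a diagnostic
on a non-finite loss; degenerate statistics (all paired differences
equal) raise an explicit error rather than returning an undefined
value.

## Known limitations

* The engine is plain R linear algebra: fine at desk scale, not a
  substitute for GPU frameworks at the published 224×224×3 scale.
* From-scratch training replaces ImageNet transfer learning, so
  absolute CNN accuracies at desk scale are modest; the contracts
  tested are descent, above-chance generalization, and determinism.
* The ELM fitness uses a single fixed split per selection run;
  cross-validated fitness would be slower and is not what the source
  procedure describes.
* With redundant columns present, accuracy-optimal masks may swap one
  informative column for redundant ones carrying the same signal; the
  recovery benchmark therefore targets 4 of 5 planted columns, not
  all 5.
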