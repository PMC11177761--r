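---
title: "Methods: two-step embryo segmentation and multi-timepoint outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step embryo segmentation and multi-timepoint outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(embryonet)
```

## The problem

In IVF laboratories, embryologists select which cleavage-stage embryo to
transfer by grading its morphology under a light microscope — blastomere
number, size symmetry and cytoplasmic fragmentation at a few routine
inspection times. The assessment is subjective and varies across
embryologists. `embryonet` implements an automated alternative that works
from exactly the material this routine already produces: three static
grayscale frames per embryo, indexed by hours post-insemination (hpi),
taken from a 10-minute-interval time-lapse series or from scheduled
single exposures. The prediction target is the binary pregnancy outcome
of the transferred embryo (clinically, a beta-hCG threshold ~15 days
after transfer).

The pipeline has two steps:

1. **Segmentation.** A U-Net separates the embryo (zona pellucida disk)
   from the culture background; the mask is post-processed, and the frame
   is cropped to the embryo and resized to the classifier's input side.
2. **Classification.** Each of the three cropped frames passes through a
   convolutional backbone that emits a 10-dimensional feature vector; the
   three vectors are concatenated (30 features) and one fully connected
   layer with a sigmoid produces the pregnancy probability. A
   single-image baseline (`build_si_model()`) applies one backbone to the
   final 68-hpi frame only; comparing the two quantifies the value of the
   earlier timepoints.

## Timepoints and frame indexing

The three analysis timepoints default to 19, 44 and 68 hpi with a ±1 h
acceptance window (`timepoint_spec()`). These are the operational values
of the routine sequential assessment; published descriptions of the same
protocol sometimes quote 19/43/67 or 19/42/66, and the triple is
configurable for that reason. With 10-minute acquisition intervals,
`frame_index_for_hpi()` maps a target time to the nearest frame index
(19 hpi → frame 114); `extract_timepoints()` takes the closest available
frame within tolerance and fails naming the target otherwise — a missing
timepoint is a data problem the caller must see, not something to
interpolate over.

## Leakage-safe splitting

Embryos from one patient are morphologically and prognostically
correlated, so a patient must never straddle the train/test boundary.
`split_grouped_stratified()` assigns whole patient groups: per-class test
quotas are set to `(1 - train_fraction) x class size`, patient groups are
shuffled under the seed, greedily assigned to the test side while they
fit under every class quota, and a repair pass moves groups whose
transfer strictly reduces the remaining deficit. With one embryo per
patient and the default cohort composition (252 embryos, 180/72 by
class, fraction 2/3) the result is exactly 168 training (120/48) and 84
test (60/24) embryos. Because no separate validation protocol is part of
the source design, a validation fraction (default 0.15 of the training
side, same grouping rules) can be carved out for early stopping.

## Augmentation recipe

Training images are expanded offline by a factor of 30
(`augmentation_config()`, `augment_embryo()`). Each augmented sample
composes, in order: a rotation drawn from [0°, 360°], a zoom from
[0.8, 1.2], and a shear whose drawn factor s in [0.8, 1.2] is applied as
the off-diagonal coefficient s − 1 (a literal coefficient of 0.8–1.2
would destroy the embryo geometry; `shear_mode = "literal"` restores the
verbatim reading). The composed warp is applied once per frame (single
resampling, bilinear, background = image border median), and then exactly
one of additive Gaussian noise (m = 0, v = 0.003) or multiplicative
speckle noise (m = 0, v = 0.006) is applied — the recipe offers the two
as alternatives, so each sample draws one with probability 1/2.
Horizontal/vertical flips and translation are implemented but off by
default. Within one augmented triplet the same geometric transform is
applied to all three frames, preserving cross-timepoint correspondence
(independent-per-frame geometry would decouple the branches; the choice
is a config switch). Noise is drawn independently per frame. Masks are
co-warped with nearest-neighbour interpolation and stay binary.

## Segmentation step

`build_unet()` follows the classic encoder–decoder layout: per level two
3×3 convolutions + ReLU, 2×2 max pooling between levels, channel count
doubling at each downsampling (depth 5 with base 64 gives
64–128–256–512–1024); the expansive path uses nearest ×2 upsampling
followed by a 2×2 "up-convolution" halving the channels, concatenation
with the matching encoder features, and two further 3×3 convolutions.
Convolutions use *same* padding so the output probability map matches the
input resolution (the original valid-padding variant crops; full-frame
masks are more convenient downstream). The final 1×1 convolution emits
per-pixel logits.

Training (`train_segmenter()`) minimizes the sum of binary cross-entropy
and soft Dice loss — BCE alone is poorly scaled for the small foreground
fraction, Dice alone has weak gradients early; the sum is a standard
compromise. Hyperparameters default to the classification regime below.
`postprocess_mask()` binarizes at 0.5, keeps the largest connected
component and fills holes — there is exactly one embryo per frame, so a
single component is a hard invariant, and an all-background map raises an
explicit empty-mask error rather than returning an empty mask.
`crop_and_resize()` expands the mask bounding box by 5%, squares it by
symmetric padding and resizes to the backbone's native side (224 px; 299
for Inception V3). Dice is `2|A∩B|/(|A|+|B|)`; two empty masks score 1
by convention (documented, and irrelevant in practice because
post-processing never emits an empty mask).

## Classification step

`backbone_spec()` names six architectures: AlexNet, ResNet-18,
ResNet-34, Inception V3, DenseNet-121, and `tinycnn`, a three-block
conv–batchnorm–ReLU network with global average pooling that this
package adds as its CPU-scale test backbone (it has no published
pretrained weights and is not part of the source design). One
architecture listing in the source material says "ResNet36"; every other
occurrence says ResNet-34, so the former is treated as a typo and only
ResNet-34 is implemented. Grayscale crops are replicated to three
channels and normalized with the ImageNet channel statistics when
pretrained weights are requested, else with mean 0.5 / sd 0.5.

No pretrained weight files ship with this package and none can be
downloaded at build time, so `pretrained = TRUE` raises an explicit
error unless `random_init_fallback = TRUE` builds the architecture with
random initialization — useful for the transfer-learning *mechanics*
(freezing, shapes) but obviously not for its accuracy benefits. With
`freeze_mode = "last_layer_only"` only the final feature layer trains;
all other parameters remain bit-identical through optimization, which
the tests assert literally.

The fusion model's three branches are independent by default (the design
drawing shows three separate networks); `share_branch_weights = TRUE` is
available since the original sharing choice is not stated. The head input
is 3 × 10 = 30 features; the single-image head sees 10.

## Training regime

`train_config()` encodes the declared regime: learning rate 0.001
reduced by a factor of 0.1 every 30 epochs (so a full 100-epoch run
visits 1e-3/1e-4/1e-5/1e-6 in 30/30/30/10-epoch blocks), batch size 32,
binary cross-entropy loss, early stopping monitored on validation loss.
Choices the source leaves open, fixed here: the optimizer is Adam
(β = 0.9/0.999); early-stop patience is 10 epochs; a `min_epochs` guard
(default 10) prevents stopping while batch-norm running statistics are
still maturing — in the first epochs the eval-mode validation loss sits
near ln 2 regardless of progress, and without the guard the "best"
checkpoint can freeze at epoch 1. Ties in validation loss resolve to the
later epoch for the same reason. The best-validation snapshot (weights
*and* normalization statistics) is restored at the end. An optional
positive-class weight (120/48 ≈ 2.5) exists but is off by default, since
the source regime does not mention loss weighting.

A failure mode worth naming: without pretrained weights, training can
stay at the majority class — a constant predictor.
`is_constant_predictor()` detects this "not learned" state from the
predictions, and the pipeline summary reports it rather than hiding it
behind an accuracy number.

## The neural-network engine

No deep-learning runtime is assumed: the package carries a compact
reverse-mode autograd engine on dense R arrays (`(H, W, N, C)` feature
maps), with the hot kernels — im2col/col2im convolution, pooling, ReLU,
bias broadcasting — in C++ via Rcpp and the matrix products in BLAS.
Every backward rule is validated against finite differences in the test
suite. Determinism: all randomness flows through R's RNG under
caller-supplied seeds, so a fixed seed reproduces cohorts, splits,
augmentations and training runs bit-identically on a given BLAS.

## Synthetic data: what it emulates and what it does not

`generate_cohort()` renders embryo-like frames: a bright zona pellucida
ring on a darker background, containing 1 (stage 1, ~19 hpi), 2–4
(~44 hpi) or 6–8 (~68 hpi) blastomeres drawn as anti-aliased ellipses
with brighter membranes, plus small bright speckles emulating
fragmentation, then pixel Gaussian noise (sd 0.02). The ground-truth
mask is the zona disk — a single connected component strictly inside the
frame. Default composition mirrors the study cohort (252 embryos,
180/72); image side defaults to 256 px with 64 px used throughout the
tests for speed.

The class signal is a controllable stand-in, not a claim about the real
discriminative features (which the source does not describe): positive
embryos draw blastomere radii with log-normal spread
`0.25·exp(−0.7·effect_size)` (negatives: 0.25) and fragment counts from
`Poisson(6·exp(−0.7·effect_size))` (negatives: Poisson(6)). Both cues are
exactly the morphology embryologists grade — size symmetry and
fragmentation. At `effect_size = 0` the label enters nowhere, so the
label-conditional image distributions are identical (the tests assert
bit-identical renders under a shared RNG stream). `signal_timepoints`
restricts where the signal is rendered; setting it to {t1, t2} creates
cohorts where the final frame is uninformative — the condition under
which the fusion-vs-single-image comparison is run.

What the generator does *not* capture: optical texture of cytoplasm,
zona thickness variation with stage, perivitelline space, debris, focus
drift, illumination gradients, morphokinetic timing between the three
stages, and inter-patient correlation of appearance. Passing tests on
synthetic cohorts therefore demonstrate that the machinery is correct
and that the architecture can exploit morphology-like signals — they do
not certify clinical accuracy on real microscopy, and the clinical
accuracy figures of the original study are deliberately not used as
targets anywhere in this package.

## Desk-scale evaluation choices

The packaged experiments run on one CPU in minutes and are sized as
follows (all parameters are arguments, these are the defaults):

- `fusion_vs_si_experiment()`: 5 seeds; balanced cohorts of n = 300 at
  64 px; `effect_size = 2`; signal in timepoints 1–2 only; both models
  use tinycnn branches, trained 10 epochs (batch 32, lr 1e-3) on raw
  frames — segmentation is bypassed so the comparison isolates the
  classifier claim. Reported: per-seed test accuracies and the median
  fusion-minus-single-image margin. Balanced classes are used here (not
  the 5:2 cohort imbalance) so that the single-image model's collapse to
  the prior reads as ~0.5 and the margin measures discrimination, not
  prior matching.
- `segmenter_benchmark()`: 200 frames at 64 px, 75/25 split, U-Net depth
  3 / base 4, 20 epochs, batch 16; reports held-out mean Dice after
  post-processing. The depth-5/base-64 configuration of the full design
  is available but unnecessary for the ring-separation task and slow on
  one CPU.
- `signal_monotonicity_experiment()`: the blastomere-size-CV threshold
  discriminator (fit on the training split of each replicate) must have
  non-decreasing accuracy in `effect_size` and chance accuracy at 0. It
  reads the generator's rendered morphology record; an image-measured
  variant would entangle this generator check with segmentation quality.

## Evaluation conventions

`compute_metrics()` applies the four standard formulas literally
(precision TP/(TP+FP), recall TP/(TP+FN), accuracy, F1 as their harmonic
mean). On an imbalanced test set literal recall and accuracy are
different quantities; published tables of this design sometimes print
them equal, which is only consistent with a macro-averaged recall. Both
views are therefore computed and labelled separately (`recall` vs
`macro_recall`), and nothing in the package asserts their equality.
Zero-denominator metrics are reported as 0 and flagged in `undefined`
rather than as NaN. `majority_vote()` is the rater-panel mode; even-panel
ties are an error by default (a 2–2 panel has no consensus) with an
opt-in negative-default policy. Comparison tables print percentages to
two decimals and flag best and second-best per metric.

## Known limitations

- CPU-only and unoptimized relative to GPU frameworks; the big
  backbones are practical for inference-shape checks and small
  fine-tuning, not for full ImageNet-scale training.
- No pretrained weights, so the accuracy advantage of transfer learning
  cannot be reproduced offline — only its mechanics.
- The synthetic generator's signal is a stand-in; results on it bound
  nothing about clinical data.
- Batch-norm statistics make eval-mode predictions depend (slightly) on
  the training history; predictions are batching-invariant but not
  architecture-portable across retrains.
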