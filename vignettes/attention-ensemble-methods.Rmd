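---
title: "Methods: the attention-ensemble dual-backbone classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the attention-ensemble dual-backbone classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pneumonet` implements a two-class chest X-ray classifier (normal vs
pneumonia) built from two convolutional backbones whose feature maps are
refined and merged by a stack of attention mechanisms:

1. **Feature extraction.** An EfficientNet-B0 branch and a DenseNet-121
   branch each map a 224x224x3 input to a 7x7 feature map (1280 and 1024
   channels respectively).  A compact `tiny_test` backbone — a stack of
   stride-2 3x3 convolutions with ReLU, widths 4/8/16 — can replace either
   branch so that the full architecture trains in minutes on one CPU.
2. **Multi-head self-attention.**  Each branch's map is flattened into
   `h*w` spatial tokens whose embeddings are the channel vectors, and
   scaled dot-product attention `softmax(QK'/sqrt(d_k))V` is applied with
   4 heads and key dimension 128, with learned per-head Q/K/V projections
   and an output projection back to the channel count.  The block replaces
   the feature map (no residual add) and uses no positional encoding, so
   it is permutation-equivariant over spatial positions; the flattening
   order is therefore only a labelling convention.
3. **Channel-attention feature fusion.**  Each branch is gated by a
   sigmoid 1x1 convolution (one output channel per input channel),
   multiplied elementwise, globally average pooled to a channel vector,
   projected by a ReLU dense layer of 784 units with dropout, and the two
   projections are summed and reshaped to 7x7x16.  The 784 width is forced
   by the reshape: `7 * 7 * 16 = 784`, and the configuration validator
   enforces that identity.  The reshape places the last axis fastest
   (row-major); the convention is arbitrary but must be fixed for
   reproducibility.
4. **Residual block.**  Two 3x3 convolution / batch-norm / ReLU stages with
   256 filters, stride 1 and same padding; the shortcut is an identity when
   channel counts match and a 1x1 convolution projection otherwise; the
   output is `ReLU(main + shortcut)`.  The internal depth (two
   convolutions) follows the standard residual design.
5. **Attention augmentation.**  A channel gate computed from the features
   themselves: dense(C, ReLU) -> batch norm -> dropout -> dense(C, sigmoid)
   -> batch norm -> dropout, applied independently at every spatial
   position, returned as the Hadamard product with the input.  The dense
   layers act on the channel axis — the only reading under which a dense
   layer of width `C` type-checks against a rank-4 input.
6. **Dynamic attention pooling.**  A spatial sigmoid gate (1x1 convolution
   to one channel) multiplies the map before global average pooling.  The
   literature describing this block gives both a gate-then-pool pseudocode
   and a pool-then-gate formula whose shapes do not compose; the executable
   pseudocode (multiply, then pool) is what is implemented.  When the gate
   saturates at 1 the block reduces to plain global average pooling.
7. **Classifier head.**  Dense(128, ReLU) with an L2 penalty of 6.72e-3 on
   its weights, batch norm, dropout, Dense(2, softmax).  Two-class softmax
   with one-hot labels is kept (rather than a single sigmoid) to match the
   published head exactly.

Every block has an identity or simple bypass selectable through
`components` flags in `assemble_model()` — fusion falls back to
"dimensionality reduction followed by concatenation" (GAP each branch,
concatenate, linear-ReLU fit to the reshape target), augmentation and
multi-head attention to the identity, dynamic pooling to plain GAP — so
component ablations are runnable.  With all four flags off the model
reduces to GAP-concatenation of backbone features feeding the head
directly.

## Preprocessing and training

*Preprocessing*: bilinear resize to 224x224 (half-pixel-centre mapping, so
an identity-size resize is exact), classical CDF histogram equalization on
the grayscale intensities (`out(v) = round((cdf(v) - cdf_min)/(N -
cdf_min) * 255)`; a constant image, whose `cdf_min = N` makes the
denominator zero, is defined to map to zeros), replication to 3 channels,
scaling to [0, 1].  Equalization precedes channel replication and
augmentation so that boundary-fill pixels are never equalized; it is
applied to all splits.

*Augmentation*: rotation sampled in +/-15 degrees, shifts in +/-0.1 of the
side, shear in +/-0.2, zoom scale in [0.8, 1.2] (the scalar 0.2 is read as
a symmetric half-width around 1, the common convention), composed into a
single affine warp about the image centre with nearest-edge boundary fill,
followed by a multiplicative brightness factor in [0.8, 1.2] and clipping.

*Class weights*: the source data are imbalanced (3875 pneumonia vs 1341
normal training images), and the balanced scheme
`w_c = n_total / (n_classes * n_c)` is used — the de-facto convention when
a weighting is stated but no formula given.  It satisfies
`sum_c n_c w_c = n_total` identically.

*Optimization*: Adam under a linear warmup, `lr(step) = peak_lr * min(1,
(step+1)/warmup_steps)`, constant afterwards; `warmup_steps` defaults to
one epoch of steps — the simplest schedule consistent with a smooth ramp,
fully configurable.  The loss is categorical cross-entropy with per-sample
class weights normalized by the total weight (so a zero-weight class
contributes exactly nothing), plus the head's L2 penalty.  Defaults follow
the tuned values: batch 8, 5 epochs, peak learning rate 7.47e-5, dropout
0.2377, L2 6.72e-3.  One global dropout value is applied to the fusion,
augmentation and head blocks; the coarser 0.23 / 0.006 quoted in some
block listings are treated as two-significant-figure roundings of the
tuned 0.2377 / 6.72e-3.

All randomness — weight initialization, shuffling, dropout masks,
augmentation draws — is keyed off explicit seeds through dedicated RNG
scopes, never ambient RNG state, so a repeated run reproduces the training
history bit for bit.

### Numerical choices

- Batch-norm epsilon is 1e-6 and the running-moment momentum 0.9.  With
  minibatches of 8 over a few hundred steps, the usual 0.99 momentum
  leaves running moments far from the batch moments the weights were
  trained against; 0.9 converges within an epoch here.
- After training, the batch-norm running moments are **recalibrated**:
  the training set is passed through the network once in class-interleaved
  chunks of 64 and the exact weighted population moments replace the
  exponential averages ("precise BN").  Without this, inference-mode
  predictions of a batch-8-trained network drift substantially from its
  training behaviour — at this problem scale the drift is large enough to
  collapse validation accuracy.
- Weight initialization is Glorot-uniform throughout (the convention of
  the framework the architecture is usually written in); biases start at
  zero.
- Softmax and cross-entropy are computed with max-shifting and a 1e-12
  floor.
- Hand-set oracle tests configure batch norm as the identity (unit scale,
  zero shift, zero running mean, unit running variance, inference mode)
  to isolate the algebra of each block, and disable dropout (inference
  mode).

## Backbones without downloads

Pretrained weights cannot be shipped or fetched, so `pretrained = TRUE` is
rejected.  The EfficientNet-B0 and DenseNet-121 branches are implemented
architecturally — the full published layer tables, with
squeeze-excitation, depthwise convolutions, dense connectivity and
transitions — and their documented output geometries (7x7x1280 and
7x7x1024 from 224x224x3) are asserted by running a forward pass at build
time rather than assumed.  They run as fixed (frozen) feature extractors
with Glorot-random weights: the backward pass is implemented only for the
`tiny_test` backbone, which is the trainable path all training-facing
functionality uses.  Fine-tuning policy for the large backbones is out of
scope; the flag exists and is rejected explicitly rather than silently
ignored.

## The synthetic fixture

`generate_synthetic_dataset()` emulates the layout of the public dataset
(train/val/test splits, normal/pneumonia class subdirectories, 8-bit
grayscale PNG — PNG rather than JPEG so regeneration is byte-identical
across codecs).  "Normal" images are a dark background with two brighter
elliptical lung fields plus Gaussian noise (sd 8 intensity units);
"pneumonia" images add 3–7 blurred bright blobs (Gaussian bumps, width ~6
px at 224, amplitude 100–140) placed inside the lung fields, emulating
opacities.  Planted blob positions are written to `blob_truth.csv` so the
Grad-CAM localization check has ground truth.  Defaults are 200 training
images per class with 25 per class for validation and test;
`study_split_counts()` provides scaled-down versions of the real 3875/1341
and 390/234 imbalanced splits for exercising class weighting.

What the fixture does *not* emulate: anatomical structure, scanner and
exposure variation, the ambiguity of real opacities, label noise.  The
classes are separable by construction, so passing smoke tests demonstrates
that the pipeline can extract and use a planted signal end to end — not
that the architecture reaches any particular accuracy on real chest
X-rays.

## Desk-scale training demonstrations

The end-to-end checks train the full architecture with two `tiny_test`
backbones from random initialization.  Two deliberate departures from the
tuned defaults apply there, both consequences of training *from scratch*
at small step counts rather than fine-tuning pretrained backbones:

- **Learning rate 3e-3.**  The tuned 7.47e-5 moves Adam-updated weights by
  ~2e-2 over the 250 steps of the smoke run — appropriate for nudging
  pretrained features, far too small to train random weights.  The smoke
  runs use 3e-3, in the standard range for from-scratch Adam training.
- **Augmentation off.**  With only 250 steps, redrawing strong affine
  warps every epoch dominates the optimization signal; augmentation has
  its own dedicated unit and property tests.

Problem sizes used by the checks: the smoke run trains on the default
fixture (200/class at 224x224, 5 epochs, batch 8, warmup Adam, class
weights) and reaches >= 95% training accuracy in roughly three minutes on
one CPU.  The component-ablation comparison (full model vs the
all-components-removed bypass, 5 seeds each) runs at a reduced size
(112x112, 100/class, 5 epochs).

**A negative desk-scale result, reported as measured.**  On real chest
X-rays with pretrained ImageNet backbones, the full attention ensemble
outperforms the all-components-removed bypass.  That direction does *not*
transfer to from-scratch training on the synthetic fixture: across every
condition we measured (64--224 px, 40--200 images per class, 3--10 epochs,
learning rates 1e-3 to 3e-3), the shallow GAP-concatenate bypass converges
within a few dozen Adam steps and reaches 0.88--0.99 validation accuracy,
while the deep randomly-initialized attention pipeline needs an order of
magnitude more steps to fit and generalizes worse at these step counts.
This is expected optimization behaviour — the fixture is separable from
channel means, which is exactly what the bypass computes, and the
ensemble's depth only pays off with pretrained features and harder data —
but it means the ablation-direction check in the acceptance suite fails at
desk scale, deliberately: the comparison is implemented and reported
honestly rather than rescaled until it passes.

## Known limitations

- The large backbones are forward-only and randomly initialized; results
  with them are architecture and plumbing demonstrations, not ImageNet
  transfer.
- Batch-norm behaviour at batch 8 is intrinsically noisy; the
  recalibration removes the train/eval moment mismatch but not the
  batch-composition dependence learned during training.
- The hyperparameter search ships its own compact tree-structured Parzen
  estimator (random startup trials, then candidates drawn from a Parzen
  density over the best quartile and ranked by good/bad density ratio).
  It is validated against a brute-force grid on a deterministic toy
  objective, not against any external optimizer.
- Undefined metrics (empty denominators, e.g. on tiny cross-validation
  folds) propagate as `NA`, never silently as zero.
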