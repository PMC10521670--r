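---
title: "Universal landmark detection across anatomies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal landmark detection across anatomies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(uniland)
```

## The problem and the model

Anatomical landmark detection assigns (x, y) coordinates to named,
reproducible points on a medical image: cephalometric reference points on a
lateral skull radiograph, ossification centres on a hand radiograph,
lung-field extrema on a chest film. The dominant approach is heatmap
regression: instead of predicting coordinates directly, the network
predicts one dense probability-like map per landmark and the landmark is
read off as the argmax.

`uniland` implements GU2Net, a *universal* detector: one network trained
once on a mixture of anatomically distinct datasets ("domains"), with an
explicit split of its weights into

* **domain-shared parameters** — the 1x1 point-wise convolutions of the
  local branch, used by every domain, which carry the cross-anatomy
  "common knowledge"; and
* **domain-specific parameters** — the channel-wise 3x3 convolutions
  (one replica per domain, selected by `domain_id` at run time), the
  per-domain output heads, and the entire global branch.

The architecture has two branches:

* **Local branch**: a U-shaped encoder-decoder in which every convolution
  block is a depth-wise separable convolution — a per-domain channel-wise
  3x3 convolution followed by a shared point-wise 1x1 convolution, each
  with batch normalization and leaky ReLU. Four 2x2 max-poolings halve the
  resolution (hence working sizes must be divisible by 16) and the decoder
  mirrors the encoder with bilinear upsampling, skip concatenations, and
  channel halving. A per-domain 1x1 head followed by a logistic sigmoid
  emits one map per landmark. For `t` domains, an `N`-in, `M`-out block
  costs `9 t N + N M` weights versus `9 t N M` for `t` standard
  convolutions (`count_separable_params()` / `count_standard_params()`).
* **Global branch**: per domain, five dilated 3x3 convolutions with
  dilations `c(1, 2, 5, 2, 1)` (receptive field 23x23,
  `global_receptive_field()`), batch normalization and plain ReLU between
  layers and a sigmoid at the end. It runs at quarter resolution on the
  bilinearly downsampled image and local heatmap — concatenated
  channel-wise by default ("cat"), or added after a per-domain 1x1
  projection of the image ("add") — and its output is upsampled back.

The final heatmap is the element-wise product of the two branches'
sigmoid maps, so a landmark scores highly only where fine local evidence
and coarse global context agree. Training minimizes the soft-label binary
cross-entropy between the fused map and a Gaussian target, summed over
pixels and channels within an image and averaged over the batch.

## Heatmap codec

Targets follow `gamma / (2*pi*sigma) * exp(-d^2 / (2*sigma^2))` with
`sigma = 3` px by default and `gamma = 2*pi*sigma`, so the printed
prefactor is exactly 1 and maps live in `[0, 1]`. The Gaussian is
evaluated at every pixel centre with its centre at the exact, possibly
fractional, landmark: the value *at the landmark* is exactly 1, and the
grid maximum sits at the nearest integer pixel (equal to 1 whenever the
landmark is integral). Decoding is a plain argmax with row-major
first-occurrence tie-breaking; no sub-pixel refinement is applied, so the
decode-encode round trip is exact up to 0.5 px per axis. Channels are
independent: overlapping Gaussians of nearly coincident landmarks are
neither clipped nor renormalized.

A consequence worth knowing when reading loss curves: soft targets carry
an irreducible cross-entropy `H(Y)` (a perfect prediction of a Gaussian
target still pays the target's own entropy, roughly 350–600 nats per
64x64 image depending on the landmark count). Training-loss plateaus
near that floor therefore indicate a *good* fit; the learnability test in
the suite measures overfitting as excess loss above the floor.

## Coordinates, spacing, and metrics

Everything uses 0-based pixel coordinates, x = column, y = row, pixel
centres at integers. `resize_sample()` maps `(x, y)` to
`(x W_new/W_old, y H_new/H_old)` and rescales the per-axis spacing by the
inverse factors, so physical distances between landmarks are preserved
exactly even when the stretch is anisotropic (the cephalogram case:
0.1 mm pixels resized from 1935x2400 to 416x512). Hand radiographs carry
no physical calibration; spacing is inferred from an assumed 50 mm wrist
width between landmarks 1 and 5 of the 37-point set
(`hand_spacing()`), computed on the resized coordinates so the pipeline is
self-consistent under anisotropic resizing.

The mean radial error (MRE) is the arithmetic mean of
`||(dx*sx, dy*sy)||` over all (image, landmark) pairs, pooled flat —
matching the successful detection rate (SDR), the percentage of errors
*strictly* below a threshold (a tie at the threshold does not count). The
reported spread is the population standard deviation (divide by N).
Per-domain threshold grids default to (2, 3, 4) mm for mm-calibrated
domains and (3, 6, 9) px otherwise.

## Training recipe

Defaults in `train_config()`: batch size 4, Adam, up to 100 epochs,
Gaussian `sigma` 3 px, checkpoint selection at minimum pooled
(sample-weighted) validation loss. When no validation sets are supplied,
10% of each training split is held out deterministically under the run
seed. Augmentation is rigid and on-the-fly: rotation by an angle uniform
in ±2° with probability 0.1, and independently integer translations
uniform in ±10 px per axis with probability 0.1; landmark coordinates are
transformed by the same map and targets re-encoded (not warped). A draw
that would push a landmark out of frame is retried and ultimately falls
back to the identity.

The learning-rate policy is cyclic between 1e-2 and 1e-4: within each
cycle (default 10 epochs) the rate decays linearly from the cycle's peak
to `lr_min`, and peaks decay geometrically across cycles, so the trace
starts at `lr_max` and ends at `lr_min`. The exact cycle shape is a
design choice of this package — the recipe's published form names only
the range and a cyclic policy.

Mixed-domain training draws the *domain of each batch* with probability
proportional to that domain's training-set size; batches themselves are
homogeneous in domain. Within-batch mixing would force per-sample
convolution routing and cross-domain batch-norm statistics inside one
batch; batch-level mixing keeps running statistics per anatomy. Loss is
applied to the final fused map only.

## Numerical choices

* Batch normalization: momentum 0.1, eps 1e-5, biased variances; running
  statistics are per-domain wherever the preceding convolution is
  (channel-wise convs, global branch) and shared after shared point-wise
  convs, so no anatomy pollutes another's statistics.
* Output squashing is the logistic sigmoid on both branches (required for
  the cross-entropy's log terms to be defined); heads and the last global
  convolution start with bias -4, the background-probability logit, which
  removes the large initial gradient from the overwhelmingly empty
  background.
* He-scaled Gaussian initialization; initialization is a pure function of
  the configuration and its seed.
* Predictions are clamped to `[1e-6, 1 - 1e-6]` before the log terms;
  gradients vanish where the clamp is active.
* Global gradient-norm clipping at 5.0 guards the early high-learning-rate
  steps.
* The point-wise bias is mathematically redundant (batch norm subtracts
  the batch mean immediately after); it is kept for interface fidelity and
  its gradient is identically zero.
* Leaky-ReLU slope 0.01 in the local branch; the global branch uses plain
  ReLU. Sub-gradient at exactly zero follows the negative-side convention.
* Up/down-sampling is bilinear with half-pixel-centre mapping and exact
  adjoints in the backward pass; the decoder is transposed-convolution
  free so every learnable convolution stays separable.

## The synthetic benchmark

The generator emulates the structure of a multi-anatomy radiograph
collection without any external data: several visually distinct
parametric shape families, each with a fixed landmark count and
consistent landmark-to-shape geometry, per-image random affine jitter,
and additive intensity noise. Landmarks are defined analytically on the
shape *before* rasterization and transformed with the same affine map, so
ground truth is exact real-valued coordinates. Randomness is counter
based — each (config, index) pair derives its own RNG stream — so any
sample is reproducible independently of generation order, and the global
RNG state is left untouched.

Families: `ellipse_ring` (a bright elliptical ring; landmarks at axis
points and the centre), `digit_fan` (a fan of rays; tips, mid-joints, and
the base), `twin_lobes` (two filled lobes; extremal and central points),
and `arch_pair` (two broad arches; points along each arch). Defaults:
64x64 images (the smallest multiple of 16 that keeps sigma-3 Gaussians
well resolved while allowing CPU training in minutes), jitter of ±8%
scale, ±10° rotation, ±4 px translation, noise SD 0.08 on a [0, 1]
intensity scale — variability comparable to patient positioning spread,
chosen once as the benchmark's fixed conditions. Landmarks keep a safety
margin of at least 2 sigma (8 px) from the border, with bounded jitter
redraws. The default benchmark registers three domains with distinct
landmark counts (5/9/4) and 200/20/40 train/val/test images each; a
two-domain preset with equal counts (5/5) exists because full parameter
swaps, including output heads, need shape-compatible domains.

What passing on this benchmark does and does not show: the shapes are
high-contrast and the jitter family is affine, so the benchmark
demonstrates that the architecture, routing, optimization, and evaluation
machinery work end to end — it does not demonstrate robustness to the
texture, occlusion, pathology, and exposure variation of real
radiographs. The bundled registry of the four real radiograph datasets is
a drop-in for the same loaders when those images are available.

## Study sizes used by the test suite

The end-to-end study trains the reduced-width joint model (encoder widths
16/32/64/128, global width 32) on the 3-domain benchmark for 20 epochs,
compares it against three single-domain specialists trained with the same
per-image budget (20 epochs over their own 200 images), and runs the
cross-anatomy swap on the two-domain equal-count benchmark (100 training
images per domain, 10 epochs). These sizes were chosen as the smallest
configuration on which the joint-versus-specialist comparison and the
swap asymmetry are stable across seeds. With the default full-size
configuration (widths 64/128/256/512, global width 168) the four-domain
model holds ~5.0M trainable parameters, about 0.37x the
standard-convolution U-Net baseline under the same widths.

## Design decisions where the design was open

* Decoder widths halve after each upsampling (1024-to-256 style blocks);
  encoder widths 64/128/256/512 with double convolution blocks. These
  unprinted widths were fixed so the four-domain default lands near 5M
  parameters with the baseline near 3x that.
* The global branch consumes image and local heatmap after downsampling
  both by 4 (the branch's stated working scale); whether the original
  design downsampled before or after concatenation is ambiguous, and this
  choice keeps the branch's cost at 1/16 of full resolution.
* The global-only ablation takes the downsampled image alone as input
  (there is no local map to feed it), and the local-only ablation fuses
  against an all-ones global map.
* Parameter swaps between domains with unequal landmark counts exchange
  everything except the output-shaped tensors (heads, final global
  convolution), which are reported as skipped.
* Domain-count sweeps average over subsets containing the probe domain,
  capped at three subsets per size for bounded runtime.

## Known limitations

2D grayscale radiographs only — no DICOM ingestion, no 3D volumes, no
attention variants, no sub-pixel decoding, no mixed-precision or
multi-device training. A trained model cannot process an unregistered
domain: there are no parameters to route it through, and
`predict_heatmaps()` refuses rather than guessing. Batch-level (not
within-batch) domain mixing is a config-visible simplification. The
synthetic benchmark's caveats are described above.
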