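---
title: "Co-optimized semi-supervised segmentation: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-optimized semi-supervised segmentation: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ischemic-penumbra delineation on multi-modal MRI is a segmentation task with
chronically few labels: expert annotation of the penumbra ring around an
infarct core is slow and inconsistent, while unlabeled slices are plentiful.
`coseg` implements a semi-supervised strategy for exactly this regime: a
supervised segmentation branch is assisted by an unsupervised reconstruction
branch, and the two are *co-optimized* — trained jointly under one mixed loss,
coupled where their information content is densest, at the encoder bottleneck.

The package treats every training image as having two states: a *labeled*
state (image + binary penumbra mask) that feeds the segmenter, and a *pseudo
unlabeled* state (image only, label deliberately withheld) that feeds the
reconstructor. All training images are therefore reused in the unlabeled
pool regardless of the label fraction; validation images are excluded from
every training stream, and test images are never seen during training.

## The four networks

* **Reconstructor R** — a ResNet-style encoder (stem convolution plus
  `n_stages` stages of bottleneck residual blocks, channel doubling per
  stage, stride-2 downsampling in each stage's first block) followed by a
  plain decoder of `n_stages` upsample + Conv-BN-ReLU units and a final
  1×1 convolution with Tanh. No skip connections: with skips an autoencoder
  can copy its input and learns nothing at the bottleneck. Output range is
  (−1, 1), which is also the phantom intensity normalisation range.
* **Segmenter S** — the *same encoder architecture* (independently
  initialised), plus a U-style decoder: each stage upsamples ×2
  (nearest-neighbour, chosen for determinism), concatenates the matching
  encoder skip, applies two Conv-BN-ReLU units and dropout. A 1×1
  convolution and per-pixel softmax produce class probabilities.
* **Discriminator D** — four stride-2 3×3 Conv-BN-ReLU layers, a hidden
  fully connected layer of 512 neurons, and a 2-way softmax separating real
  inputs from reconstructions.
* **Transfer block T** — a 1×1 convolution, BatchNorm and ReLU applied to
  R's bottleneck feature, added elementwise onto S's bottleneck. Because
  both encoders share one architecture the spatial shapes agree by
  construction; the ReLU makes T's contribution nonnegative, so a zeroed T
  is exactly the identity on S's path.

Residual blocks use three convolutions (1×1, 3×3, 1×1) with an identity (or
projected) shortcut. The two paths are fused either by concatenation
followed by a 1×1 projection (default) or by elementwise addition; no
activation follows the fusion, so a zero-weight block with `add` fusion is
the identity map — a property the tests rely on. The depth (`n_stages = 4`,
two blocks per stage at `base_width = 32` by default) is a declared layout
choice: the architecture family is fixed, its width and depth are
configurable because the method's claims do not hinge on network size.

One open design point was which of R's layers to transfer. We use R's
encoder bottleneck — it is the only feature whose shape matches S's
bottleneck for additive fusion — and we inject the fused feature only into
S's decoding path, not back into R.

## Losses

With foreground probabilities $p$ and binary mask $y$, the segmentation loss
is the soft Dice loss

$$\ell_s = 1 - \frac{2\sum p\,y + s}{\sum p + \sum y + s},$$

with smoothing $s = 1$ during training (stability on empty masks) and
$s = 0$ for reporting. When both prediction and mask are empty the loss is 0
by convention: an empty prediction of an empty mask is perfect.

The reconstruction branch is trained as an adversarial autoencoder. The
generator side minimises

$$\ell_r = \mathrm{MSE}(R(x), x) + w_{adv}\,\mathrm{CE}(D(R(x)), \text{real}),$$

while D minimises its own cross-entropy on real vs reconstructed batches.
A formulation that subtracts D's cross-entropy on the *input* under both
labels is not a trainable objective (the terms cancel against each other and
contain no generator signal), so the package deliberately uses this standard
adversarial reading; $w_{adv}$ defaults to 1 and is configurable.
Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before any logarithm.

The mixed objective is

$$\ell_{mix} = \ell_s + \lambda\,\ell_r,$$

with $\lambda = 0.2$ by default. The weight sits on the reconstruction term
so that $\lambda = 0$ *disables the reconstruction branch entirely*: in that
mode the trainer runs no reconstruction forward pass and no transfer fusion,
making a $\lambda = 0$ run bit-identical to a plain supervised segmenter
under the same seed. This is the semantics the λ-sweep relies on.

## Training procedure

Training is two-phase:

1. **Unsupervised pretraining** of R and D on the pseudo-unlabeled pool
   (defaults: Adam, learning rate $10^{-5}$, mini-batch 3, 300 epochs,
   dropout 0.01), alternating one D step and one R step per mini-batch. The
   best (lowest generator loss) epoch is kept.
2. **Joint co-optimization** (defaults: Adam, learning rate $10^{-4}$,
   mini-batch 3, 80 epochs): each step draws one labeled and one
   pseudo-unlabeled mini-batch from independently reshuffled streams. R runs
   on the unlabeled batch (giving $\ell_r$); R's encoder also runs on the
   labeled batch, and T adds the mapped feature onto S's bottleneck before
   decoding (giving $\ell_s$). S, T and R update on $\ell_{mix}$ (R can be
   frozen with `freeze_recon`), then D takes its own step. Per-epoch steps
   are `ceiling(n_labeled / batch)`; the unlabeled stream wraps around.

The monitor is validation Dice on a held-out fraction (default 0.2) of the
labeled set, evaluated each epoch with hard (argmax) masks; the returned
checkpoint is the maximum-validation-Dice epoch, ties broken toward the
earlier epoch, with early stopping after a patience of epochs without
improvement. If no validation records exist the final epoch is kept.

Determinism: every stochastic element (initialisation, shuffling, dropout,
phantom sampling) draws from R's RNG, seeded from the config seed with
fixed, salted derivations. Two runs with the same configuration are
bit-identical on the same machine with single-threaded BLAS; across BLAS
builds bit-level equality is not guaranteed.

## The phantom generator

Real acute-stroke perfusion MRI is not redistributable, so the package
ships a generator whose *structure* matches the study data: per case a
2-D multi-modal slice (default 6 channels emulating DWI / CBV / Tmax /
CBF / T2 / TTP — the 6-channel input stack the method consumes), 2 mm
isotropic spacing, a dark elliptical infarct core inside a brain ellipse,
and a penumbra annulus around the core as the segmentation target; default
cohort size 30, matching the training cohort size the method was designed
around. Channel contrasts are fixed per region: the diffusion-like channel
has the darkest core, a designated perfusion channel carries the strongest
penumbra contrast, remaining channels get moderate, channel-dependent
offsets. Gaussian intensity noise (sd 0.05 by default, on the [−1, 1]
intensity scale) is added and values are clipped to [−1, 1] to match the
reconstructor's Tanh range. The penumbra annulus is augmented with the
core's 8-neighbourhood so the ring always fully encloses the core, also for
strongly eccentric ellipses.

What the phantoms deliberately do **not** model: MR physics (bias fields,
coil profiles), registration artifacts, anatomy, 3-D continuity, lesion
texture, or ambiguous boundaries. Passing the phantom benchmark therefore
shows that the training machinery works and that unlabeled data does not
harm (and labels help) under controlled conditions — it does not certify
clinical performance.

## Evaluation metrics

The challenge triplet, computed per 2-D slice in physical units:

* **DC**: $2|X \cap Y| / (|X| + |Y|)$; both-empty pairs count as 1
  (flagged).
* **HD** (mm): exact symmetric Hausdorff distance between boundary point
  sets (not the HD95 variant).
* **ASSD** (mm): symmetric mean of nearest-boundary distances.

A *surface pixel* is a foreground pixel with a background pixel among its
8-neighbours; the image border counts as background. This convention is
stated explicitly because surface definitions differ between evaluators.
Empty masks make the surface distances undefined: such cases return `NA`
with a warning and are excluded from HD/ASSD aggregates while still
counting toward DC. Aggregates report mean and sample standard deviation
(n − 1).

## Desk-scale study sizes

The shipped benchmark (`run_benchmark_suite()`) runs on a single CPU:
200 training and 50 test phantom slices of 64 × 64 pixels with 6 channels,
label fractions 10/20/50/100%, validation split 0.2, mini-batch 3, λ = 0.2
versus the λ = 0 supervised baseline, 10 joint epochs, three replicate
seeds. At this scale the networks use `base_width = 4`, one residual block
per stage, 2 pretraining epochs and an early-stopping patience of 3 epochs
(`desk_train_config()`), and both learning rates are raised to $10^{-3}$: with only a few hundred Adam steps,
the published rates of $10^{-5}$–$10^{-4}$ — appropriate for tens of
thousands of GPU steps — would leave the networks essentially at their
initialisation, so the rate is scaled inversely with the step budget. These
are the package's declared desk-scale study conditions; they were chosen
once, a priori, as the smallest sizes at which the segmenter visibly learns
the phantom task.

## Numerical choices

* BatchNorm: ε = 10⁻⁵, running-statistics momentum 0.1, biased batch
  variance; batch size 3 follows the training regime, and BN statistics are
  unstable at batch size 1 (documented, not special-cased).
* Initialisation: He-scaled Gaussians for convolutions and FC layers,
  BN γ = 1, β = 0. R and S draw from one seeded stream in a fixed order, so
  their encoders share shapes but not values.
* Tanh outputs are nudged into the open interval by 10⁻¹² where double
  precision rounds to ±1 (the gradient there is zero anyway).
* Dropout (rate 0.01) sits after each decoder stage; the placement is a
  declared choice.
* Argmax ties in prediction go to the background class.
* Labeled-count rounding is round-half-up, reproducing the canonical
  3/6/15/24/30 counts on a 30-case cohort; the validation carve-out rounds
  the same way.
* The Adam moment parameters stay at (0.9, 0.999); only learning rates are
  exposed.

## Known limitations

* 2-D slices only; volumetric (3-D) networks and volume-level evaluation
  are out of scope.
* The discriminator is deliberately small; with very small unlabeled pools
  it can dominate early (generator cross-entropy grows while MSE falls),
  which the mixed loss tolerates but a larger `adv_weight` would not.
* Bit-exact reproducibility holds per BLAS build, not across builds.
* The phantom benchmark is a mechanism check, not a clinical claim.
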