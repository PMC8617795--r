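---
title: "Methods: kernel-enhanced segmentation networks and their interpretability measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-enhanced segmentation networks and their interpretability measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its numerical
choices, and the limits of what its tests demonstrate.

## 1. The segmentation model

A network maps a grayscale image $I \in \mathbb{R}^{R \times C}$ to a
prediction mask $\hat M = \varphi_L \circ \dots \circ \varphi_1(I) \in
[0,1]^{R \times C}$, each $\varphi_l$ a convolution plus bias and ReLU,
with a sigmoid at the output (binary segmentation: background vs nerve).
Three encoder–decoder realizations are provided:

* **FCN** — a VGG-style convolutional encoder (two 3×3 convolutions and a
  2×2 max pooling per stage, filters doubling from `base_filters`); the
  coarse grid passes through a 1×1 score convolution and a chain of
  learnable 2× transposed convolutions back to input resolution. An
  optional skip-refined variant (`fcn_skips`) adds intermediate pool
  scores, in the FCN-8s spirit.
* **U-net** — the symmetric encoder–decoder; each decoder stage upsamples
  by a 2×2 transposed convolution, concatenates the same-resolution
  encoder features, and applies two convolutions.
* **ResUnet** — the same U shape with each two-convolution block replaced
  by a residual block $F \mapsto \phi(F) + F$, where
  $\phi(F) = W_2 \otimes \mathrm{ReLU}(W_1 \otimes F + b_1) + b_2$ and a
  1×1 projection aligns channels when they differ. The block applies no
  activation after the sum, so zero transform weights give an exact
  identity — a property the tests exercise directly.

Training minimizes the Dice-based loss $1 - s(M, \hat M)$ with
$s = (2\sum M \odot \hat M + \epsilon)/(\sum M + \sum \hat M + \epsilon)$,
$\epsilon = 1$. The Dice coefficient itself is a similarity; minimizing
one minus it keeps the loss non-negative and zero at perfect overlap,
and $\epsilon$ makes the empty-vs-empty case a loss of zero rather
than 0/0. Optimization is mini-batch Adam (default learning rate
$10^{-3}$, batch 32 — the settings used for the nerve-ultrasound
experiments this package models; $10^{-4}$ is the documented alternative
for noisier data). The best-validation-loss weights are retained.

Exact filter counts and kernel sizes inside each stage are defaults
(3×3 kernels, 2×2 pooling, `base_filters` doubling per stage), all
configurable; the architecture family fixes the topology, not the widths.

## 2. The random Fourier features layer

For the Gaussian kernel $\kappa(x,x') = \exp(-\lVert x-x'\rVert^2 /
2\sigma^2)$, Bochner's theorem gives
$\kappa(x - x') = E_\omega\{\zeta_\omega(x)\zeta_\omega(x')^*\}$ with
$\omega$ drawn from the kernel's spectral density. The real feature map

$$\hat\varphi(x) = \sqrt{2/Q}\,\big[\cos(\omega_q^\top x + b_q)\big]_{q=1}^{Q},
\qquad \omega_q \sim \mathcal N(0, \sigma^{-2} I),\; b_q \sim U[0, 2\pi)$$

satisfies $E\{\hat\varphi(x)^\top\hat\varphi(x')\} = \kappa(x-x')$ with
Monte-Carlo variance $\propto 1/Q$. Note the spectral standard deviation
is $1/\sigma$: that is the Fourier transform of the stated kernel. (A
common typographic slip writes $\mathcal N(0, \sigma^2 I)$; we follow the
kernel, and the sampler's variance is unit-tested against it.)

The layer applies $\hat\varphi$ **independently at each spatial position**
of the bottleneck feature grid — a 1×1-convolution pattern — so the
`8×8×D` bottleneck of a 128×128/depth-4 model becomes an image-shaped
`8×8×Q̆` grid. Flattening the whole grid into one vector would destroy
that square form and is deliberately not offered. Placement follows the
cost argument $O(Q'P')$: the layer sits where the feature count is
smallest — after the last pooling in FCN, at the bottleneck end in U-net
and ResUnet.

Choices where the design was genuinely open:

* **$\omega, b$ are fixed at initialization** (classical RFF). A
  `rff_trainable` flag exposes the deep-kernel variant in which they
  receive Adam updates; the default keeps the kernel interpretation
  clean.
* **Bandwidth $\sigma$** defaults to the median heuristic: the median
  pairwise Euclidean distance between bottleneck feature vectors of a
  warm-up batch (8 training images), computed once before training.
  This adapts $\sigma$ to the scale of the learned features;
  `rff_sigma` overrides it.
* **$Q$ means channels per position** (`Q_factor`, grid
  {8, 16, 32, 64, 128}), not $8 \cdot 8 \cdot Q̆$ features for the whole
  grid — the per-position reading is the only one consistent with an
  image-shaped output.

## 3. Grad-CAM++ for segmentation

The class-conditional score for label $\lambda \in \{0,1\}$ is the mean
pre-activation logit over that class's pixels,
$y(\lambda) = E\{G_{ij} : M_{ij} = \lambda\}$, taken against the
ground-truth mask when available and the binarized prediction otherwise.
Backpropagating $y(\lambda)$ to the explained layer $l$ (default: the
convolutional block immediately before the RFF insertion, or the
bottleneck end without RFF) gives $g = \partial y / \partial F_l^d$.
The channel weights are

$$\gamma_d = \textstyle\sum_{ij} \alpha_{ij}\,\mathrm{ReLU}(g_{ij}),
\qquad
\alpha_{ij} = \frac{g_{ij}^2}{2 g_{ij}^2 + (\sum_{ab} F_{ab})\, g_{ij}^3},$$

the standard Grad-CAM++ closed form, obtained by expressing the second
and third derivatives of an exponentiated score through powers of the
first-order gradient. Cells with zero denominator receive $\alpha = 0$
(no feature, no credit). The saliency map is
$S = (\mu \circ \mathrm{ReLU}) \sum_d \gamma_d F_l^d$ with $\mu$ bilinear
upsampling (the upsampling operator is otherwise unconstrained;
bilinear is the conventional choice), and
$\tilde S = S / \max S$, with an all-zero map returned unchanged.

The closed form is validated two ways: an `exact = TRUE` path evaluates
the exponential-score derivatives explicitly, and the test suite computes
second and third derivatives of $Y = e^{S}$ by Richardson-extrapolated
finite differences on a two-layer toy network — a route sharing no code
with the closed form — and requires agreement to $10^{-5}$.

## 4. Relevance measures

The explanation map $\tilde I(\lambda) = \tilde S(\lambda) \odot I$ feeds
the network up to the (linear-activation) logits, giving
$\tilde y(\lambda)$. **Increase Confidence** is the percentage of test
images with $\tilde y > y$; **Win**$(r, r')$ the percentage where model
$r$'s $\tilde y$ strictly exceeds model $r'$'s, images paired by id.
Both use strict inequality, so ties count for neither side and the
complement identity $\mathrm{Win}(r,r') = 100 - \mathrm{Win}(r',r)$ holds
exactly only in the tie-free case — a model compared against itself
scores 0 both ways rather than 50. Increase Confidence defaults to
$\lambda = 1$ (the nerve), with the label exposed as an argument.

Region-averaged heatmaps crop each normalized map to its mask's bounding
box, rescale to a common 64×64 canvas (bilinear; size configurable), and
take the pixel-wise **median** across samples, which resists outlier
maps. Empty-mask samples are skipped with a warning.

## 5. The synthetic ultrasound generator

The generator emulates, per image: a single nerve of irregular elliptical
cross-section (random semi-major axis, eccentricity, orientation and
center) rendered as a darker core with a 1–2 px hyperechoic rim; a
uniform tissue background; a linear top-to-bottom attenuation ramp of
relative magnitude `attenuation_strength`; and multiplicative unit-mean
gamma speckle, all clipped to [0, 1]. Defaults: 128×128 canvas (so four
2× poolings reach the 8×8 bottleneck), radius 12–24 px, eccentricity
0.3–0.8, background/interior/rim intensities 0.25/0.55/0.85,
`speckle_shape = 4` — giving a point signal-to-noise ratio of
$\sqrt{4} = 2$, close to the Rayleigh statistics of fully developed
speckle — and attenuation 0.3. Datasets split 70/10/20
(train/validation/test) by a seeded permutation, with per-image seeds
derived from the dataset seed, so everything is bit-reproducible.

What it does **not** emulate: acoustic shadowing, reverberation and
anisotropy artifacts, multiple or adjacent structures (vessels, fascia),
the honeycomb fascicular texture of real nerves, shift-variant speckle
statistics, and annotation noise. Passing tests on this generator
demonstrate that the architectures, losses, metrics and explanation
machinery are implemented correctly and that training converges on a
controlled task; they do not certify clinical-grade performance on real
ultrasound, which the real datasets (readable through the same PNG/TIFF
pair interface) would be needed to assess.

## 6. Numerical choices and problem sizes

* Weight initialization: He-style normal, $\mathrm{sd} = \sqrt{2/\mathrm{fan_{in}}}$,
  seeded; identical seeds give bit-identical models.
* Binarization threshold 0.5 for the overlap metrics; AUC uses the raw
  probabilities via the rank (trapezoidal) form, ties contributing half.
* Per-image metrics with zero denominators are reported `NA`, excluded
  from aggregation, and counted, rather than zero-filled.
* Max-pooling ties take the first maximum in column order; 0/0 cells in
  $\alpha$ become 0; the all-zero saliency map normalizes to itself.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* The worked experiments use 200 images at 64×64 with a depth-2,
  8-filter RFF-U-net (Q̆ = 16) trained 30 epochs — sizes chosen so the
  full pipeline (training, evaluation, saliency, relevance) runs in a
  few minutes on a single CPU while leaving the default 128×128/depth-4
  configuration available for larger studies.

## 7. Known limitations

* The engine is CPU-only and single-threaded apart from BLAS; it is
  meant for method study and testing, not large-scale training.
* Binary segmentation only; the multiclass (softmax) head is out of
  scope.
* The FCN connects its (RFF-mapped) coarse features directly to the
  score/upsampling head; whether further convolutions should intervene
  is left open by the architecture family, and the direct connection is
  the simpler reading.
* Checkpoints are R serializations (RDS); they are runtime artifacts,
  not an interchange format.
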