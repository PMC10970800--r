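---
title: "Methods: residual-in-residual super-resolution for grayscale radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual-in-residual super-resolution for grayscale radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rirsr)
```

## The problem

Clinical radiographs are often acquired, stored or transmitted at reduced
resolution. Single-image super-resolution (SISR) reconstructs a
high-resolution (HR) image $I_{HR}$ from a low-resolution (LR) observation
$I_{LR}$, where the forward model is known: antialiased bicubic
downsampling by a power-of-two factor $\alpha \in \{2, 4, 8\}$, optionally
followed by salt-and-pepper impulse noise on the LR image at density $d
\in \{0.005, 0.01, 0.02\}$. The package implements a convolutional network
for this inverse problem, the exact forward model used to synthesize
training data, the PSNR/SSIM/multi-scale similarity metric suite used to
score reconstructions against a bicubic-interpolation baseline, a seeded
phantom generator so that the entire pipeline runs self-contained, and an
ablation driver over the residual-block design choices.

## The network

The model is a residual-in-residual (RIR) trunk between a shallow feature
extractor and a sub-pixel upscaler:

* **Shallow features.** One $3\times3$ convolution maps the single
  intensity channel to $f$ feature channels ($f = 64$ in the reference
  configuration), $N_{SF} = W_{SF}(I_{LR})$.
* **Residual blocks.** Each block processes its input with three parallel
  same-padded convolutions of kernel sizes $1\times1$, $3\times3$ and
  $5\times5$ (an inception-style multi-kernel design), each followed by a
  LeakyReLU. The three branch outputs are concatenated ($3f$ channels) and
  fused back to $f$ channels by a $1\times1$ convolution; an optional
  squeeze-excitation-style channel attention gate rescales the fused map;
  a short skip connection adds the block input; a final LeakyReLU closes
  the block. The ablation flags `use_channel_attention`,
  `use_concat_fusion` (off replaces concatenation+fusion by branch
  summation) and `use_skip` select the four block variants of the
  ablation study; the default — attention off, concatenation on, skip on —
  is the proposed model.
* **Residual groups and dense feature fusion.** A group chains
  `n_blocks` blocks; the block outputs *and* the group input are
  concatenated ($(B{+}1)f$ channels, 320 at the reference configuration)
  and fused by a $1\times1$ convolution. Groups are chained sequentially;
  the group outputs are concatenated ($Gf$ channels, 256 at reference)
  and fused by a final $1\times1$ convolution, and a long skip connection
  adds the shallow features: $F_{DF} + N_{SF}$.
* **Upscaler.** A $3\times3$ convolution expands $f \to \alpha^2 f$
  channels, a pixel shuffler rearranges $(h, w, \alpha^2 f)$ into
  $(\alpha h, \alpha w, f)$ — the standard sub-pixel contract — and a
  final $3\times3$ convolution produces the single-channel HR image. For
  $\alpha = 8$ the default is the single-stage $\alpha^2 f$ expansion;
  cascaded $\times2$ stages are exposed via `upscale_mode = "cascade"`.

There is no batch normalization anywhere: its train/inference discrepancy
is a known liability for super-resolution regression, and the residual
structure plus the initialization below make it unnecessary.

All forward and backward passes are written explicitly in R over
RcppArmadillo im2col/GEMM convolution kernels; there is no autodiff
framework underneath. Analytic gradients are verified against central
finite differences in the test suite for every block variant.

## Initialization

The scheme matters more than usual here because desk-scale training runs
are short (hundreds of Adam steps, see below) and Adam's per-step
parameter movement is bounded by the learning rate:

* He-style fan-in scaling with the gain matched to the layer's role:
  $\sqrt{2/(1+s^2)}$ (LeakyReLU slope $s$) for branch convolutions that
  feed an activation, unit gain for the purely linear fusion layers —
  plain He gain on linear layers compounds a $\times 2$ variance per
  fusion stage, roughly $\times 64$ across the network.
* Residual branches start scaled by $0.1$ and the trunk fusion and output
  perturbations by $0.01$, so every block and the trunk start near the
  identity — the standard batchnorm-free stabilization for deep residual
  image-restoration trunks.
* Feature channel 1 carries an identity tap from the input, and the
  pre-shuffle convolution starts as a depthwise sub-pixel interpolator:
  for shuffle phase $(d_r, d_c)$ the HR site's center lies at LR offset
  $u = (d + 0.5)/\alpha - 0.5$, and the $3$-tap Lagrange (quadratic)
  weights $\left(\frac{u(u-1)}{2},\ 1-u^2,\ \frac{u(u+1)}{2}\right)$
  per axis are exact on locally quadratic intensity profiles. Channels
  beyond the first add an ICNR-style random component (one base filter
  bank shared across all $\alpha^2$ shuffle positions, so the start is
  checkerboard-free). The untrained network therefore implements a
  classical interpolation operator that training refines — the
  deconvolution-as-interpolation initialization long used for upsampling
  layers — rather than having to rediscover upsampling from random
  weights.

## Degradation model

`bicubic_resize()` reimplements the MATLAB-style `imresize` convention:
separable resampling with the Keys cubic kernel ($a = -0.5$), kernel
support widened by $1/\mathrm{scale}$ on antialiased shrink, symmetric
boundary handling, per-site weight normalization, output clipped to
$[0, 255]$. Identity at scale 1 and constancy on constant images are
exact. Salt-and-pepper corruption flips each pixel independently with
probability $d$ to 0 or 255 with equal probability; noise is always
applied to the LR image after downsampling, never to the HR ground truth.
`extract_patch_pairs()` enumerates LR patch origins at a given stride and
returns aligned $p \times p$ LR / $\alpha p \times \alpha p$ HR pairs; if
the enumeration exceeds `max_pairs` (default 102,400, the reference
training-set size) a seeded uniform subsample is returned — stride-1
enumeration over realistic training sets produces far more than the fixed
reference count, so subsampling reconciles the two.

## Training recipe

`train_sr()` minimizes the mean absolute (L1) difference between network
output and HR ground truth with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), batch size 32, seeded reshuffling each epoch, last
incomplete batch dropped. Patches are scaled to $[0, 1]$ for optimization
(the recorded history converts the loss back to 0–255 intensity units).
The default schedule is the reference recipe: initial rate $2\times
10^{-4}$ decayed by $0.1$ every 120 epochs, i.e. piecewise-constant with
breaks exactly at multiples of 120.

**Desk-scale rate.** The reference recipe's epochs contain ~3,200 updates
(102,400 patches at batch 32). The package's self-contained experiments
train on ~512 phantom patch pairs — 16 updates per epoch, a ~200-fold
smaller step budget over the same 30 epochs — and Adam's per-step movement
is bounded by the rate, so the full-scale rate cannot traverse weight
space in so few steps. The desk-scale experiments (the end-to-end test
suites and `scripts/acceptance.R`) therefore use $10^{-3}$, keeping the
schedule's shape and every other constant unchanged; the package defaults
remain the reference values.

## Metrics

On the 0–255 scale: MSE; PSNR $= 10\log_{10}(255^2/\mathrm{MSE})$ with
`Inf` as the sentinel for identical images; SSIM with local statistics
from an $11\times11$ Gaussian window ($\sigma = 1.5$; a uniform
$8\times8$ window is exposed as an option) evaluated at every valid
window position, stabilizers $C_1 = (0.01 \cdot 255)^2$ and
$C_2 = (0.03 \cdot 255)^2$; and a multi-scale similarity defined as the
weighted geometric combination $\left(\prod_i \mathrm{SSIM}_i^{\alpha_i}
\right)^{1/N}$ over $N$ dyadic scales (2×2 mean pooling between scales),
defaults $N = 5$ with unit weights. Note this multi-scale form carries an
outer $1/N$ power absent from the common MS-SSIM convention, so it is
implemented with its own parameters rather than borrowing the usual
per-scale weights; higher values indicate better reconstruction, the
orientation used when comparing methods. Metrics are computed on the full
image with no border crop. `evaluate_sr()` runs the paired protocol —
degrade each held-out HR, super-resolve the LR, score against the clean
HR — and reports the bicubic-upscaling baseline on the exact same LR
inputs, which is model-independent by construction.

## The phantom generator

Tests and experiments run on seeded synthetic radiograph-like phantoms,
not clinical data. A phantom composes: a constant base plus three broad
Gaussian bumps (smooth low-frequency anatomy, which dominates radiograph
spectra); a thorax-like elliptical region with a *sharp* boundary;
`n_bands` rib-like periodic bands with a tanh-sharpened (quasi-square)
profile, gently warped across the image; `n_blobs` small bright Gaussian
spots (lesion-like, peak ~40 intensity units); and zero-mean Gaussian
fine texture (`texture_sigma`, default 2). Everything is clipped to
$[0, 255]$ and kept in floating point until PNG write time, so
quantization happens exactly once.

The sharp ellipse boundary and quasi-square bands are deliberate: real
radiographs are full of crisp anatomical edges, and sharp edges are
precisely the content plain interpolation cannot recover — a phantom whose
only high-frequency energy is white noise would make the
interpolation baseline unbeatable in principle (unlearnable noise sets
the same PSNR ceiling for every method) and would test nothing about
reconstruction. Conversely, the white-texture component *is* unlearnable
by any translation-equivariant model and bounds attainable PSNR near
$10\log_{10}(255^2/\sigma^2)$; it is kept small but nonzero so that
scores stay in a realistic range.

What passing these tests does **not** show: anatomical realism, scanner
noise models (Poisson, blur kernels), pathology, or any claim about
downstream diagnostic utility. The phantoms emulate second-order image
statistics only.

## Problem sizes

The self-contained experiments use: tiny architectures (1–2 groups, 1–2
blocks, 8–16 filters) for training runs; ~512 patch pairs (16×16 LR →
64×64 HR at $\times4$) drawn from 8 phantoms of 256×256; 30 epochs; 20
held-out phantoms for paired evaluation; 10 independent seeds for the
learning-signal experiment; and 3 dyadic scales for the multi-scale
metric at these image sizes. These sizes were chosen so a complete run is
a matter of minutes on a single core while still exercising every stage
at realistic statistics; the reference configuration (4×4 blocks, 64
filters, 102,400 patches) is what the defaults describe and is what a
user would train on real radiograph collections.

## Numerical choices

* Convolution GEMMs run in float32 by default (`precision = "single"`,
  the standard deep-learning arithmetic); `precision = "double"` is used
  by the finite-difference gradient tests. All user-visible arrays are
  doubles either way, and both paths are deterministic given the seeds.
* Convolutions zero-pad; the resize operator reflects. Zero padding is
  the common choice for SR trunks; the resize convention follows the
  routine it reimplements.
* LeakyReLU slope 0.2 everywhere (exposed in the configuration); at
  exactly zero pre-activation the derivative convention is the slope.
* Outputs are clipped to $[0, 255]$ only at the user-facing surface
  (`sr_forward()`, PNG write); internal feature maps are unclipped.
* Checkpoints are plain text (config key/values plus every named tensor
  at 17 significant digits), which round-trips IEEE doubles exactly:
  reloaded models reproduce forward outputs bit for bit.
* Degenerate inputs are rejected with explicit messages: non-divisible
  image sizes, out-of-range densities, patches larger than the LR image,
  images smaller than the SSIM window, channel mismatches.

## Known limitations

* No GPU path and no autodiff: the architecture is fixed to the family
  described here; adding layer types means writing their backward passes.
* The multi-scale similarity follows the literal weighted-geometric-mean
  definition above; values are not numerically comparable to MS-SSIM
  implementations that use the conventional per-scale exponents.
* Negative per-window SSIM values raised to fractional weights would be
  undefined; this does not arise for the image pairs produced by this
  pipeline but is not guarded against for adversarial inputs.
* Training is practical up to the reference configuration on CPU but
  slow; the package is a faithful, testable implementation, not a
  performance-tuned training system.
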