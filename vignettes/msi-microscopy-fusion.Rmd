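---
title: "Methods: edge-loss-controlled fusion of MSI ion images with microscopy"
author: "msifuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-loss-controlled fusion of MSI ion images with microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifuse)
```

## The problem

Mass spectrometry imaging (MSI) of plant tissue trades molecular coverage
against spatial resolution: a MALDI raster at 12–20 µm pitch resolves the
chemistry but not the morphology — epidermis layers, vascular bundles and
scattered parenchymal cells are all smaller than, or comparable to, one MSI
pixel.  A co-registered brightfield microscopy image of the same section
resolves the morphology at micron scale but carries no chemical contrast.
`msifuse` fuses the two: it fits a small convolutional network to a *single*
registered image pair and reads the network output as a super-resolved
chemical image on the microscopy pixel grid, at integer magnifications up to
20-fold.

Because curated high-resolution ground-truth MSI does not exist for plant
tissue, no transferable model is trained.  The network is fitted per image
pair, self-supervised, and discarded; what transfers is the procedure, not
the weights.

## Model

Let $X \in [0,1]^{H \times W \times 3}$ be the registered microscopy image
and $\hat y \in [0,1]^{H \times W}$ the bilinear magnification of the native
ion image to the same grid.  The network $f_\theta$ maps $X$ to a
single-channel output $y = f_\theta(X)$, and is trained under

$$
L \;=\; w_1 \, L_\mathrm{MSE} \;+\; w_2 \, L_\mathrm{edge},
\qquad
L_\mathrm{MSE} = \tfrac1N \sum_i (y_i - \hat y_i)^2,
\qquad
L_\mathrm{edge} = \tfrac1M \sum_i \big( (K \!\ast\! y)_i - (K \!\ast\! \Lambda(X))_i \big)^2,
$$

where $K$ is a designated $3 \times 3$ edge-extraction kernel,
$\Lambda(X)$ is the Rec. 601 luminance of the microscopy image, and both
convolutions are same-size with replicate padding, so $M = N = HW$.  The
MSE term anchors the output to the chemical intensity distribution; the
edge term penalizes departures of the output's edge map from the tissue's
morphological edges.  The two terms pull in different directions at
different rates, which is exactly what the early-stopping rule (below)
exploits.

### Architecture

`build_network()` constructs one initialization block — a $3\times3$
convolution $3 \to 64$ followed by ReLU — and two residual blocks with the
channel plan $64 \to 32 \to 1$.  Each residual block runs two $3\times3$
convolutions (in $\to$ out with ReLU between, then out $\to$ out) in
parallel with a $1\times1$ convolution skip from the block input, and sums
the two paths.  All convolutions preserve the spatial size.  Design
points that were genuinely open, and how they were settled:

* **Within-block widths.**  Only the block-boundary channel counts are
  fixed by the channel plan; the width of each block's second convolution
  is set to the block's *output* width (so $64\to32,32$ and $32\to1,1$) —
  the smallest architecture consistent with the plan.
* **Output head.**  The first block's sum passes through ReLU; the final
  block's sum is linear.  A terminal ReLU would clamp every negative
  pre-activation to zero at initialization and stall early training on
  min-max-normalized targets; instead the raw output stays unbounded and is
  clipped to $[0,1]$ only on export.
* **Padding.**  Replicate (edge) padding everywhere, including inside the
  loss convolution.  Zero padding would manufacture a bright rim of phantom
  edges at the borders that the edge loss would then chase.
* **Full-image batches.**  One sample, no patching: the fit is to one
  registered pair of modest size, so patch sampling would only add a
  stochastic term to an otherwise deterministic optimization.

`build_cnn_baseline()` provides the minimal comparison method — three
$3\times3$ convolutions $3 \to 64 \to 32 \to 1$ with ReLUs and no skips —
which is typically trained with weights $(1, 0)$, i.e. MSE only.

### Edge kernel

The edge-extraction kernel is deliberately a *single* $3\times3$
convolution, applied as written (no kernel flip; the default is symmetric
anyway).  The default is the 4-neighbor Laplacian
$\bigl[\begin{smallmatrix}0&-1&0\\-1&4&-1\\0&-1&0\end{smallmatrix}\bigr]$ —
the canonical one-kernel edge extractor, zero-sum so that constant regions
carry no edge signal under replicate padding.  `laplacian8`, `sobel_x`,
`sobel_y` and arbitrary $3\times3$ matrices are selectable; a Sobel
*magnitude* map was considered and rejected because it needs two
convolutions and a nonlinearity, changing the loss definition away from a
single convolution.  The comparison target is the microscopy *luminance*:
the output is single-channel, so a 1-vs-3-channel comparison needs a
reduction, and Rec. 601 luminance is the least arbitrary one.

### Normalization and interpolation

Both modalities are min-max normalized to $[0,1]$ per image
(`minmax_normalize()`, constant grids map to zero, the original extrema are
recorded for back-scaling).  Whether intensities should be normalized
before the MSE term is a genuine choice; sharing one scale across the two
loss terms mitigates the order-of-magnitude disparity that otherwise makes
one term obsolete, so normalization is applied and documented rather than
left implicit.  The ion image is magnified with bilinear interpolation in
the half-pixel-center convention (`upscale_bilinear()`, output pixel $i$
samples source coordinate $(i+0.5)/m - 0.5$, clamped) — the dialect of the
common image-library linear resize, pinned by a scalar oracle in the tests.
Registration itself is out of scope (done externally with manual landmark
tools); `validate_registration()` enforces its output contract — microscopy
shape must equal ion shape times the magnification *exactly*, with no
silent crop or pad, because published acquisition geometries show that
silent mismatch is a real hazard.

## Training and early stopping

`train_fusion()` runs full-batch Adam (default moments 0.9/0.999, eps
1e-8) at learning rate 3e-4 with an epoch cap of 2000 — the cap is an upper
limit, not a target.  Per epoch both loss components are recorded.  Two
mechanisms use the edge loss as the proxy for visual quality:

* **Best-checkpoint retention.**  The returned fused image is the forward
  pass of the epoch with *minimal edge loss*, never the final epoch.  The
  total loss keeps falling long after the output has started to acquire
  fuzzy artifacts; the edge loss tracks the artifact onset.
* **Early stopping.**  Every epoch whose edge loss fails to improve on its
  running minimum increments a cumulative counter (a plateau counts as a
  failure; the counter is *never reset*), and training halts when the
  counter reaches the patience, default 5.  The cumulative reading — "total
  counts of loss increase" rather than consecutive epochs — is robust to
  the oscillation the edge loss shows near its floor.

With weights $(1, 0)$ the edge loss is still computed and recorded every
epoch (and still drives early stopping and best-checkpoint selection), but
its gradient is never evaluated — the tests verify the parameter trajectory
is bit-identical to an MSE-only loop.  Training with both weights zero is
rejected.  Default weights are $(1, 1)$: on normalized inputs the two terms
are commensurate, and early stopping, not the weighting, is the operative
control.

Checkpoints (`save_checkpoint()` / `load_checkpoint()`) carry the
parameters *after* a completed epoch, the optimizer state, the early-stop
state and the trace, plus a content checksum and the run's configuration
hash; resuming reproduces the uninterrupted trace exactly, and loading
refuses tampered files or mismatched configurations.  Determinism is
per-platform: fixed seeds give bit-identical runs on one machine, but
floating-point reduction order may differ across BLAS builds, so
cross-platform comparisons should use tolerances.

## Evaluation

`psnr()` uses data range 1 after normalization and returns `Inf` for
identical inputs.  `ssim()` is the canonical form: 11×11 Gaussian window
(σ = 1.5), $C_1 = (0.01)^2$, $C_2 = (0.03)^2$, windows evaluated where they
fit entirely inside the image.  `evaluate_checkpoints()` scores every saved
checkpoint against *both* references — PSNR/SSIM against the interpolated
ion target, edge loss against the microscopy luminance — because the two
metric families diverge over training and that divergence is the
scientifically interesting signal.  A pluggable `feature_metric()` accepts
any callable feature extractor for perceptual-style metrics; no pretrained
weights ship with the package.

## The synthetic phantom

`generate_phantom()` produces the ground-truthed test bed: a seeded Voronoi
tessellation of cell regions (default 25 cells on a 64×64 grid) assigned to
three concentric tissue classes — an epidermis-like rim, a mesophyll-like
middle zone, a vascular-like core — mimicking the radially organized
anatomy of leaf and stem cross-sections.  Cell walls (region boundaries,
1–2 px) are darkened in the microscopy channels and attenuated in the ion
truth by `wall_darkness` (default 0.6, the high-contrast walls typical of
plant sections).  Each cell's abundance is its class mean (defaults 0.25 /
0.95 / 0.5 on a 0–1 scale) with ±20 % per-cell jitter, so color predicts
abundance class but not exactly — the network must use both modalities.
The low-resolution ion image is the block mean over `magnification`-sized
tiles (an MSI pixel integrates signal over its footprint) plus Gaussian
noise (default s.d. 0.02, a few percent of full scale, typical of
normalized ion-count images) clipped at zero.

Default conditions — 64×64 truth, magnification 8, noise s.d. 0.02 — are
the package's study conditions: large enough that the three tissue zones
and a few dozen cell boundaries exist, small enough that the full test
suite trains dozens of networks.  The trainer tests use 32×32 phantoms at
magnification 4 with reduced channel widths; the acceptance checks run the
full 64/32-channel network on five 64×64 phantoms for up to 150 of the
allowed 300 epochs.

What the phantom does *not* emulate: optics (point-spread function,
chromatic effects, illumination gradients), matrix-crystal artifacts,
nonlinear registration error, Poisson counting statistics (noise is
Gaussian by choice — the simplest controllable model), and realistic mass
spectra.  Passing the phantom suite therefore demonstrates that the
machinery is correct and that fusion recovers structure *when the
microscopy is informative about the chemistry*; it does not certify fusion
quality on any particular real tissue, where that correlation is an
empirical question.

## Numerical choices and degenerate inputs

* Constant grids normalize to all zeros rather than erroring; non-finite
  values are rejected at the door.
* A repeat of the current best edge loss counts as "not improving"
  (strict `<` comparison), making the patience-1 boundary semantics
  explicit: the sequence 1, 1 halts at the second value.
* Ion extraction from imzML sums all peaks within the ppm window (default
  5 ppm) — the usual ion-image convention; pixels without spectra are zero.
* The per-pixel coordinate convention is 0-based (row, col), origin
  top-left, row-major, everywhere; imzML's 1-based x/y positions are
  shifted on read.
* Losses agree with scalar brute-force oracles to 1e-10; gradients were
  verified against finite differences during development and the gradient
  check is part of the test suite.

## Known limitations

* The edge loss tracks artifact onset but cannot detect the slowly
  concentrating fuzz of extreme over-training; the epoch cap is the
  backstop.
* Single-ion fitting only: each ion image is a separate run, matching the
  per-slice workflow; joint multi-ion training is out of scope.
* The imzML reader covers continuous/processed mode with uncompressed
  32/64-bit floats — the common export configuration — not the full
  standard; the writer is a fixture writer for tests.
* No learning-rate schedules and no multi-task loss balancing beyond fixed
  weights; the early-stopping rule is the intended control.

## A minimal run

```{r example, eval = FALSE}
tri <- generate_phantom(phantom_spec(seed = 1))
pair <- validate_registration(tri$microscopy, tri$ion_lr, magnification = 8)
net <- build_network(network_spec(), seed = 1)
fit <- train_fusion(net, pair, edge_kernel("laplacian4"),
                    train_config(max_epochs = 150, seed = 1))
truth <- minmax_normalize(tri$ion_truth_hr)
c(fused = ssim(pmin(pmax(fit$fused$values, 0), 1), truth),
  bilinear = ssim(pair$ion_interp, truth))
```

The same pipeline runs from the shell via the script in
`inst/cli/msifuse.R` (`simulate`, `fuse`, `evaluate` subcommands), and on
real data by replacing the phantom with `read_imzml()` /
`extract_ion_image()` (or `read_ion_csv()`) and `read_microscopy()`.
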