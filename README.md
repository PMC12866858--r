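# msifuse

Super-resolution fusion of mass spectrometry imaging (MSI) ion images with
co-registered microscopy, for plant-tissue sections.

MALDI MSI maps the chemistry of a tissue section at 12–20 µm pixel pitch —
too coarse to resolve epidermis layers, vascular bundles, or individual
cells.  A registered brightfield microscopy image of the same section has
micron-scale morphology but no chemical contrast.  `msifuse` combines the
two: a small residual convolutional network is fitted to **one** registered
image pair (no training corpus, no pretrained weights) and its output is a
fused chemical image on the microscopy grid, at integer magnifications of
the MSI raster up to 20× (e.g. a 135 × 49 ion image at 20 µm pitch becomes
a 2700 × 980 fused image at 1 µm).

## Method

With microscopy `X` (H × W × 3, in [0,1]) and the bilinearly magnified ion
image `ŷ` (H × W, in [0,1]), the network output `y = f_θ(X)` is trained
under the weighted additive loss

    L = w₁ · L_MSE + w₂ · L_edge
    L_MSE  = 1/N Σᵢ (yᵢ − ŷᵢ)²
    L_edge = 1/M Σᵢ ((K ∗ y)ᵢ − (K ∗ Λ(X))ᵢ)²

where `K` is a designated 3 × 3 edge-extraction kernel (default: 4-neighbor
Laplacian), `Λ(X)` the Rec. 601 luminance of the microscopy, and both
convolutions are same-size with replicate padding.  The MSE term anchors
the chemistry; the **edge perceptual loss** preserves the morphology.
Because the two terms converge at different rates, training is controlled
by the edge loss: the best checkpoint is the epoch with minimal edge loss,
and training halts early once the edge loss has failed to improve on its
running minimum a fixed total number of times (default 5).

The network is an initialization block (3×3 conv, 3→64, ReLU) followed by
two residual blocks (channels 64→32→1), each with two 3×3 convolutions in
parallel with a 1×1 convolution skip.  Optimization is full-batch Adam
(lr 3e-4, epoch cap 2000).  A plain three-layer CNN baseline
(`build_cnn_baseline()`) is included for comparison.  Forward and backward
passes are implemented in the package (C++/RcppArmadillo); there is no
deep-learning framework dependency.

A seeded synthetic phantom generator (`generate_phantom()`) produces
Voronoi-cell "tissue" with dark cell walls, a ground-truth high-resolution
ion map correlated with tissue class, and its block-downsampled noisy ion
image — so the whole pipeline is testable against known ground truth.

## Worked example

```r
library(msifuse)

tri  <- generate_phantom(phantom_spec(seed = 1))        # 64x64 truth, 8x, noise 0.02
pair <- validate_registration(tri$microscopy, tri$ion_lr, magnification = 8)
net  <- build_network(network_spec(), seed = 1)
fit  <- train_fusion(net, pair, edge_kernel("laplacian4"),
                     train_config(max_epochs = 150, seed = 1))

truth <- minmax_normalize(tri$ion_truth_hr)
ssim(pmin(pmax(fit$fused$values, 0), 1), truth)  # fused vs ground truth
#> [1] 0.6609
ssim(pair$ion_interp, truth)                     # bilinear baseline
#> [1] 0.2385
```

The fused image recovers the cell-scale structure (SSIM 0.66 against the
ground truth) that plain bilinear magnification of the noisy low-resolution
ion image cannot (SSIM 0.24).  `fit$trace` holds the per-epoch MSE, edge
and total losses plus the early-stopping counter; `write_fused()` exports a
16-bit TIFF with a lossless float sidecar.

On real data, replace the phantom with `read_imzml()` +
`extract_ion_image()` (or `read_ion_csv()` for grids exported from MSI
preprocessing tools) and `read_microscopy()` for the registered optical
image; registration itself is done externally (e.g. BigWarp) and
`validate_registration()` enforces the exact-magnification contract on its
output.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/msifuse.R", package="msifuse"))')
Rscript $CLI simulate --seed 7 --out run/            # write a phantom triplet
Rscript $CLI fuse --microscopy run/microscopy.tiff \
                  --ion run/ion_lr.csv --magnification 8 \
                  --checkpoints --out run/
Rscript $CLI evaluate --microscopy run/microscopy.tiff \
                  --ion run/ion_lr.csv --magnification 8 \
                  --truth run/ion_truth_hr.csv --out run/
```

All run artifacts embed a configuration hash; `evaluate` refuses
checkpoints from mixed configurations.

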