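# gridreg

Learning-based 3D deformable image registration on a **sparse grid of
control points**, for researchers who register medical volumes (e.g.
longitudinal prostate MR, inter-subject pelvic or brain MR) and want
compact, fold-free deformations with an explicit handle on the
transformation's degrees of freedom.

## The idea

Instead of decoding a displacement vector at every voxel, the network
predicts displacements only at the nodes of a corner-aligned control
grid of size $g_w \times g_h \times g_d$ and reconstructs the dense
field by basis interpolation

$$T^\uparrow(x, y, z) = \sum_{i,j,k} T_{ijk}\, B(x - x_i)\, B(y - y_j)\, B(z - z_k),$$

with a trilinear hat, cubic B-spline (Cox–de Boor) or renormalized
Gaussian basis. A multiscale convolutional encoder reads the
concatenated fixed/moving pair; per-level skip projections flatten the
features into fixed-length token sequences; and a cross-attention
decoder, whose queries are sinusoidal positional encodings of the
control-point coordinates, reads the tokens out per control point:

$$A^{(h)} = \mathrm{softmax}\!\left(Q^{(h)} K^{(h)\top}/\sqrt{d}\right),$$

so the trainable parameters are independent of the grid size — one
model, trained while sampling the grid from
$\{5^3, 8^3, 10^3, 15^3\}$, registers at any of them. A Bayesian head
predicts a mean and a softplus-positive variance per control point;
training optimizes a heteroscedastic (uncertainty-weighted) similarity
with Monte-Carlo reparameterized samples, a soft Dice term when masks
exist, and a bending-energy penalty. Warping follows the backward
(gather) convention `output(x) = moving(x + T(x))`.

Because the grid is coarse and displacements stay below half the
control spacing, the reconstructed fields are smooth and fold-free:
the percentage of voxels with a negative Jacobian determinant is the
package's headline regularity metric.

Everything — the network, a reverse-mode autodiff tape, compiled 3D
convolution and warping kernels, the three upsamplers, all losses and
metrics, a seeded synthetic phantom generator, and training/inference —
is self-contained in this package.

## Worked example

```r
library(gridreg)

# a synthetic pair with known ground-truth deformation on a 5^3 grid
pair <- make_pair(phantom_spec(seed = 7))

# classical route: optimize the control grid directly (no network)
fit <- fit_gdf(pair$fixed, pair$moving, grid_size = c(5, 5, 5), iters = 500)
err <- sqrt(colSums(matrix(fit$gdf$vectors - pair$truth$vectors, nrow = 3)^2))
mean(err)                     # mean control-point error, voxels
#> [1] 0.3319587

# learning route: train the grid-adaptive network on a small cohort
pairs <- lapply(1:8, function(i) make_pair(phantom_spec(seed = i)))
cfg   <- registration_config(network = small_network_config(),
                             epochs = 2, seed = 11)
ckpt  <- train(pairs, cfg)

# one checkpoint, any grid: register at 10^3 control points
res <- register_pair(ckpt, pair$fixed, pair$moving,
                     grid_size = c(10, 10, 10), pair$moving_mask)
res$jacobian
#> jacobian_stats: |logdet| 0.0011 +/- 0.0008, folding 0.000%
dice_coefficient(pair$fixed_mask, res$warped_mask)
#> [1] 0.9409971
```

`mean(err)` is the recovery error of the classical fit against the known
truth (well under one voxel); `folding 0.000%` says the predicted
deformation is invertible everywhere; the Dice value is the mask overlap
after registration.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/gridreg.R synth --out data/ --n 10 --seed 1
Rscript inst/cli/gridreg.R train --data data/ --out ckpt.rds --small --epochs 10
Rscript inst/cli/gridreg.R register --ckpt ckpt.rds --fixed f.nii.gz \
        --moving m.nii.gz --out out/case1 --grid-size 10
Rscript inst/cli/gridreg.R evaluate --pred out/ --truth data/
```

## Package tour

| Area | Functions |
|---|---|
| Geometry & warping | `make_control_grid`, `warp`, `warp_points`, `image_volume`, `read_volume` |
| Interpolation | `upsample`, `upsample_oracle`, `trilinear_basis`, `bspline_basis`, `gaussian_basis` |
| Network | `network_config`, `small_network_config`, `init_weights`, `encode`, `decode`, `cross_attention`, `bayesian_head`, `sample_transform`, `gridreg_forward` |
| Objectives | `similarity_image`, `uncertainty_loss`, `dice_loss`, `bending_energy`, `total_loss` |
| Metrics | `dice_coefficient`, `centroid_distance`, `jacobian_stats` |
| Synthetic data | `phantom_spec`, `generate_phantom`, `generate_true_deformation`, `make_pair`, `write_synth_dataset` |
| Pipeline | `train`, `select_grid`, `register_pair`, `register_files`, `evaluate`, `fit_gdf` |

The methods vignette (`vignettes/gridreg-methods.Rmd`) documents the
model, the loss conventions, the synthetic-data assumptions and every
numerically delicate choice.
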