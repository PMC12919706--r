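---
title: "Sparse-grid registration: models, objectives and design choices"
author: "gridreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-grid registration: models, objectives and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gridreg)
```

## The model

Deformable registration estimates a spatial transformation that aligns a
moving image $M$ to a fixed image $F$, both 3D scalar volumes on a voxel
domain $\Omega$ of size $W \times H \times D$. Dense, voxel-wise decoders
parameterize the transformation with $3WHD$ degrees of freedom; in
homogeneous or noisy tissue most of those degrees of freedom chase
correspondences that do not exist. `gridreg` instead predicts a
displacement vector at each node of a sparse, corner-aligned control grid
of size $g_w \times g_h \times g_d$ and reconstructs the dense
displacement field (DDF) by basis-function interpolation. The coarse grid
is an implicit regularizer: with displacement magnitudes below half the
control spacing the interpolated field cannot fold.

The network has three parts:

1. **Encoder.** The fixed and moving volumes are concatenated as a
   2-channel input to a stack of stride-2 $3^3$ convolutions with ReLU;
   channels start at `base_channels` and double per level, spatial
   dimensions halve per level.
2. **Skip projections.** Each level is resampled to a fixed
   `proj_spatial` lattice by adaptive average pooling, flattened to
   $N_p$ tokens, mapped point-wise to `proj_channels` features, and
   given sinusoidal positional information of the token centers.
3. **Cross-attention decoder.** Queries are deterministic sinusoidal
   positional encodings of the (normalized) control-point coordinates.
   Per head, $A = \mathrm{softmax}(QK^\top/\sqrt{d})$ over the tokens;
   head outputs are concatenated and projected. Because all projection
   matrices act on feature dimensions only, the trainable parameters are
   independent of the grid size — one trained model decodes any grid.

A Bayesian head emits a mean $\mu$ and raw variance $\eta$ per control
point with $\sigma^2 = \mathrm{softplus}(\eta) > 0$. Training draws $S$
Monte-Carlo transformation samples $T^{(s)} = \mu + \sigma \odot
\varepsilon^{(s)}$ (reparameterization trick); inference uses only the
mean field, so registration is deterministic.

### Decoder wiring

The per-level interaction between the token sequences and the
control-point queries is genuinely open design space. `gridreg` keeps a
*token state* $Y$ of fixed width `decoder_channels` that starts at zero
at the bottleneck; at each level, going bottom-to-top, the level's
projected tokens are concatenated with $Y$ on the feature axis, the
concatenation is (a) read out by cross-attention with the control-point
queries, accumulated into the grid features, and (b) refined token-wise
by a linear/ReLU layer into the next level's state. This satisfies all
the architectural contracts (fixed token count, per-level concatenation,
grid-size-independent weights) with one attention read-out per level.
The topmost token refinement would never be consumed, so those weights
are not created — every parameter receives gradient.

### Local versus global attention

The attention equation is a global softmax over all tokens, but the
design intent is that a control point should attend to features near it.
Both variants are exposed: `local_radius = NULL` (default) is the global
softmax as printed; a numeric radius (normalized coordinates, e.g. 0.35)
masks tokens outside the query's neighborhood before the softmax and
errors if a query would lose all its tokens.

## Field interpolation

All three upsamplers are the same tensor-product basis convolution
$T^\uparrow(x,y,z) = \sum_{ijk} T_{ijk} B(x - x_i) B(y - y_j) B(z - z_k)$
and differ only in the 1D basis:

* **trilinear** — the unit hat $\max(0, 1 - |x - x_i|/\Delta)$; exact
  partition of unity, interpolates the control values, reproduces linear
  ramps;
* **bspline** — clamped uniform B-splines by the Cox–de Boor recursion
  on the normalized axis, degree 3 (reduced when a grid axis has fewer
  than 4 points); the right endpoint is evaluated as a left limit
  because the degree-0 basis is a half-open indicator;
* **gauss_deconv** — transposed convolution with a truncated Gaussian.
  The discrete Gaussian does not sum to one on the lattice, so the
  per-voxel weights are renormalized; without this a constant grid
  displacement would acquire a global bias. Defaults
  `gauss_sigma = 0.45` control spacings and truncation at 3 sigma
  (1.35 spacings) were fixed once by minimizing the L2 distance to the
  cubic B-spline kernel on a uniform lattice.

`upsample()` evaluates the tensor product separably (three 1D passes,
exact because the product factorizes); `upsample_oracle()` is the
literal triple sum kept for verification. Both are differentiable in the
grid vectors; the package's reverse-mode tape propagates gradients
through the basis matrices by their transposes.

## Objectives

All sums over $\Omega$ are implemented as means so the weights are
comparable across image sizes.

* **Uncertainty-weighted similarity.** Per sample, the squared residual
  between the warped moving image and the fixed image is divided by
  $2\sigma^2(x)$ and averaged; $\lambda_0 \overline{\log \sigma^2}$ is
  added once. The control-grid variance is predicted per control point
  but indexed per voxel in the loss, so it is upsampled with the same
  interpolation mode as the displacement, averaged over the three
  components, and clamped below at $10^{-6}$. With $\sigma^2 \equiv 1$,
  $\lambda_0 = 0$, $S = 1$ this reduces to half the mean squared
  residual — the standard heteroscedastic Gaussian reading of the
  similarity term.
* **Soft Dice.** $1 - 2\sum s_f s_w / (\sum s_f + \sum s_w +
  \varepsilon)$ on trilinearly warped (hence soft) masks; included only
  when training masks exist.
* **Bending energy.** Central second differences at unit voxel spacing
  on the common interior region (voxels interior along all three axes),
  pure terms plus twice the mixed terms, per component, divided by the
  total voxel count. Affine fields have exactly zero energy; boundary
  voxels contribute nothing, avoiding padding artifacts.

Default weights are $\lambda_0 = 0.01$, $\lambda_1 = \lambda_2 = 1$,
$\lambda_3 = 0.12$, $S = 4$. The bending weight deserves a note: the
reference sweep optimum $2 \times 10^5$ is stated on an unnormalized
(sum) convention at clinical volume size ($\approx 1.7 \times 10^6$
voxels); dividing by the voxel count gives $\approx 0.12$ on the mean
convention used here. For the *direct* control-grid fit (`fit_gdf()`,
no network) the default is lighter, $\lambda_3 = 0.02$ with Adam step
0.2: the direct fit is used on well-textured synthetic pairs where
fidelity, not noise suppression, is the objective, and a heavy bending
penalty biases the under-constrained corner control points.

## Evaluation metrics

Dice overlap; centroid distance in mm (per-axis spacing applied before
the norm), over corresponding landmarks or mask centroids; and
Jacobian-based regularity. The Jacobian of $\phi(x) = x + T(x)$ is
computed by central differences (one-sided at borders). The log-det
summary is reported as the mean and SD of $|\log \det J|$ over voxels
with positive determinant — the printed reference values are small
positive magnitudes, consistent with this reading, and the convention is
recorded in the output (`logdet_convention`). The folding rate is the
percentage of voxels with $\det J < 0$.

## Synthetic data

`phantom_spec()` fixes the study conditions: $32^3$ volumes, a
quasi-ellipsoidal organ (radius 0.3 of the volume) with homogeneous
interior and smooth boundary contrast, 15 Gaussian intensity blobs of
1.5–3 voxel width and amplitude up to 0.35 (roughly one distinct
feature per 2000 voxels, comparable to the visible structure density in
pelvic MR at this resolution), additive Gaussian noise of SD 0.02
intensity units, and a ground-truth deformation drawn on a $5^3$ grid:
iid Gaussian control vectors smoothed once per axis and scaled to a
maximum displacement of 3 voxels — below half the control spacing
($\approx 3.9$), which guarantees an invertible truth. The moving image
is the phantom; the fixed image is the truth-warped phantom plus fresh
noise; masks and landmarks ride along. What the phantom does *not*
emulate: MR physics, multi-modal appearance, anatomical variability
across subjects, or pathology. Tests that pass on these fixtures
demonstrate the estimator and its regularity behavior, not clinical
accuracy.

## Problem sizes and training profiles

The default configuration (base 16 channels, 5 levels, $8^3$ tokens,
$C_{pe} = 66$, 4 heads of width 16) targets clinical $128^3$ volumes.
Two deliberate deviations from the reference description: the positional
encoding width must be divisible by 6 (three axes, two phases), so the
default is 66 rather than 64; and the printed total parameter count
(252,960) is not reproducible from the printed architecture — a 5-level
doubling encoder from 16 channels alone exceeds $10^6$ parameters — so
that count is treated as unmatchable and no width was tuned toward it.

All examples, tests and the acceptance study run at desk scale:
`small_network_config()` (base 8 channels, 4 levels, $4^3$ tokens,
$C_{pe} = 48$, 4 heads of width 8, $\approx 10^5$ parameters) on $32^3$
synthetic volumes, cohorts of 40 training and 10 held-out pairs, and 10
training epochs. At this scale a from-scratch network sees only a few
hundred optimization steps, two orders of magnitude fewer than a full
clinical run, so the desk-scale training profile
(`desk_training_config()`) departs from the clinical defaults in ways
that buy learning speed: single-pair batches (more steps per epoch), an
Adam step of `1e-3` instead of `1e-4`, local attention over an $8^3$
token lattice (the locality prior removes what would otherwise have to
be learned), and a fixed displacement-head gain of 5 (flow scaling) so
the head can reach voxel-scale outputs within the step budget. The
profile was frozen after studying the optimization behavior of the
synthetic task; the paper-faithful defaults (`network_config()`,
`head_gain = 1`, global attention) remain untouched.

Two caveats follow from the short budget. First, desk-scale training
improves held-out image similarity but the predicted fields remain
sub-voxel in magnitude; binary-mask Dice — already 0.91 before
registration on these phantoms and quantized at the voxel level — is
insensitive at that field scale, so the end-to-end tests assert
held-out MSE improvement and Dice non-degradation rather than Dice
gains. Second, deformation regularity (zero folding) holds at every
setting because it derives from the coarse parameterization, not from
training length.

## Numerical choices

* Displacements are stored in voxels of the fixed lattice under the
  backward (gather) convention `output(x) = moving(x + T(x))`; mm enter
  only inside metrics. Landmarks are transported by solving
  `x + T(x) = p` with a fixed-point iteration, which converges for the
  smooth, sub-spacing fields the grid produces.
* Out-of-bounds sampling clamps to the border; clamped coordinates have
  zero derivative.
* Control points are 0-based and corner-aligned
  (`linspace(0, dim - 1, g)` per axis), so the extreme control points
  lie on the volume boundary.
* Softmax rows subtract the row maximum; softplus switches to identity
  above 30; variance is clamped below at $10^{-6}$ in the loss.
* Grid selection ties break toward the coarsest candidate grid.
* Weight initialization is fan-in uniform, fully determined by the
  configuration seed; every stochastic path (sampling, batching, grid
  draws) restores the global RNG state on exit.

## Known limitations

* The decoder wiring between levels is this package's own resolution of
  an under-specified design; other read-out schemes are plausible.
* Monte-Carlo sampling during training uses `S = 4` by default; very
  small variances make the samples nearly deterministic and the
  uncertainty map then reflects the log-penalty equilibrium
  $\sigma^2 \approx \overline{r^2} / (2\lambda_0)$ rather than posterior
  spread.
* No diffeomorphic integration: regularity comes from coarseness and
  the bending penalty, not from a group structure.
* World-coordinate (affine-composed) registration and 2D images are out
  of scope.
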