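# ------------------------------------------------------------------
# Training objectives: uncertainty-weighted similarity, soft Dice,
# bending energy, and their weighted sum. Every function accepts plain
# arrays or autodiff nodes, so the same code scores results and drives
# backpropagation. All sums over the voxel domain are implemented as
# means so the loss weights are comparable across image sizes.
# ------------------------------------------------------------------

#' Loss weights and Monte-Carlo settings
#'
#' @param lambda0 uncertainty (log-variance) penalty
#' @param lambda1 similarity weight
#' @param lambda2 Dice weight (used only when masks are available)
#' @param lambda3 bending-energy weight; the default rescales the
#'   sum-convention sweep optimum 2e5 to the mean convention at clinical
#'   volume size
#' @param dice_eps Dice smoothing constant
#' @param mc_samples number of Monte-Carlo transformation samples S
#' @return a `loss_weights` object
#' @export
loss_weights <- function(lambda0 = 0.01, lambda1 = 1, lambda2 = 1,
                         lambda3 = 0.12, dice_eps = 1e-6, mc_samples = 4L) {
  if (any(c(lambda0, lambda1, lambda2, lambda3) < 0))
    stop("loss weights must be >= 0")
  if (dice_eps <= 0) stop("dice_eps must be > 0")
  if (mc_samples < 1L) stop("mc_samples must be >= 1")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, dice_eps = dice_eps,
                 mc_samples = as.integer(mc_samples)),
            class = "loss_weights")
}

as_arr <- function(x) {
  if (inherits(x, c("image_volume", "mask_volume"))) x$data else x
}

#' Mean-squared-error image similarity
#'
#' @param warped,fixed volumes (or arrays/nodes) of identical shape
#' @return scalar MSE over the voxel domain
#' @export
similarity_image <- function(warped, fixed) {
  a <- as_arr(warped); b <- as_arr(fixed)
  if (!identical(dim(val(a)), dim(val(b)))) stop("shape mismatch")
  r <- ad_sub(a, b)
  ad_mean(ad_mul(r, r))
}

# channel slice of a (C, W, H, D) array/node
ad_chan <- function(x, c) {
  if (!is_node(x)) return(x[c, , , ])
  xv <- val(x)
  node_on(x$tape, xv[c, , , ], list(x), function(g) {
    gx <- array(0, dim(xv))
    gx[c, , , ] <- g
    acc_grad(x, gx)
  })
}

#' Heteroscedastic (uncertainty-weighted) similarity loss
#'
#' Each Monte-Carlo transformation sample is upsampled and used to warp
#' the moving image; the per-voxel squared residual is divided by twice
#' the voxel-level variance, obtained by upsampling the control-grid
#' variance with the same interpolation mode as the displacement and
#' averaged over the three components, clamped below at 1e-6. A
#' log-variance penalty weighted by `lambda0` is added once.
#'
#' @param moving,fixed image volumes (or arrays); `moving` is constant
#' @param samples list of sampled grid displacement arrays/nodes
#'   `(3, gw, gh, gd)`
#' @param var_grid control-grid variance array/node `(3, gw, gh, gd)`,
#'   strictly positive
#' @param cfg an `upsampler_config`
#' @param weights a `loss_weights` (uses `lambda0`)
#' @return scalar loss (node when inputs are nodes)
#' @export
uncertainty_loss <- function(moving, fixed, samples, var_grid,
                             cfg = upsampler_config(),
                             weights = loss_weights()) {
  mov <- as_arr(moving); fix <- as_arr(fixed)
  if (min(val(var_grid)) <= 0) stop("domain error: variance must be > 0")
  shp <- dim(fix)
  var_vox <- upsample(var_grid, shp, cfg)
  var_vox <- ad_scale(ad_add(ad_add(ad_chan(var_vox, 1), ad_chan(var_vox, 2)),
                             ad_chan(var_vox, 3)), 1 / 3)
  var_vox <- ad_clamp_min(var_vox, 1e-6)
  res_term <- NULL
  for (s in seq_along(samples)) {
    dense <- upsample(samples[[s]], shp, cfg)
    warped <- ad_warp(mov, dense)
    r <- ad_sub(warped, fix)
    term <- ad_mean(ad_div(ad_mul(r, r), ad_scale(var_vox, 2)))
    res_term <- if (is.null(res_term)) term else ad_add(res_term, term)
  }
  res_term <- ad_scale(res_term, 1 / length(samples))
  if (weights$lambda0 > 0)
    res_term <- ad_add(res_term,
                       ad_scale(ad_mean(ad_log(var_vox)), weights$lambda0))
  res_term
}

#' Soft Dice loss
#'
#' `1 - 2 sum(a*b) / (sum(a) + sum(b) + eps)`; differentiable for soft
#' (trilinearly warped) masks in \[0, 1\].
#'
#' @param fixed_mask,warped_mask masks (or arrays/nodes), same shape
#' @param eps smoothing constant
#' @return scalar in \[0, 1\]
#' @export
dice_loss <- function(fixed_mask, warped_mask, eps = 1e-6) {
  a <- as_arr(fixed_mask); b <- as_arr(warped_mask)
  if (!identical(dim(val(a)), dim(val(b)))) stop("shape mismatch")
  inter <- ad_sum(ad_mul(a, b))
  ad_sub(1, ad_div(ad_scale(inter, 2),
                   ad_add(ad_add(ad_sum(a), ad_sum(b)), eps)))
}

# finite-difference matrices for the bending stencils
d2_matrix <- function(m) {
  D <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}
d1c_matrix <- function(m) {
  D <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D[i, c(i, i + 2)] <- c(-0.5, 0.5)
  D
}
trim_matrix <- function(m) {
  D <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D[i, i + 1] <- 1
  D
}

#' Bending energy of a displacement field
#'
#' Sum over the common interior region of the squared pure second
#' derivatives plus twice the squared mixed second derivatives, per
#' component, by central finite differences at unit voxel spacing,
#' divided by the total voxel count. Vanishes on affine fields.
#'
#' @param ddf a `dense_field`, or a `(3, W, H, D)` array/node
#' @return nonnegative scalar (node when the input is a node)
#' @export
bending_energy <- function(ddf) {
  v <- if (inherits(ddf, "dense_field")) ddf$vectors else ddf
  d <- dim(val(v))[2:4]
  if (any(d < 3)) stop("dimension error: each axis must have >= 3 voxels")
  D2 <- lapply(d, d2_matrix)
  D1 <- lapply(d, d1c_matrix)
  Tr <- lapply(d, trim_matrix)
  sq <- function(x) ad_sum(ad_mul(x, x))
  tot <- ad_add(ad_add(
    sq(ad_axismats(v, D2[[1]], Tr[[2]], Tr[[3]])),
    sq(ad_axismats(v, Tr[[1]], D2[[2]], Tr[[3]]))),
    sq(ad_axismats(v, Tr[[1]], Tr[[2]], D2[[3]])))
  mix <- ad_add(ad_add(
    sq(ad_axismats(v, D1[[1]], D1[[2]], Tr[[3]])),
    sq(ad_axismats(v, D1[[1]], Tr[[2]], D1[[3]]))),
    sq(ad_axismats(v, Tr[[1]], D1[[2]], D1[[3]])))
  ad_scale(ad_add(tot, ad_scale(mix, 2)), 1 / prod(d))
}

#' Weighted total training loss
#'
#' @param uncertainty,dice,bending scalar loss components (numbers or
#'   nodes); `dice` may be `NULL` when no masks exist
#' @param weights a `loss_weights`
#' @param masks_available if `FALSE` the Dice term contributes zero
#' @return a `loss_report` list: `total`, `uncertainty_term`,
#'   `dice_term`, `bending_term` (numeric) and `total_node` when built on
#'   a tape
#' @export
total_loss <- function(uncertainty, dice = NULL, bending,
                       weights = loss_weights(), masks_available = TRUE) {
  use_dice <- masks_available && !is.null(dice) && weights$lambda2 > 0
  tot <- ad_scale(uncertainty, weights$lambda1)
  if (use_dice) tot <- ad_add(tot, ad_scale(dice, weights$lambda2))
  tot <- ad_add(tot, ad_scale(bending, weights$lambda3))
  structure(list(
    total = as.numeric(val(tot)),
    uncertainty_term = as.numeric(val(uncertainty)),
    dice_term = if (use_dice) as.numeric(val(dice)) else 0,
    bending_term = as.numeric(val(bending)),
    total_node = if (is_node(tot)) tot else NULL
  ), class = "loss_report")
}
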