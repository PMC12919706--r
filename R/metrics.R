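# ------------------------------------------------------------------
# Registration accuracy and deformation-regularity metrics.
# ------------------------------------------------------------------

#' Dice similarity coefficient between binary masks
#'
#' Both masks empty is defined as 1 (perfect agreement on emptiness);
#' exactly one empty gives 0.
#'
#' @param a,b `mask_volume`s or binary arrays of the same shape
#' @return scalar in \[0, 1\]
#' @export
dice_coefficient <- function(a, b) {
  av <- as_arr(a); bv <- as_arr(b)
  if (!identical(dim(av), dim(bv))) stop("shape mismatch")
  sa <- sum(av); sb <- sum(bv)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(av * bv) / (sa + sb)
}

mask_centroid <- function(m) {
  d <- dim(m)
  s <- sum(m)
  if (s == 0) stop("undefined centroid: empty mask")
  idx <- which(m > 0, arr.ind = TRUE) - 1  # 0-based voxel coords
  w <- m[m > 0]
  colSums(idx * w) / s
}

#' Mean Euclidean centroid distance in mm
#'
#' For landmark sets, the mean over corresponding point pairs; for
#' masks, the distance between the two mask centroids
#' `c = sum(x s(x)) / sum(s(x))`. Per-axis spacing converts voxel
#' offsets to mm before the norm.
#'
#' @param fixed,warped two `landmark_set`s (corresponding rows) or two
#'   `mask_volume`s/binary arrays
#' @param spacing voxel size in mm (taken from a `mask_volume` when
#'   available)
#' @return mean distance in mm
#' @export
centroid_distance <- function(fixed, warped, spacing = c(1, 1, 1)) {
  if (inherits(fixed, "landmark_set")) {
    if (nrow(fixed$points) != nrow(warped$points))
      stop("landmark sets must correspond")
    d <- sweep(fixed$points - warped$points, 2, spacing, "*")
    return(mean(sqrt(rowSums(d^2))))
  }
  if (inherits(fixed, "mask_volume")) spacing <- fixed$spacing
  ca <- mask_centroid(as_arr(fixed))
  cb <- mask_centroid(as_arr(warped))
  sqrt(sum(((ca - cb) * spacing)^2))
}

# np.gradient-style derivative along one axis of a 3D array: central
# differences in the interior, one-sided at the borders.
grad1 <- function(a, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  n <- dim(b)[1]
  g <- b * 0
  if (n >= 2) {
    g[1, , ] <- b[2, , ] - b[1, , ]
    g[n, , ] <- b[n, , ] - b[n - 1, , ]
    if (n > 2) g[2:(n - 1), , ] <- (b[3:n, , ] - b[1:(n - 2), , ]) / 2
  }
  aperm(g, order(perm))
}

#' Jacobian-determinant regularity statistics of a deformation
#'
#' The transformation is `phi(x) = x + T(x)`; its Jacobian is computed
#' by central finite differences (one-sided at borders). The log-det
#' summary is the mean and SD of `|log det J|` over voxels with positive
#' determinant (recorded in `logdet_convention`); the folding rate is
#' the percentage of voxels with negative determinant.
#'
#' @param ddf a `dense_field` or `(3, W, H, D)` array, voxel units
#' @param spacing per-axis voxel size (mm); anisotropic spacing is
#'   accounted for in the derivative scaling
#' @return a `jacobian_stats` list: `logdet_mean`, `logdet_sd`,
#'   `folding_rate` (percent), `det_map`, `logdet_convention`
#' @export
jacobian_stats <- function(ddf, spacing = c(1, 1, 1)) {
  v <- ddf_vectors(ddf)
  d <- dim(v)[2:4]
  if (any(d < 2)) stop("field must have >= 2 voxels per axis")
  # J[c, a] = delta_ca + (spacing[c]/spacing[a]) * dT_c/dx_a
  J <- vector("list", 9)
  k <- 1
  for (cc in 1:3) for (aa in 1:3) {
    g <- grad1(v[cc, , , ], aa) * spacing[cc] / spacing[aa]
    if (cc == aa) g <- g + 1
    J[[k]] <- g
    k <- k + 1
  }
  # det of 3x3 per voxel (row-major over [c, a])
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  pos <- det > 0
  ld <- abs(log(det[pos]))
  structure(list(
    logdet_mean = if (any(pos)) mean(ld) else NA_real_,
    logdet_sd = if (sum(pos) > 1) stats::sd(ld) else 0,
    folding_rate = 100 * mean(det < 0),
    det_map = det,
    logdet_convention = "mean |log det J| over voxels with det > 0"
  ), class = "jacobian_stats")
}

#' @export
print.jacobian_stats <- function(x, ...) {
  cat(sprintf("jacobian_stats: |logdet| %.4f +/- %.4f, folding %.3f%%\n",
              x$logdet_mean, x$logdet_sd, x$folding_rate))
  invisible(x)
}
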