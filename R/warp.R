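# ------------------------------------------------------------------
# Spatial transform (warping) operator, STN-style backward resampling:
# output(x) = moving(x + T(x)). Out-of-bounds sample coordinates are
# clamped to the volume border.
# ------------------------------------------------------------------

#' Warp a volume with a dense displacement field
#'
#' @param moving an `image_volume`, `mask_volume`, or 3D array
#' @param ddf a `dense_field` or `(3, W, H, D)` array, voxel units
#' @param mode `"trilinear"` (differentiable) or `"nearest"`
#' @return warped object of the same class as `moving`
#' @export
warp <- function(moving, ddf, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  dv <- ddf_vectors(ddf)
  arr <- if (inherits(moving, c("image_volume", "mask_volume")))
    moving$data else as.array(moving)
  if (!identical(dim(dv)[2:4], dim(arr)))
    stop("dimension error: ddf spatial shape must equal the moving shape")
  out <- warp_fw(arr, dv, if (mode == "nearest") 1L else 0L)
  if (inherits(moving, "image_volume"))
    image_volume(out, moving$spacing, moving$origin)
  else if (inherits(moving, "mask_volume") && mode == "nearest")
    mask_volume(out, moving$spacing, moving$origin)
  else out
}

# Sample each displacement component at fractional voxel points (K x 3,
# 0-based) by trilinear interpolation with border clamping.
sample_ddf <- function(dv, pts) {
  d <- dim(dv)[2:4]
  K <- nrow(pts)
  out <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    p <- pmin(pmax(pts[k, ], 0), d - 1)
    p0 <- pmin(floor(p), d - 1)
    p1 <- pmin(p0 + 1, d - 1)
    f <- p - p0
    for (c in 1:3) {
      acc <- 0
      for (ix in 0:1) for (iy in 0:1) for (iz in 0:1) {
        w <- (if (ix) f[1] else 1 - f[1]) *
             (if (iy) f[2] else 1 - f[2]) *
             (if (iz) f[3] else 1 - f[3])
        if (w > 0)
          acc <- acc + w * dv[c,
                              (if (ix) p1[1] else p0[1]) + 1,
                              (if (iy) p1[2] else p0[2]) + 1,
                              (if (iz) p1[3] else p0[3]) + 1]
      }
      out[k, c] <- acc
    }
  }
  out
}

#' Transport landmarks consistently with the image warp
#'
#' Under the gather convention a feature at position `p` of the moving
#' image appears in the warped image at the location `x` solving
#' `x + T(x) = p`; that fixed point is found by the iteration
#' `x <- p - T(x)`, which converges for the smooth, moderate fields the
#' sparse grid produces.
#'
#' @param points a `landmark_set` with 0-based voxel coordinates on the
#'   moving image
#' @param ddf a `dense_field` or `(3, W, H, D)` array
#' @param iters fixed-point iterations
#' @return a `landmark_set` of transported points; out-of-bounds input
#'   points are dropped with a warning
#' @export
warp_points <- function(points, ddf, iters = 25L) {
  dv <- ddf_vectors(ddf)
  d <- dim(dv)[2:4]
  pts <- points$points
  ok <- apply(pts, 1, function(p) all(p >= 0 & p <= d - 1))
  if (!all(ok)) {
    warning(sprintf("%d out-of-bounds landmark(s) excluded", sum(!ok)))
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) == 0L) stop("no landmarks remain inside the volume")
  }
  x <- pts
  for (i in seq_len(iters)) {
    x <- pts - sample_ddf(dv, x)
    x <- sweep(pmin(pmax(x, 0), matrix(d - 1, nrow(x), 3, byrow = TRUE)), 1, 0, "+")
  }
  landmark_set(x, points$labels[ok])
}
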