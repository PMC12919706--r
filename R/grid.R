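# ------------------------------------------------------------------
# Control grids and displacement fields.
#
# A control grid is the axis-aligned tensor-product lattice carrying the
# sparse displacement parameterization. Grids are corner-aligned: the
# extreme control points sit exactly on the volume boundary, i.e. the
# per-axis positions are linspace(0, dim - 1, g). Displacements are
# stored in voxel units of the fixed-image lattice under the backward
# (gather) convention: output(x) = moving(x + T(x)).
# ------------------------------------------------------------------

#' Build a corner-aligned control-point grid
#'
#' @param image_shape 3 integers, the voxel dimensions `(W, H, D)`
#' @param grid_size 3 integers `(gw, gh, gd)`, control points per axis
#' @return a `control_grid`: `size`, per-axis coordinate list `axes`, and
#'   the `G x 3` stacked coordinate matrix `coords` (0-based voxel units)
#' @export
make_control_grid <- function(image_shape, grid_size) {
  image_shape <- as.integer(image_shape)
  grid_size <- as.integer(grid_size)
  if (length(image_shape) != 3L || length(grid_size) != 3L)
    stop("image_shape and grid_size must have length 3")
  if (any(grid_size < 2L))
    stop("invalid grid: each grid axis must have at least 2 control points")
  if (any(grid_size > image_shape))
    stop("invalid grid: grid larger than image")
  axes <- lapply(1:3, function(a)
    seq(0, image_shape[a] - 1, length.out = grid_size[a]))
  coords <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  dimnames(coords) <- NULL
  structure(list(size = grid_size, axes = axes, coords = coords,
                 image_shape = image_shape),
            class = "control_grid")
}

#' Per-axis control-point spacing of a grid, in voxels
#' @param grid a `control_grid`
#' @return length-3 numeric
#' @export
grid_spacing <- function(grid) {
  (grid$image_shape - 1) / (grid$size - 1)
}

#' Construct a gridded displacement field (GDF)
#'
#' @param grid a `control_grid`
#' @param vectors numeric array `(3, gw, gh, gd)` of displacements in
#'   voxel units
#' @return a `gridded_field`
#' @export
gridded_field <- function(grid, vectors) {
  vectors <- as.array(vectors)
  if (!identical(dim(vectors), c(3L, grid$size)))
    stop("vectors shape must be (3, gw, gh, gd)")
  if (!all(is.finite(vectors))) stop("displacements must be finite")
  structure(list(grid = grid, vectors = vectors), class = "gridded_field")
}

#' Construct a dense displacement field (DDF)
#'
#' @param vectors numeric array `(3, W, H, D)` in voxel units
#' @return a `dense_field`
#' @export
dense_field <- function(vectors) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[1] != 3L)
    stop("vectors shape must be (3, W, H, D)")
  structure(list(vectors = vectors, shape = dim(vectors)[2:4]),
            class = "dense_field")
}

#' @export
print.control_grid <- function(x, ...) {
  cat(sprintf("control_grid %s on image %s (%d points)\n",
              paste(x$size, collapse = "x"),
              paste(x$image_shape, collapse = "x"), nrow(x$coords)))
  invisible(x)
}

# accept a dense_field or a bare (3,W,H,D) array
ddf_vectors <- function(ddf) {
  if (inherits(ddf, "dense_field")) ddf$vectors else as.array(ddf)
}

gdf_vectors <- function(gdf) {
  if (inherits(gdf, "gridded_field")) gdf$vectors else as.array(gdf)
}
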