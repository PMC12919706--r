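# ------------------------------------------------------------------
# Domain containers. All are light S3 wrappers over plain arrays:
#   image_volume  — 3D scalar field with voxel spacing (mm) and origin
#   mask_volume   — binary volume sharing the image geometry
#   landmark_set  — labelled voxel coordinates (0-based)
# Voxel coordinates are 0-based throughout the package, matching the
# NIfTI voxel-index convention.
# ------------------------------------------------------------------

#' Construct an image volume
#'
#' @param data 3D numeric array of intensities, shape `(W, H, D)`
#' @param spacing per-axis voxel size in mm (length 3)
#' @param origin world-space offset in mm (length 3)
#' @return an object of class `image_volume`
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary mask volume
#'
#' @inheritParams image_volume
#' @return an object of class `mask_volume`
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "mask_volume")
}

#' Construct a landmark set
#'
#' @param points K x 3 matrix of 0-based voxel coordinates
#' @param labels length-K identifiers (defaults to `"L1" ...`)
#' @return an object of class `landmark_set`
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1L) stop("at least one landmark required")
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(points)))
  structure(list(points = points, labels = as.character(labels)),
            class = "landmark_set")
}

#' Rescale intensities to the unit interval
#'
#' @param vol an `image_volume`
#' @return an `image_volume` with intensities in \[0, 1\]
#' @export
normalize_intensity <- function(vol) {
  d <- vol$data
  rng <- range(d)
  if (diff(rng) > 0) d <- (d - rng[1]) / diff(rng) else d <- d * 0
  image_volume(d, vol$spacing, vol$origin)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set with %d points\n", nrow(x$points)))
  invisible(x)
}

# ---- NIfTI I/O ---------------------------------------------------

#' Read a NIfTI volume
#'
#' Spacing is taken from the pixdim header field, origin from the affine
#' translation.
#'
#' @param path `.nii` / `.nii.gz` file
#' @param mask read as a binary mask (values rounded to 0/1)
#' @return `image_volume` or `mask_volume`
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  da <- dim(img)
  a <- array(as.numeric(img), da)  # plain array, no NIfTI attributes
  if (length(da) > 3L)
    a <- array(a[seq_len(prod(da[1:3]))], da[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  aff <- tryCatch(RNifti::xform(img), error = function(e) diag(4))
  orig <- aff[1:3, 4]
  if (mask) mask_volume(round(a), sp, orig) else image_volume(a, sp, orig)
}

#' Write a volume (or a raw array) to NIfTI
#'
#' @param vol `image_volume`, `mask_volume`, or numeric array (a 4D array
#'   is written as a multi-component field, e.g. a displacement field)
#' @param path destination file
#' @param spacing voxel size, used when `vol` is a bare array
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, c("image_volume", "mask_volume"))) {
    a <- vol$data
    spacing <- vol$spacing
  } else a <- vol
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(a)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- landmark CSV ------------------------------------------------

#' Read landmarks from CSV (`label,x,y,z`, voxel coordinates)
#'
#' @param path CSV file
#' @return a `landmark_set`
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d))) stop("landmark CSV must have columns label,x,y,z")
  landmark_set(as.matrix(d[, c("x", "y", "z")]), d$label)
}

#' Write landmarks to CSV
#'
#' @param lm a `landmark_set`
#' @param path destination CSV
#' @export
write_landmarks <- function(lm, path) {
  d <- data.frame(label = lm$labels, x = lm$points[, 1],
                  y = lm$points[, 2], z = lm$points[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
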