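# ------------------------------------------------------------------
# Seeded synthetic fixtures: smooth phantoms with a central organ,
# blob-like intensity features, landmarks, and ground-truth deformations
# drawn on a coarse control grid. Everything is fully determined by the
# seed (R's default Mersenne-Twister RNG), and the global RNG state is
# left untouched.
# ------------------------------------------------------------------

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Specification of a synthetic phantom pair
#'
#' @param shape volume dimensions (default 32^3)
#' @param num_blobs number of smooth intensity features
#' @param organ_radius organ semi-axis as a fraction of the volume
#' @param noise_sd additive Gaussian intensity noise (intensity units)
#' @param deform_grid control-grid size of the true deformation
#' @param max_disp maximum true displacement in voxels; must stay below
#'   half the true control spacing so the truth cannot fold
#' @param num_landmarks landmarks placed on distinct intensity features
#' @param seed RNG seed
#' @return a `phantom_spec`
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), num_blobs = 15L,
                         organ_radius = 0.3, noise_sd = 0.02,
                         deform_grid = c(5L, 5L, 5L), max_disp = 3,
                         num_landmarks = 6L, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- (shape - 1) / (as.integer(deform_grid) - 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (max_disp >= min(spacing) / 2)
    stop("max_disp must be below half the control spacing")
  structure(list(shape = shape, num_blobs = as.integer(num_blobs),
                 organ_radius = organ_radius, noise_sd = noise_sd,
                 deform_grid = as.integer(deform_grid), max_disp = max_disp,
                 num_landmarks = as.integer(num_landmarks),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume, organ mask and landmarks
#'
#' A quasi-ellipsoidal "organ" with homogeneous interior and smooth
#' boundary contrast sits on a darker background; scattered Gaussian
#' blobs supply distinct intensity features, the strongest of which
#' carry the landmarks. Additive Gaussian noise at `noise_sd`.
#'
#' @param spec a `phantom_spec`
#' @return list: `image` (`image_volume`, intensities in \[0, 1\]),
#'   `mask` (`mask_volume`), `landmarks` (`landmark_set`)
#' @export
generate_phantom <- function(spec) {
  with_local_seed(spec$seed, {
    d <- spec$shape
    ax <- lapply(1:3, function(a) seq_len(d[a]) - 1)
    center <- (d - 1) / 2 + stats::runif(3, -1.5, 1.5)
    semi <- spec$organ_radius * d * stats::runif(3, 0.85, 1.15)
    # ellipsoid level function on the lattice
    q1 <- ((ax[[1]] - center[1]) / semi[1])^2
    q2 <- ((ax[[2]] - center[2]) / semi[2])^2
    q3 <- ((ax[[3]] - center[3]) / semi[3])^2
    lev <- outer(outer(q1, q2, "+"), q3, "+")
    mask <- array(as.numeric(lev <= 1), d)
    img <- 0.15 + 0.45 / (1 + exp(8 * (lev - 1)))  # soft boundary contrast
    centers <- matrix(0, spec$num_blobs, 3)
    amps <- numeric(spec$num_blobs)
    for (b in seq_len(spec$num_blobs)) {
      ctr <- stats::runif(3, 0.12, 0.88) * (d - 1)
      sig <- stats::runif(1, 1.5, 3)
      amp <- stats::runif(1, 0.12, 0.35) * sample(c(-1, 1), 1)
      ex <- exp(-(ax[[1]] - ctr[1])^2 / (2 * sig^2))
      ey <- exp(-(ax[[2]] - ctr[2])^2 / (2 * sig^2))
      ez <- exp(-(ax[[3]] - ctr[3])^2 / (2 * sig^2))
      img <- img + amp * outer(outer(ex, ey), ez)
      centers[b, ] <- ctr
      amps[b] <- amp
    }
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- d
    k <- min(spec$num_landmarks, spec$num_blobs)
    pick <- order(-abs(amps))[seq_len(k)]
    list(image = image_volume(img),
         mask = mask_volume(mask),
         landmarks = landmark_set(centers[pick, , drop = FALSE]))
  })
}

# nearest-neighbour smoothing matrix on a grid axis ([0.25 0.5 0.25],
# renormalized at the ends)
smooth_matrix <- function(n) {
  M <- diag(n) * 0.5
  for (i in seq_len(n)) {
    if (i > 1) M[i, i - 1] <- 0.25
    if (i < n) M[i, i + 1] <- 0.25
  }
  M / rowSums(M)
}

#' Draw a smooth ground-truth gridded deformation
#'
#' Control-point vectors are iid Gaussian, smoothed once along each grid
#' axis and rescaled so the largest component equals `max_disp`. Because
#' `max_disp` is below half the control spacing, the upsampled truth is
#' fold-free.
#'
#' @param spec a `phantom_spec`
#' @return a `gridded_field` on the corner-aligned `deform_grid`
#' @export
generate_true_deformation <- function(spec) {
  with_local_seed(spec$seed + 1000L, {
    g <- spec$deform_grid
    grid <- make_control_grid(spec$shape, g)
    v <- array(stats::rnorm(3 * prod(g)), c(3, g))
    v <- ad_axismats(v, smooth_matrix(g[1]), smooth_matrix(g[2]),
                     smooth_matrix(g[3]))
    m <- max(abs(v))
    if (spec$max_disp == 0 || m == 0) v <- v * 0
    else v <- v * (spec$max_disp / m)
    gridded_field(grid, v)
  })
}

#' Generate a registered synthetic pair with known truth
#'
#' The moving image is the phantom; the fixed image is the moving image
#' warped by the upsampled true deformation plus fresh noise. Masks and
#' landmarks are transported with the same field.
#'
#' @param spec a `phantom_spec`
#' @return list: `fixed`, `moving` (`image_volume`s), `truth`
#'   (`gridded_field`), `fixed_mask`, `moving_mask`, `landmarks_moving`,
#'   `landmarks_fixed`, `spec`
#' @export
make_pair <- function(spec) {
  ph <- generate_phantom(spec)
  truth <- generate_true_deformation(spec)
  dense <- upsample(truth, spec$shape, upsampler_config("trilinear"))
  fixed <- warp(ph$image, dense, "trilinear")
  if (spec$noise_sd > 0)
    fixed$data <- pmin(pmax(fixed$data + with_local_seed(
      spec$seed + 2000L,
      array(stats::rnorm(prod(spec$shape), 0, spec$noise_sd), spec$shape)), 0), 1)
  fixed_mask <- warp(ph$mask, dense, "nearest")
  lm_fixed <- warp_points(ph$landmarks, dense)
  list(fixed = fixed, moving = ph$image, truth = truth,
       fixed_mask = fixed_mask, moving_mask = ph$mask,
       landmarks_moving = ph$landmarks, landmarks_fixed = lm_fixed,
       spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' One NIfTI/CSV group per case plus a dataset-level spec file; the
#' layout is what [train()] and [evaluate()] read back.
#'
#' @param dir output directory (created if missing)
#' @param n_pairs number of cases
#' @param spec base `phantom_spec`; case i uses `seed + i - 1`
#' @return invisibly, the vector of case prefixes
#' @export
write_synth_dataset <- function(dir, n_pairs, spec = phantom_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefixes <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    pr <- file.path(dir, sprintf("case_%03d", i))
    pair <- make_pair(sp)
    write_volume(pair$fixed, paste0(pr, "_fixed.nii.gz"))
    write_volume(pair$moving, paste0(pr, "_moving.nii.gz"))
    write_volume(pair$fixed_mask, paste0(pr, "_fixed_mask.nii.gz"))
    write_volume(pair$moving_mask, paste0(pr, "_moving_mask.nii.gz"))
    write_landmarks(pair$landmarks_fixed, paste0(pr, "_landmarks_fixed.csv"))
    write_landmarks(pair$landmarks_moving, paste0(pr, "_landmarks_moving.csv"))
    tv <- aperm(pair$truth$vectors, c(2, 3, 4, 1))  # components last
    write_volume(tv, paste0(pr, "_truth_gdf.nii.gz"))
    prefixes[i] <- pr
  }
  meta <- unclass(spec)
  meta$n_pairs <- n_pairs
  jsonlite::write_json(meta, file.path(dir, "dataset_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefixes)
}

#' Load a synthetic dataset written by [write_synth_dataset()]
#'
#' @param dir dataset directory
#' @return list of pair lists (fixed/moving volumes, masks, landmarks)
#' @export
read_synth_dataset <- function(dir) {
  fx <- sort(list.files(dir, pattern = "_fixed\\.nii\\.gz$", full.names = TRUE))
  if (length(fx) == 0) stop("empty dataset: no *_fixed.nii.gz in ", dir)
  lapply(fx, function(f) {
    pr <- sub("_fixed\\.nii\\.gz$", "", f)
    pair <- list(fixed = read_volume(f),
                 moving = read_volume(paste0(pr, "_moving.nii.gz")))
    mf <- paste0(pr, "_fixed_mask.nii.gz")
    if (file.exists(mf)) {
      pair$fixed_mask <- read_volume(mf, mask = TRUE)
      pair$moving_mask <- read_volume(paste0(pr, "_moving_mask.nii.gz"),
                                      mask = TRUE)
    }
    lf <- paste0(pr, "_landmarks_fixed.csv")
    if (file.exists(lf)) {
      pair$landmarks_fixed <- read_landmarks(lf)
      pair$landmarks_moving <- read_landmarks(paste0(pr, "_landmarks_moving.csv"))
    }
    pair
  })
}
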