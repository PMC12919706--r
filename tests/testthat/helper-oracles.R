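# Independent reference implementations used to verify the package's
# fast paths. These are deliberately naive (triple loops, explicit
# slicing) and share no code with the implementation under test.

# Brute-force backward warp: per-voxel trilinear gather with border
# clamping, written as explicit loops.
warp_gather_oracle <- function(mov, ddf) {
  d <- dim(mov)
  out <- array(0, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    s <- c(x - 1 + ddf[1, x, y, z], y - 1 + ddf[2, x, y, z],
           z - 1 + ddf[3, x, y, z])
    s <- pmin(pmax(s, 0), d - 1)
    p0 <- pmin(floor(s), d - 1)
    p1 <- pmin(p0 + 1, d - 1)
    f <- s - p0
    acc <- 0
    for (ix in 0:1) for (iy in 0:1) for (iz in 0:1) {
      w <- (if (ix) f[1] else 1 - f[1]) *
           (if (iy) f[2] else 1 - f[2]) *
           (if (iz) f[3] else 1 - f[3])
      acc <- acc + w * mov[(if (ix) p1[1] else p0[1]) + 1,
                           (if (iy) p1[2] else p0[2]) + 1,
                           (if (iz) p1[3] else p0[3]) + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# Explicit per-head attention: slice Q/K/V, form the score matrix, apply
# a hand-written row softmax, concatenate heads, project.
attention_oracle <- function(queries, tokens, params, H, d) {
  Q <- queries %*% params$wq
  K <- tokens %*% params$wk
  V <- tokens %*% params$wv
  heads <- list()
  for (h in 1:H) {
    idx <- ((h - 1) * d + 1):(h * d)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(d)
    A <- S
    for (r in seq_len(nrow(S))) {
      e <- exp(S[r, ] - max(S[r, ]))
      A[r, ] <- e / sum(e)
    }
    heads[[h]] <- A %*% V[, idx, drop = FALSE]
  }
  do.call(cbind, heads) %*% params$wo
}

# Explicit finite-difference bending energy: central second differences
# on the common interior, mixed terms with factor 2, divided by the
# total voxel count.
bending_oracle <- function(v) {
  d <- dim(v)[2:4]
  tot <- 0
  for (cc in 1:3) {
    f <- v[cc, , , ]
    for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
      dxx <- f[x + 1, y, z] - 2 * f[x, y, z] + f[x - 1, y, z]
      dyy <- f[x, y + 1, z] - 2 * f[x, y, z] + f[x, y - 1, z]
      dzz <- f[x, y, z + 1] - 2 * f[x, y, z] + f[x, y, z - 1]
      dxy <- (f[x + 1, y + 1, z] - f[x + 1, y - 1, z] -
              f[x - 1, y + 1, z] + f[x - 1, y - 1, z]) / 4
      dxz <- (f[x + 1, y, z + 1] - f[x + 1, y, z - 1] -
              f[x - 1, y, z + 1] + f[x - 1, y, z - 1]) / 4
      dyz <- (f[x, y + 1, z + 1] - f[x, y + 1, z - 1] -
              f[x, y - 1, z + 1] + f[x, y - 1, z - 1]) / 4
      tot <- tot + dxx^2 + dyy^2 + dzz^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
    }
  }
  tot / prod(d)
}

rand_volume <- function(n, seed = 1) {
  set.seed(seed)
  array(runif(n^3), c(n, n, n))
}

rand_ddf <- function(n, scale = 0.5, seed = 1) {
  set.seed(seed)
  array(rnorm(3 * n^3, 0, scale), c(3, n, n, n))
}

tiny_cfg <- function(...) {
  small_network_config(base_channels = 4L, num_layers = 3L,
                       proj_channels = 8L, proj_spatial = c(3L, 3L, 3L),
                       pe_channels = 12L, heads = 2L, head_dim = 4L,
                       decoder_channels = 8L, out_channels = 8L, ...)
}
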