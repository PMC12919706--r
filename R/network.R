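# ------------------------------------------------------------------
# The registration network: a multiscale stride-2 convolutional encoder
# on the concatenated fixed/moving pair, per-level skip projections that
# flatten features into fixed-length token sequences, and a
# cross-attention decoder whose queries are sinusoidal positional
# encodings of the control-point coordinates. Because the attention
# projection weights act on feature dimensions only, one weight set
# serves any grid size: changing (gw, gh, gd) changes only the number of
# queries. A Bayesian head emits a mean and a softplus-positive variance
# per control point.
# ------------------------------------------------------------------

#' Network architecture configuration
#'
#' @param base_channels encoder channels at the first level; doubled at
#'   each subsequent level
#' @param num_layers number of stride-2 encoder levels (>= 2)
#' @param proj_channels token feature width Cp after projection
#' @param proj_spatial 3 ints, spatial size each level is resampled to
#'   before flattening; token count Np = prod(proj_spatial)
#' @param pe_channels query positional-encoding width Cpe, divisible by 6
#' @param heads,head_dim attention heads H and per-head width d
#' @param decoder_channels token-state width Cd carried between levels
#' @param out_channels decoder output width Cout per control point
#' @param projector use per-level skip projections; if `FALSE` only the
#'   bottleneck level feeds the decoder
#' @param head_gain fixed multiplier on the displacement-mean head output
#'   (flow scaling); lets short training runs reach voxel-scale
#'   displacements without destabilizing the shared trunk
#' @param bayesian attach the variance head
#' @param local_radius optional attention locality radius in normalized
#'   coordinates (`NULL` = full attention as in the printed equation)
#' @param grid_sizes candidate grid sizes for adaptive training
#' @param seed weight-initialization seed
#' @return a `network_config`
#' @export
network_config <- function(base_channels = 16L, num_layers = 5L,
                           proj_channels = 32L, proj_spatial = c(8L, 8L, 8L),
                           pe_channels = 66L, heads = 4L, head_dim = 16L,
                           decoder_channels = 64L, out_channels = 64L,
                           projector = TRUE, head_gain = 1,
                           bayesian = TRUE, local_radius = NULL,
                           grid_sizes = list(c(5L, 5L, 5L), c(8L, 8L, 8L),
                                             c(10L, 10L, 10L), c(15L, 15L, 15L)),
                           seed = 1L) {
  if (num_layers < 2L) stop("num_layers must be >= 2")
  if (pe_channels %% 6L != 0L)
    stop("configuration error: pe_channels must be divisible by 6")
  structure(list(base_channels = as.integer(base_channels),
                 num_layers = as.integer(num_layers),
                 proj_channels = as.integer(proj_channels),
                 proj_spatial = as.integer(proj_spatial),
                 pe_channels = as.integer(pe_channels),
                 heads = as.integer(heads), head_dim = as.integer(head_dim),
                 decoder_channels = as.integer(decoder_channels),
                 out_channels = as.integer(out_channels),
                 projector = isTRUE(projector), head_gain = head_gain,
                 bayesian = isTRUE(bayesian),
                 local_radius = local_radius, grid_sizes = grid_sizes,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Reduced architecture for desk-scale (32^3) volumes
#'
#' The default configuration targets clinical 128^3 volumes; this
#' profile scales widths and depth down proportionally for the 32^3
#' synthetic studies used in the examples and tests.
#'
#' @param ... overrides passed to [network_config()]
#' @return a `network_config`
#' @export
small_network_config <- function(...) {
  args <- list(base_channels = 8L, num_layers = 4L, proj_channels = 16L,
               proj_spatial = c(4L, 4L, 4L), pe_channels = 48L,
               heads = 4L, head_dim = 8L, decoder_channels = 32L,
               out_channels = 32L)
  do.call(network_config, utils::modifyList(args, list(...)))
}

encoder_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$num_layers) - 1L)

proj_levels <- function(cfg) {
  if (cfg$projector) seq_len(cfg$num_layers) else cfg$num_layers
}

fanin_init <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialize network weights
#'
#' Fan-in uniform initialization; fully determined by `cfg$seed`.
#'
#' @param cfg a `network_config`
#' @param in_channels input channels (2: fixed + moving)
#' @return named list of weight arrays
#' @export
init_weights <- function(cfg, in_channels = 2L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  w <- list()
  ch <- c(in_channels, encoder_channels(cfg))
  for (l in seq_len(cfg$num_layers)) {
    fi <- ch[l] * 27
    w[[paste0("enc", l, ".w")]] <- fanin_init(c(ch[l + 1L], ch[l], 3, 3, 3), fi)
    w[[paste0("enc", l, ".b")]] <- rep(0, ch[l + 1L])
  }
  Hd <- cfg$heads * cfg$head_dim
  FK <- cfg$proj_channels + cfg$decoder_channels
  lv <- proj_levels(cfg)
  for (l in lv) {
    cl <- encoder_channels(cfg)[l]
    w[[paste0("proj", l, ".w")]] <- fanin_init(c(cl, cfg$proj_channels), cl)
    w[[paste0("proj", l, ".b")]] <- rep(0, cfg$proj_channels)
    if (l > min(lv)) {  # token state is consumed by the next level up
      w[[paste0("tok", l, ".w")]] <- fanin_init(c(FK, cfg$decoder_channels), FK)
      w[[paste0("tok", l, ".b")]] <- rep(0, cfg$decoder_channels)
    }
    w[[paste0("att", l, ".wq")]] <- fanin_init(c(cfg$pe_channels, Hd), cfg$pe_channels)
    w[[paste0("att", l, ".wk")]] <- fanin_init(c(FK, Hd), FK)
    w[[paste0("att", l, ".wv")]] <- fanin_init(c(FK, Hd), FK)
    w[[paste0("att", l, ".wo")]] <- fanin_init(c(Hd, cfg$out_channels), Hd)
  }
  w[["head.mu.w"]] <- fanin_init(c(cfg$out_channels, 3), cfg$out_channels)
  w[["head.mu.b"]] <- rep(0, 3)
  if (cfg$bayesian) {
    w[["head.eta.w"]] <- fanin_init(c(cfg$out_channels, 3), cfg$out_channels)
    w[["head.eta.b"]] <- rep(0, 3)
  }
  w
}

#' Total trainable parameter count
#' @param weights named list from [init_weights()]
#' @return integer
#' @export
count_params <- function(weights) sum(vapply(weights, length, 1L))

# ---- positional encoding -----------------------------------------

pe_cache_env <- new.env(parent = emptyenv())

#' Sinusoidal 3D positional encoding
#'
#' `C/6` frequency bands per axis and phase: for band k (0-based) the
#' angular frequency is `pi * 2^k`, giving `sin` and `cos` features of
#' each of the three normalized coordinates. Deterministic (non-learned),
#' so the same encoder serves arbitrary grid sizes.
#'
#' @param coords `G x 3` matrix of normalized coordinates in \[0, 1\]
#' @param channels output width, divisible by 6
#' @return `G x channels` matrix
#' @export
positional_encoding <- function(coords, channels) {
  if (channels %% 6L != 0L)
    stop("configuration error: channels must be divisible by 6")
  coords <- matrix(coords, ncol = 3)
  bands <- channels %/% 6L
  out <- matrix(0, nrow(coords), channels)
  col <- 1L
  for (a in 1:3) for (k in seq_len(bands) - 1L) {
    w <- pi * 2^k
    out[, col] <- sin(w * coords[, a])
    out[, col + 1L] <- cos(w * coords[, a])
    col <- col + 2L
  }
  out
}

# cached query PEs per (grid size, channels)
pe_for_grid <- function(grid, channels) {
  key <- paste(c(grid$size, grid$image_shape, channels), collapse = "_")
  if (!is.null(pe_cache_env[[key]])) return(pe_cache_env[[key]])
  nc <- sweep(grid$coords, 2, pmax(grid$image_shape - 1, 1), "/")
  pe <- positional_encoding(nc, channels)
  pe_cache_env[[key]] <- pe
  pe
}

# token-center coordinates of the projection lattice, normalized
token_centers <- function(proj_spatial) {
  ax <- lapply(proj_spatial, function(p) (seq_len(p) - 0.5) / p)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# token PEs truncated to the token width (sinusoidal widths are
# multiples of 6; tokens need not be)
token_pe <- function(proj_spatial, width) {
  full <- 6L * ceiling(width / 6L)
  positional_encoding(token_centers(proj_spatial), full)[, seq_len(width),
                                                         drop = FALSE]
}

# ---- forward components ------------------------------------------

# adaptive average-pooling matrix (p x n); also upsamples when p > n
pool_matrix <- function(n, p) {
  M <- matrix(0, p, n)
  for (i in seq_len(p)) {
    s <- floor((i - 1) * n / p) + 1L
    e <- ceiling(i * n / p)
    M[i, s:e] <- 1 / (e - s + 1L)
  }
  M
}

#' Encode a fixed/moving pair into a multiscale feature pyramid
#'
#' @param fixed,moving `image_volume`s (or 3D arrays) of identical shape
#' @param cfg a `network_config`
#' @param weights from [init_weights()]
#' @param tape optional autodiff tape; when given, weights are assumed
#'   to be parameter nodes
#' @return list of `num_layers` feature arrays/nodes `(C_l, W_l, H_l, D_l)`
#' @export
encode <- function(fixed, moving, cfg, weights, tape = NULL) {
  f <- as_arr(fixed); m <- as_arr(moving)
  if (!identical(dim(f), dim(m))) stop("fixed/moving shape mismatch")
  if (any(dim(f) < 2^cfg$num_layers))
    stop("configuration error: spatial dim smaller than 2^num_layers")
  x <- array(0, c(2L, dim(f)))
  x[1, , , ] <- f
  x[2, , , ] <- m
  pyr <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    x <- ad_relu(ad_conv3d(x, weights[[paste0("enc", l, ".w")]],
                           weights[[paste0("enc", l, ".b")]], 2L))
    pyr[[l]] <- x
  }
  pyr
}

#' Project one pyramid level into a token sequence
#'
#' The level is resampled to `proj_spatial` by adaptive average pooling,
#' flattened to Np rows, mapped to Cp channels by a per-level point-wise
#' linear layer, and given sinusoidal positional information of the
#' token centers.
#'
#' @param level_features `(C_l, W_l, H_l, D_l)` array/node
#' @param level level index (selects the projection weights)
#' @param cfg,weights as in [encode()]
#' @return `(Np, Cp)` token matrix/node
#' @export
project_tokens <- function(level_features, level, cfg, weights) {
  d <- dim(val(level_features))
  pm <- lapply(1:3, function(a) pool_matrix(d[a + 1L], cfg$proj_spatial[a]))
  x <- ad_axismats(level_features, pm[[1]], pm[[2]], pm[[3]])
  np <- prod(cfg$proj_spatial)
  x <- ad_aperm(x, c(2, 3, 4, 1))
  x <- ad_reshape(x, c(np, d[1]))
  x <- ad_linear(x, weights[[paste0("proj", level, ".w")]],
                 weights[[paste0("proj", level, ".b")]])
  ad_add(x, token_pe(cfg$proj_spatial, cfg$proj_channels))
}

#' Multi-head cross-attention between control-point queries and tokens
#'
#' `A^(h) = softmax(Q^(h) K^(h)T / sqrt(d))` row-wise over tokens; the
#' head outputs are concatenated and projected by `WO`. With a locality
#' mask, scores of tokens outside a query's neighborhood are suppressed
#' before the softmax.
#'
#' @param queries `G x Cpe` query matrix (positional encodings)
#' @param tokens `Np x F` token matrix/node
#' @param params list with `wq (Cpe x Hd)`, `wk`, `wv (F x Hd)`,
#'   `wo (Hd x Cout)`
#' @param heads,head_dim H and d
#' @param local_mask optional `G x Np` matrix of 0 (keep) / `-Inf`-like
#'   penalties added to the scores
#' @return list: `output` (`G x Cout` matrix/node), `attn` (list of H
#'   numeric attention matrices, each row-stochastic)
#' @export
cross_attention <- function(queries, tokens, params, heads, head_dim,
                            local_mask = NULL) {
  if (!is.null(local_mask) && any(apply(local_mask, 1, function(r) all(r < -1e8))))
    stop("degenerate locality: some query has no tokens in its neighborhood")
  Q <- ad_matmul(queries, params$wq)
  K <- ad_matmul(tokens, params$wk)
  V <- ad_matmul(tokens, params$wv)
  heads_out <- vector("list", heads)
  attn <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * head_dim + 1L):(h * head_dim)
    S <- ad_scale(ad_matmul(ad_cols(Q, idx), ad_t(ad_cols(K, idx))),
                  1 / sqrt(head_dim))
    if (!is.null(local_mask)) S <- ad_add(S, local_mask)
    A <- ad_softmax_rows(S)
    attn[[h]] <- val(A)
    heads_out[[h]] <- ad_matmul(A, ad_cols(V, idx))
  }
  Ycat <- Reduce(ad_cbind, heads_out)
  list(output = ad_matmul(Ycat, params$wo), attn = attn)
}

locality_mask <- function(grid, cfg) {
  if (is.null(cfg$local_radius)) return(NULL)
  qc <- sweep(grid$coords, 2, pmax(grid$image_shape - 1, 1), "/")
  tc <- token_centers(cfg$proj_spatial)
  d2 <- outer(rowSums(qc^2), rowSums(tc^2), "+") - 2 * qc %*% t(tc)
  ifelse(sqrt(pmax(d2, 0)) <= cfg$local_radius, 0, -1e9)
}

#' Decode a feature pyramid into control-grid features
#'
#' Runs bottom-to-top. A token state `Y` (`Np x Cd`, zero at the
#' bottom) is concatenated with each level's projected tokens; the
#' concatenation feeds (a) a cross-attention read-out with control-point
#' queries, accumulated into the grid features, and (b) a token-wise
#' linear/ReLU refinement producing the next level's state.
#'
#' @param pyramid from [encode()]
#' @param grid a `control_grid`
#' @param cfg,weights as in [encode()]
#' @return list: `grid_features` (`Cout x gw x gh x gd` array/node),
#'   `features_matrix` (`G x Cout`), `attn` (per level, per head)
#' @export
decode <- function(pyramid, grid, cfg, weights) {
  pe <- pe_for_grid(grid, cfg$pe_channels)
  mask <- locality_mask(grid, cfg)
  np <- prod(cfg$proj_spatial)
  Y <- matrix(0, np, cfg$decoder_channels)
  Z <- NULL
  attn <- list()
  for (l in rev(proj_levels(cfg))) {
    P <- project_tokens(pyramid[[l]], l, cfg, weights)
    Yhat <- ad_cbind(P, Y)
    ca <- cross_attention(pe, Yhat, list(
      wq = weights[[paste0("att", l, ".wq")]],
      wk = weights[[paste0("att", l, ".wk")]],
      wv = weights[[paste0("att", l, ".wv")]],
      wo = weights[[paste0("att", l, ".wo")]]),
      cfg$heads, cfg$head_dim, mask)
    Z <- if (is.null(Z)) ca$output else ad_add(Z, ca$output)
    attn[[paste0("level", l)]] <- ca$attn
    if (l > min(proj_levels(cfg)))
      Y <- ad_relu(ad_linear(Yhat, weights[[paste0("tok", l, ".w")]],
                             weights[[paste0("tok", l, ".b")]]))
  }
  gf <- ad_aperm(ad_reshape(Z, c(grid$size, dim(val(Z))[2])), c(4, 1, 2, 3))
  list(grid_features = gf, features_matrix = Z, attn = attn)
}

#' Bayesian output head
#'
#' Two linear heads map decoder features to a displacement mean and a
#' raw variance; `var = softplus(eta)` is strictly positive.
#'
#' @param features_matrix `G x Cout` matrix/node from [decode()]
#' @param grid the `control_grid`
#' @param weights network weights
#' @param gain fixed multiplier applied to the mean head (flow scaling)
#' @return list: `mean`, `raw_var`, `var`, each `(3, gw, gh, gd)`
#'   arrays/nodes
#' @export
bayesian_head <- function(features_matrix, grid, weights, gain = 1) {
  to_field <- function(m)
    ad_aperm(ad_reshape(m, c(grid$size, 3L)), c(4, 1, 2, 3))
  mu <- ad_linear(features_matrix, weights[["head.mu.w"]],
                  weights[["head.mu.b"]])
  if (gain != 1) mu <- ad_scale(mu, gain)
  if (is.null(weights[["head.eta.w"]]))  # non-Bayesian ablation
    return(list(mean = to_field(mu), raw_var = NULL, var = NULL))
  eta <- ad_linear(features_matrix, weights[["head.eta.w"]],
                   weights[["head.eta.b"]])
  list(mean = to_field(mu), raw_var = to_field(eta),
       var = to_field(ad_softplus(eta)))
}

#' Draw Monte-Carlo transformation samples by reparameterization
#'
#' `T^(s) = mu + sqrt(var) * eps`, `eps ~ N(0, I)`; seeded and
#' reproducible, and the global RNG state is restored on exit.
#'
#' @param out list with `mean` and `var` arrays from [bayesian_head()]
#'   (values, not nodes)
#' @param S number of samples (>= 1)
#' @param seed RNG seed
#' @return list of S displacement arrays `(3, gw, gh, gd)`
#' @export
sample_transform <- function(out, S, seed = 1L) {
  if (S < 1L) stop("S must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mu <- val(out$mean); sd <- sqrt(val(out$var))
  lapply(seq_len(S), function(s)
    mu + sd * array(stats::rnorm(length(mu)), dim(mu)))
}

# node-level sampling for training (eps drawn by caller's RNG)
sample_transform_node <- function(mean_node, var_node, S) {
  sdn <- ad_sqrt(var_node)
  lapply(seq_len(S), function(s) {
    eps <- array(stats::rnorm(length(val(mean_node))), dim(val(mean_node)))
    ad_add(mean_node, ad_mul(sdn, eps))
  })
}

#' Full forward pass of the registration network
#'
#' Composes encode, project, decode, the Bayesian head and upsampling of
#' the mean field. In inference mode no sampling occurs and the dense
#' field is deterministic.
#'
#' @param fixed,moving `image_volume`s or arrays of identical shape
#' @param grid_size 3 ints; any size >= 2 per axis works with the same
#'   weights
#' @param cfg,weights as in [encode()]
#' @param upsampler an `upsampler_config`
#' @param tape optional tape for training (weights must then be nodes)
#' @return list: `bayes` (mean/var arrays or nodes), `dense`
#'   (`(3, W, H, D)` displacement of the mean field), `grid`, `attn`
#' @export
gridreg_forward <- function(fixed, moving, grid_size, cfg, weights,
                            upsampler = upsampler_config(), tape = NULL) {
  shp <- dim(as_arr(fixed))
  grid <- make_control_grid(shp, grid_size)
  pyr <- encode(fixed, moving, cfg, weights, tape)
  dec <- decode(pyr, grid, cfg, weights)
  bay <- bayesian_head(dec$features_matrix, grid, weights,
                       gain = cfg$head_gain %||% 1)
  dense <- upsample(bay$mean, shp, upsampler)
  list(bayes = bay, dense = dense, grid = grid, attn = dec$attn)
}
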