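test_that("encoder doubles channels and halves spatial dims per level", {
  cfg <- network_config(base_channels = 16L, num_layers = 5L)
  w <- init_weights(cfg)
  fx <- rand_volume(32, 101); mv <- rand_volume(32, 102)
  pyr <- encode(fx, mv, cfg, w)
  chans <- sapply(pyr, function(p) dim(p)[1])
  sizes <- sapply(pyr, function(p) dim(p)[2])
  expect_equal(chans, c(16, 32, 64, 128, 256))
  expect_equal(sizes, c(16, 8, 4, 2, 1))
  # deterministic under identical weights and inputs
  pyr2 <- encode(fx, mv, cfg, w)
  expect_identical(pyr[[5]], pyr2[[5]])
  expect_error(encode(rand_volume(16), rand_volume(16), cfg, w),
               "configuration error")
})

test_that("token projection yields a fixed token count at every level", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  pyr <- encode(rand_volume(16, 103), rand_volume(16, 104), cfg, w)
  np <- prod(cfg$proj_spatial)
  tk1 <- project_tokens(pyr[[1]], 1, cfg, w)
  tk3 <- project_tokens(pyr[[3]], 3, cfg, w)
  expect_equal(dim(tk1), c(np, cfg$proj_channels))
  expect_equal(dim(tk3), c(np, cfg$proj_channels))
  expect_false(isTRUE(all.equal(tk1, tk3)))
  # zero features map to the bias + positional pattern, finite
  tz <- project_tokens(array(0, dim(pyr[[2]])), 2, cfg, w)
  expect_true(all(is.finite(tz)))
})

test_that("positional encodings are cached, injective and zero-anchored", {
  pe1 <- positional_encoding(matrix(c(0.2, 0.4, 0.8), 1), 12)
  pe2 <- positional_encoding(matrix(c(0.2, 0.4, 0.8), 1), 12)
  expect_identical(pe1, pe2)
  expect_error(positional_encoding(matrix(0.5, 1, 3), 8), "divisible by 6")
  pe0 <- positional_encoding(matrix(0, 1, 3), 12)
  expect_equal(as.vector(pe0), rep(c(0, 1), 6))
  for (g in c(5, 8, 10, 15)) {
    grid <- make_control_grid(c(32, 32, 32), rep(g, 3))
    pe <- gridreg:::pe_for_grid(grid, 48)
    expect_equal(nrow(unique(pe)), g^3)  # all rows distinct
  }
})

test_that("cross-attention matches the explicit per-head oracle", {
  set.seed(111)
  G <- 8; Np <- 27; H <- 2; d <- 4; Cpe <- 12; Fk <- 10; Cout <- 6
  q <- matrix(rnorm(G * Cpe), G)
  tk <- matrix(rnorm(Np * Fk), Np)
  params <- list(wq = matrix(rnorm(Cpe * H * d), Cpe),
                 wk = matrix(rnorm(Fk * H * d), Fk),
                 wv = matrix(rnorm(Fk * H * d), Fk),
                 wo = matrix(rnorm(H * d * Cout), H * d))
  res <- cross_attention(q, tk, params, H, d)
  expect_lt(max(abs(res$output - attention_oracle(q, tk, params, H, d))), 1e-6)
  for (A in res$attn) expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
})

test_that("single-token attention is the value row broadcast over queries", {
  set.seed(112)
  q <- matrix(rnorm(5 * 6), 5)
  tk <- matrix(rnorm(1 * 4), 1)
  params <- list(wq = matrix(rnorm(6 * 8), 6), wk = matrix(rnorm(4 * 8), 4),
                 wv = matrix(rnorm(4 * 8), 4), wo = matrix(rnorm(8 * 3), 8))
  res <- cross_attention(q, tk, params, 2, 4)
  for (A in res$attn) expect_true(all(A == 1))
  expect_lt(max(abs(sweep(res$output, 2, res$output[1, ]))), 1e-12)
})

test_that("attention is invariant to permuting tokens", {
  set.seed(113)
  cfg <- tiny_cfg()
  q <- matrix(rnorm(4 * cfg$pe_channels), 4)
  tk <- matrix(rnorm(20 * 7), 20)
  params <- list(wq = matrix(rnorm(cfg$pe_channels * 8), cfg$pe_channels),
                 wk = matrix(rnorm(7 * 8), 7), wv = matrix(rnorm(7 * 8), 7),
                 wo = matrix(rnorm(8 * 5), 8))
  o1 <- cross_attention(q, tk, params, 2, 4)$output
  perm <- sample(20)
  o2 <- cross_attention(q, tk[perm, ], params, 2, 4)$output
  expect_lt(max(abs(o1 - o2)), 1e-10)
})

test_that("a degenerate locality mask raises an error", {
  q <- matrix(rnorm(2 * 6), 2)
  tk <- matrix(rnorm(3 * 4), 3)
  params <- list(wq = matrix(rnorm(6 * 4), 6), wk = matrix(rnorm(4 * 4), 4),
                 wv = matrix(rnorm(4 * 4), 4), wo = matrix(rnorm(4 * 2), 4))
  mask <- matrix(c(0, -1e9, -1e9, -1e9, -1e9, -1e9), 2, byrow = TRUE)
  expect_error(cross_attention(q, tk, params, 1, 4, local_mask = mask),
               "degenerate locality")
})

test_that("one weight set decodes every candidate grid size", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  pyr <- encode(rand_volume(16, 121), rand_volume(16, 122), cfg, w)
  for (g in c(3, 5, 8)) {
    grid <- make_control_grid(c(16, 16, 16), rep(g, 3))
    dec <- decode(pyr, grid, cfg, w)
    expect_equal(dim(dec$grid_features), c(cfg$out_channels, g, g, g))
  }
  # degenerate single-point grid (constructed directly, test-only)
  g1 <- structure(list(size = c(1L, 1L, 1L), coords = matrix(7.5, 1, 3),
                       image_shape = c(16L, 16L, 16L),
                       axes = list(7.5, 7.5, 7.5)), class = "control_grid")
  dec <- decode(pyr, g1, cfg, w)
  expect_equal(dim(dec$grid_features), c(cfg$out_channels, 1, 1, 1))
})

test_that("parameter shapes and count are independent of the grid size", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  n0 <- count_params(w)
  fx <- rand_volume(16, 131); mv <- rand_volume(16, 132)
  for (g in c(5, 15)) {
    out <- gridreg_forward(fx, mv, rep(g, 3), cfg, w)
    expect_equal(dim(out$bayes$mean), c(3, g, g, g))
  }
  expect_equal(count_params(w), n0)  # unchanged by any forward pass
})

test_that("Bayesian head produces softplus-positive variances", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  G <- 27
  Z <- matrix(rnorm(G * cfg$out_channels), G)
  grid <- make_control_grid(c(16, 16, 16), c(3, 3, 3))
  out <- bayesian_head(Z, grid, w)
  expect_true(all(out$var > 0))
  expect_equal(dim(out$mean), c(3, 3, 3, 3))
  # softplus fixed points through the head arithmetic
  wz <- w
  wz[["head.eta.w"]] <- wz[["head.eta.w"]] * 0
  wz[["head.eta.b"]] <- c(0, -20, 5)
  oz <- bayesian_head(Z, grid, wz)
  expect_equal(oz$var[1, 1, 1, 1], log(2), tolerance = 1e-9)
  expect_true(oz$var[2, 1, 1, 1] > 0 && oz$var[2, 1, 1, 1] < 1e-8)
})

test_that("reparameterized sampling is seeded and statistically correct", {
  mu <- array(0, c(3, 2, 2, 2))
  vr <- array(1, c(3, 2, 2, 2))
  s1 <- sample_transform(list(mean = mu, var = vr), 3, seed = 5)
  s2 <- sample_transform(list(mean = mu, var = vr), 3, seed = 5)
  expect_identical(s1, s2)
  # degenerate variance -> all samples equal the mean
  mu2 <- array(rnorm(24), c(3, 2, 2, 2))
  s0 <- sample_transform(list(mean = mu2, var = vr * 1e-30), 4, seed = 1)
  for (s in s0) expect_equal(s, mu2, tolerance = 1e-10)
  # law of large numbers at one point
  draws <- sapply(sample_transform(list(mean = mu, var = vr), 1e4, seed = 9),
                  function(s) s[1, 1, 1, 1])
  expect_lt(abs(mean(draws)), 4 / sqrt(1e4))
  expect_lt(abs(var(draws) - 1), 0.1)
})

test_that("inference is deterministic and grid-adaptive", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  fx <- rand_volume(16, 141); mv <- rand_volume(16, 142)
  o1 <- gridreg_forward(fx, mv, c(5, 5, 5), cfg, w)
  o2 <- gridreg_forward(fx, mv, c(5, 5, 5), cfg, w)
  expect_identical(o1$dense, o2$dense)
  o3 <- gridreg_forward(fx, mv, c(8, 8, 8), cfg, w)
  expect_equal(dim(o3$dense), dim(o1$dense))  # same image shape
})

test_that("gradients reach every trainable tensor end to end", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg)
  fx <- rand_volume(16, 151); mv <- rand_volume(16, 152)
  tp <- gridreg:::ad_tape()
  wn <- lapply(w, function(x) gridreg:::ad_param(tp, x))
  out <- gridreg_forward(fx, mv, c(4, 4, 4), cfg, wn, tape = tp)
  set.seed(153)
  samples <- gridreg:::sample_transform_node(out$bayes$mean, out$bayes$var, 2)
  rep <- total_loss(uncertainty_loss(mv, fx, samples, out$bayes$var),
                    NULL, bending_energy(out$dense), loss_weights(),
                    masks_available = FALSE)
  gridreg:::ad_backward(tp, rep$total_node)
  for (nm in names(wn)) {
    expect_false(is.null(wn[[nm]]$grad), info = nm)
    expect_gt(max(abs(wn[[nm]]$grad)), 0, label = paste("grad", nm))
  }
})

test_that("removing the projector still yields a valid forward pass", {
  cfg <- tiny_cfg(projector = FALSE)
  w <- init_weights(cfg)
  expect_false(any(grepl("^proj1\\.", names(w))))  # bottleneck only
  out <- gridreg_forward(rand_volume(16, 161), rand_volume(16, 162),
                         c(5, 5, 5), cfg, w)
  expect_equal(dim(out$bayes$mean), c(3, 5, 5, 5))
  expect_true(all(is.finite(out$dense)))
})

test_that("local attention masks distant tokens but keeps rows stochastic", {
  cfg <- tiny_cfg(local_radius = 0.6)
  w <- init_weights(cfg)
  out <- gridreg_forward(rand_volume(16, 171), rand_volume(16, 172),
                         c(4, 4, 4), cfg, w)
  A <- out$attn[[1]][[1]]
  expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  expect_gt(sum(A < 1e-12), 0)  # some tokens are masked out
})
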