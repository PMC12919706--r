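test_that("trilinear basis is the unit hat", {
  expect_equal(trilinear_basis(3, 3, 2), 1)
  expect_equal(trilinear_basis(4, 3, 2), 0.5)
  expect_equal(trilinear_basis(5.2, 3, 2), 0)
  expect_equal(trilinear_basis(0.8, 3, 2), 0)
  expect_error(trilinear_basis(1, 1, 0), "spacing")
})

test_that("B-spline degree 0 is the half-open indicator", {
  kn <- bspline_knots(5, 0)
  t <- kn$knots
  for (i in 1:5) {
    mid <- (t[i] + t[i + 1]) / 2
    expect_equal(bspline_basis(i, 0, mid, kn), 1)
    if (i < 5) expect_equal(bspline_basis(i, 0, t[i + 1], kn), 0)
  }
  expect_error(bspline_basis(1, 0, 1.2, kn), "domain")
})

test_that("cubic B-spline basis sums to one (partition of unity)", {
  kn <- bspline_knots(7, 3)
  xs <- seq(0.01, 0.99, length.out = 100)
  sums <- sapply(xs, function(x) sum(sapply(1:7, bspline_basis, p = 3, x = x,
                                            knots = kn)))
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("degree-1 B-spline on uniform knots equals the hat function", {
  g <- 5
  kn <- bspline_knots(g, 1)
  xs <- seq(0, 0.999, length.out = 57)
  sp <- 1 / (g - 1)
  for (i in 1:g) {
    bs <- sapply(xs, function(x) bspline_basis(i, 1, x, kn))
    hat <- trilinear_basis(xs, (i - 1) * sp, sp)
    expect_lt(max(abs(bs - hat)), 1e-10)
  }
})

test_that("Gaussian basis: center value, symmetry, positivity", {
  expect_equal(gaussian_basis(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  for (d in c(0.3, 1.7)) {
    expect_equal(gaussian_basis(2 + d, 2, 0.8), gaussian_basis(2 - d, 2, 0.8))
  }
  xs <- seq(-3, 3, by = 0.25)
  expect_lt(max(abs(gaussian_basis(xs, 0, 1) -
                    exp(-xs^2 / 2) / sqrt(2 * pi))), 1e-12)
  expect_error(gaussian_basis(0, 0, -1), "domain")
})

test_that("all modes reproduce constants and match the triple-sum oracle", {
  set.seed(21)
  g <- array(rnorm(3 * 125), c(3, 5, 5, 5))
  cg <- array(rep(c(1, -2, 0.5), 125), c(3, 5, 5, 5))
  for (m in c("trilinear", "bspline", "gauss_deconv")) {
    cfg <- upsampler_config(m)
    u <- upsample(g, c(16, 16, 16), cfg)
    o <- upsample_oracle(g, c(16, 16, 16), cfg)
    # 50 random voxels
    set.seed(22)
    idx <- cbind(sample(16, 50, TRUE), sample(16, 50, TRUE), sample(16, 50, TRUE))
    for (r in 1:50)
      expect_lt(max(abs(u[, idx[r, 1], idx[r, 2], idx[r, 3]] -
                        o[, idx[r, 1], idx[r, 2], idx[r, 3]])), 1e-5)
    uc <- upsample(cg, c(16, 16, 16), cfg)
    expect_lt(max(abs(uc[1, , , ] - 1)), 1e-6)
    expect_lt(max(abs(uc[2, , , ] + 2)), 1e-6)
  }
})

test_that("trilinear upsampling reproduces linear ramps and interpolates", {
  # grid sampling v(x) = 0.2 x along the first axis
  ax <- seq(0, 15, length.out = 4)
  g <- array(0, c(3, 4, 4, 4))
  for (i in 1:4) g[1, i, , ] <- 0.2 * ax[i]
  u <- upsample(g, c(16, 16, 16), upsampler_config("trilinear"))
  expect_lt(max(abs(u[1, , , ] - array(rep(0.2 * (0:15), 16 * 16), c(16, 16, 16)))),
            1e-10)
  # control points on integer voxels: dense field matches control values
  set.seed(3)
  gv <- array(rnorm(3 * 64), c(3, 4, 4, 4))
  u <- upsample(gv, c(16, 16, 16), upsampler_config("trilinear"))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_equal(u[, ax[i] + 1, ax[j] + 1, ax[k] + 1], gv[, i, j, k])
})

test_that("upsampling is linear and the oracle agrees on degenerate grids", {
  set.seed(5)
  g1 <- array(rnorm(3 * 27), c(3, 3, 3, 3))
  g2 <- array(rnorm(3 * 27), c(3, 3, 3, 3))
  for (m in c("trilinear", "bspline", "gauss_deconv")) {
    cfg <- upsampler_config(m)
    lhs <- upsample(2.5 * g1 - 1.3 * g2, c(12, 12, 12), cfg)
    rhs <- 2.5 * upsample(g1, c(12, 12, 12), cfg) -
           1.3 * upsample(g2, c(12, 12, 12), cfg)
    expect_lt(max(abs(lhs - rhs)), 1e-6)
  }
  z <- array(0, c(3, 3, 3, 3))
  expect_equal(upsample_oracle(z, c(8, 8, 8)), array(0, c(3, 8, 8, 8)))
  # single active control point = that basis bump
  b <- z; b[2, 2, 2, 2] <- 1
  cfg <- upsampler_config("trilinear")
  u <- upsample_oracle(b, c(8, 8, 8), cfg)
  xi <- seq(0, 7, length.out = 3)
  w <- sapply(0:7, function(x) trilinear_basis(x, xi[2], 3.5))
  expect_equal(u[2, , , ], outer(outer(w, w), w), tolerance = 1e-12)
})

test_that("upsample gradients match finite differences", {
  set.seed(31)
  g <- array(rnorm(3 * 64, 0, 0.3), c(3, 4, 4, 4))
  mv <- rand_volume(9, 41)
  fx <- rand_volume(9, 42)
  for (m in c("trilinear", "bspline", "gauss_deconv")) {
    cfg <- upsampler_config(m)
    tp <- gridreg:::ad_tape()
    gn <- gridreg:::ad_param(tp, g)
    loss <- similarity_image(gridreg:::ad_warp(mv, upsample(gn, c(9, 9, 9), cfg)), fx)
    gridreg:::ad_backward(tp, loss)
    h <- 1e-5
    set.seed(51)
    for (i in sample(length(g), 6)) {
      gp <- g; gp[i] <- gp[i] + h
      gm <- g; gm[i] <- gm[i] - h
      fd <- (similarity_image(warp(mv, upsample(gp, c(9, 9, 9), cfg)), fx) -
             similarity_image(warp(mv, upsample(gm, c(9, 9, 9), cfg)), fx)) / (2 * h)
      expect_lt(abs(fd - gn$grad[i]) / max(abs(fd), 1e-4), 1e-4)
    }
  }
})

test_that("B-spline upsampling is smoother than trilinear", {
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    g <- array(rnorm(3 * 125), c(3, 5, 5, 5))
    bt <- bending_energy(upsample(g, c(14, 14, 14), upsampler_config("trilinear")))
    bb <- bending_energy(upsample(g, c(14, 14, 14), upsampler_config("bspline")))
    wins <- wins + (bb <= bt)
  }
  expect_gte(wins, 95)
})
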