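test_that("image similarity is voxel-mean squared error", {
  a <- rand_volume(8, 61)
  expect_equal(similarity_image(a, a), 0)
  expect_equal(similarity_image(a + 0.3, a), 0.09, tolerance = 1e-12)
  b <- rand_volume(8, 62)
  # explicit loop oracle
  acc <- 0
  for (z in 1:8) for (y in 1:8) for (x in 1:8) acc <- acc + (a[x, y, z] - b[x, y, z])^2
  expect_equal(similarity_image(a, b), acc / 512, tolerance = 1e-12)
  expect_error(similarity_image(a, rand_volume(7)), "shape")
})

test_that("uncertainty loss reduces to half the mean squared residual at unit variance", {
  set.seed(71)
  mv <- rand_volume(12, 71); fx <- rand_volume(12, 72)
  g <- array(rnorm(3 * 27, 0, 0.4), c(3, 3, 3, 3))
  ones <- array(1, c(3, 3, 3, 3))
  lw <- loss_weights(lambda0 = 0)
  lu <- uncertainty_loss(mv, fx, list(g), ones, upsampler_config(), lw)
  res <- warp(mv, upsample(g, c(12, 12, 12))) - fx
  expect_equal(lu, 0.5 * mean(res^2), tolerance = 1e-10)
})

test_that("zero residual leaves only the log-variance penalty", {
  mv <- rand_volume(10, 73)
  z <- array(0, c(3, 3, 3, 3))
  vg <- array(0.5, c(3, 3, 3, 3))
  lw <- loss_weights(lambda0 = 0.05)
  lu <- uncertainty_loss(mv, mv, list(z), vg, upsampler_config(), lw)
  expect_equal(lu, 0.05 * log(0.5), tolerance = 1e-8)
})

test_that("duplicate Monte-Carlo samples average to the single-sample value", {
  set.seed(75)
  mv <- rand_volume(10, 75); fx <- rand_volume(10, 76)
  g <- array(rnorm(3 * 27, 0, 0.3), c(3, 3, 3, 3))
  vg <- array(0.8, c(3, 3, 3, 3))
  l1 <- uncertainty_loss(mv, fx, list(g), vg)
  l2 <- uncertainty_loss(mv, fx, list(g, g), vg)
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_error(uncertainty_loss(mv, fx, list(g), -vg), "domain")
})

test_that("the loss is stationary in sigma^2 at the heteroscedastic optimum", {
  # constant variance field: loss(s2) = mean(r^2)/(2 s2) + lambda0 log s2,
  # minimized at s2 = mean(r^2) / (2 lambda0)
  set.seed(77)
  mv <- rand_volume(10, 77); fx <- rand_volume(10, 78)
  g <- array(0, c(3, 3, 3, 3))
  lw <- loss_weights(lambda0 = 0.5)
  r2 <- mean((mv - fx)^2)
  opt <- r2 / (2 * 0.5)
  s2s <- opt * exp(seq(-1, 1, length.out = 41))
  ls <- sapply(s2s, function(s2)
    uncertainty_loss(mv, fx, list(g), array(s2, c(3, 3, 3, 3)),
                     upsampler_config(), lw))
  expect_equal(s2s[which.min(ls)], opt, tolerance = 0.06)
})

test_that("Monte-Carlo loss variance shrinks roughly as 1/S", {
  set.seed(79)
  mv <- rand_volume(10, 79); fx <- rand_volume(10, 80)
  mu <- array(rnorm(3 * 27, 0, 0.3), c(3, 3, 3, 3))
  vg <- array(0.4, c(3, 3, 3, 3))
  lw <- loss_weights(lambda0 = 0)
  out <- list(mean = mu, var = vg)
  vars <- sapply(c(1, 4, 16), function(S) {
    ls <- sapply(1:120, function(seed)
      uncertainty_loss(mv, fx, sample_transform(out, S, seed), vg,
                       upsampler_config(), lw))
    var(ls)
  })
  expect_true(vars[1] > vars[2] && vars[2] > vars[3])
  expect_gt(vars[1] / vars[3], 6)
  expect_lt(vars[1] / vars[3], 45)
})

test_that("Dice loss matches hand counts and bounds", {
  m <- array(0, c(8, 8, 8)); m[2:5, 2:5, 2:5] <- 1
  expect_lt(dice_loss(m, m), 1e-5)
  n <- array(0, c(8, 8, 8)); n[6:8, 6:8, 6:8] <- 1
  expect_equal(dice_loss(m, n), 1, tolerance = 1e-6)
  # two 4^3 cubes overlapping in a 2x4x4 slab
  a <- array(0, c(10, 8, 8)); a[1:4, 1:4, 1:4] <- 1
  b <- array(0, c(10, 8, 8)); b[3:6, 1:4, 1:4] <- 1
  expect_equal(dice_loss(a, b), 1 - 64 / 128, tolerance = 1e-6)
  # identity minimizes over random mask pairs
  set.seed(83)
  for (i in 1:10) {
    p <- array(rbinom(216, 1, 0.4), c(6, 6, 6))
    q <- array(rbinom(216, 1, 0.4), c(6, 6, 6))
    expect_lte(dice_loss(p, p), dice_loss(p, q) + 1e-9)
  }
})

test_that("bending energy vanishes on affine fields and matches closed forms", {
  z <- array(0, c(3, 9, 9, 9))
  expect_equal(bending_energy(z), 0)
  set.seed(85)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3); b <- rnorm(3)
    v <- array(0, c(3, 9, 9, 9))
    for (x in 1:9) for (y in 1:9) for (zz in 1:9)
      v[, x, y, zz] <- A %*% c(x - 1, y - 1, zz - 1) + b
    expect_lt(bending_energy(v), 1e-10)
  }
  # t_x = x^2: interior second derivative 2 -> 4 per interior voxel
  q <- array(0, c(3, 9, 9, 9))
  for (x in 1:9) q[1, x, , ] <- (x - 1)^2
  expect_equal(bending_energy(q), 4 * (7 / 9)^3, tolerance = 1e-10)
  expect_equal(bending_energy(q), bending_oracle(q), tolerance = 1e-8)
  # random field vs loop oracle
  v <- array(rnorm(3 * 729, 0, 0.5), c(3, 9, 9, 9))
  expect_equal(bending_energy(v), bending_oracle(v), tolerance = 1e-8)
  expect_error(bending_energy(array(0, c(3, 2, 9, 9))), "dimension")
})

test_that("total loss combines terms per the mask-availability switch", {
  lw <- loss_weights(lambda1 = 1, lambda2 = 3, lambda3 = 2)
  rep <- total_loss(0.5, 0.2, 0.1, lw, masks_available = TRUE)
  expect_equal(rep$total, 1 * 0.5 + 3 * 0.2 + 2 * 0.1, tolerance = 1e-9)
  rep2 <- total_loss(0.5, 0.2, 0.1, lw, masks_available = FALSE)
  expect_equal(rep2$total, 1 * 0.5 + 2 * 0.1, tolerance = 1e-9)  # no Dice term
  expect_equal(rep2$dice_term, 0)
  rep3 <- total_loss(0.4, 0.3, 0.2, loss_weights(lambda1 = 0, lambda2 = 0,
                                                 lambda3 = 0))
  expect_equal(rep3$total, 0)
  expect_equal(rep$total,
               with(rep, 1 * uncertainty_term + 3 * dice_term + 2 * bending_term),
               tolerance = 1e-6)
})
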