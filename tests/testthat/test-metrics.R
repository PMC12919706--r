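test_that("Dice coefficient: identity, disjoint, half overlap, empty conventions", {
  m <- array(0, c(8, 8, 8)); m[2:5, 2:5, 2:5] <- 1
  expect_equal(dice_coefficient(m, m), 1)
  n <- array(0, c(8, 8, 8)); n[6:8, 6:8, 6:8] <- 1
  expect_equal(dice_coefficient(m, n), 0)
  a <- array(0, c(10, 8, 8)); a[1:4, 1:4, 1:4] <- 1
  b <- array(0, c(10, 8, 8)); b[3:6, 1:4, 1:4] <- 1
  expect_equal(dice_coefficient(a, b), 0.5)
  e <- array(0, c(8, 8, 8))
  expect_equal(dice_coefficient(e, e), 1)
  expect_equal(dice_coefficient(e, m), 0)
})

test_that("Dice coefficient complements the Dice loss on binary masks", {
  set.seed(91)
  for (i in 1:5) {
    p <- array(rbinom(512, 1, 0.3), c(8, 8, 8))
    q <- array(rbinom(512, 1, 0.3), c(8, 8, 8))
    if (sum(p) + sum(q) == 0) next
    expect_equal(dice_coefficient(p, q), 1 - dice_loss(p, q, eps = 1e-12),
                 tolerance = 1e-9)
  }
})

test_that("centroid distance: translation and landmark means", {
  m <- array(0, c(16, 16, 16)); m[4:6, 4:6, 4:6] <- 1
  expect_equal(centroid_distance(mask_volume(m), mask_volume(m)), 0)
  n <- array(0, c(16, 16, 16)); n[7:9, 8:10, 4:6] <- 1  # shifted (3,4,0)
  expect_equal(centroid_distance(mask_volume(m), mask_volume(n)), 5.0)
  # anisotropic spacing enters before the norm
  expect_equal(centroid_distance(mask_volume(m, spacing = c(2, 1, 1)),
                                 mask_volume(n, spacing = c(2, 1, 1))),
               sqrt(36 + 16))
  # landmarks displaced by 1 mm and 3 mm -> mean 2 mm
  la <- landmark_set(rbind(c(2, 2, 2), c(5, 5, 5)))
  lb <- landmark_set(rbind(c(3, 2, 2), c(5, 8, 5)))
  expect_equal(centroid_distance(la, lb), 2.0)
  expect_error(centroid_distance(mask_volume(array(0, c(4, 4, 4))),
                                 mask_volume(m[1:4, 1:4, 1:4])), "centroid")
})

test_that("centroid distance is invariant to consistent relabeling", {
  set.seed(93)
  pa <- matrix(runif(15, 0, 10), 5)
  pb <- pa + matrix(rnorm(15), 5)
  perm <- sample(5)
  d1 <- centroid_distance(landmark_set(pa), landmark_set(pb))
  d2 <- centroid_distance(landmark_set(pa[perm, ]), landmark_set(pb[perm, ]))
  expect_equal(d1, d2)
})

test_that("Jacobian statistics: identity, uniform expansion, reflection", {
  z <- array(0, c(3, 8, 8, 8))
  js <- jacobian_stats(z)
  expect_true(all(abs(js$det_map - 1) < 1e-12))
  expect_equal(js$logdet_mean, 0)
  expect_equal(js$folding_rate, 0)

  # T(x) = 0.1 x per axis -> det = 1.1^3 everywhere
  v <- array(0, c(3, 8, 8, 8))
  for (x in 1:8) v[1, x, , ] <- 0.1 * (x - 1)
  for (y in 1:8) v[2, , y, ] <- 0.1 * (y - 1)
  for (zz in 1:8) v[3, , , zz] <- 0.1 * (zz - 1)
  js <- jacobian_stats(v)
  expect_equal(max(abs(js$det_map - 1.331)), 0, tolerance = 1e-9)
  expect_equal(js$logdet_mean, 3 * log(1.1), tolerance = 1e-9)

  # reflection T_x = -2x: det = -1 everywhere -> 100% folding
  r <- array(0, c(3, 8, 8, 8))
  for (x in 1:8) r[1, x, , ] <- -2 * (x - 1)
  js <- jacobian_stats(r)
  expect_true(all(js$det_map < 0))
  expect_equal(js$folding_rate, 100)
})

test_that("smooth coarse-grid fields under half the spacing never fold", {
  # smooth random control fields (3-tap kernel) scaled to just below half
  # the control spacing: the regularity the coarse parameterization buys
  sm <- function(n) {
    M <- diag(n) * 0.5
    for (i in seq_len(n)) {
      if (i > 1) M[i, i - 1] <- 0.25
      if (i < n) M[i, i + 1] <- 0.25
    }
    M / rowSums(M)
  }
  grid <- make_control_grid(c(16, 16, 16), c(4, 4, 4))
  half <- min(grid_spacing(grid)) / 2
  folds <- 0
  for (s in 1:100) {
    set.seed(s)
    v <- array(rnorm(3 * 64), c(3, 4, 4, 4))
    v <- gridreg:::ad_axismats(v, sm(4), sm(4), sm(4))
    v <- v * (0.95 * half / max(abs(v)))
    folds <- folds + (jacobian_stats(upsample(v, c(16, 16, 16)))$folding_rate > 0)
  }
  expect_lte(folds, 1)
})
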