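test_that("local NCC scores identity and affine intensity maps as 1", {
  # full-variance noise: every window has non-degenerate local variance
  v <- volume3d(rand_vol(c(12, 12, 12), seed = 31))
  cfg <- loss_config(ncc_window = 5)
  expect_equal(local_ncc(v, v, cfg), 1, tolerance = 1e-6)
  w <- volume3d(2 * v$data + 3)
  expect_equal(local_ncc(v, w, cfg), 1, tolerance = 1e-6)
  # symmetry
  u <- volume3d(rand_vol(c(12, 12, 12), seed = 32))
  expect_equal(local_ncc(v, u, cfg), local_ncc(u, v, cfg),
               tolerance = 1e-12)
  expect_error(local_ncc(v, u, loss_config(ncc_window = 13)), "window")
  expect_error(loss_config(ncc_window = 4), "odd")
})

test_that("the centered window matches a direct evaluation of the correlation", {
  set.seed(33)
  f <- rand_vol(c(9, 9, 9)); m <- rand_vol(c(9, 9, 9))
  cfg <- loss_config(ncc_window = 9)
  cc <- local_ncc_map(f, m, cfg)
  # brute-force sums for the full window centered at (5,5,5)
  sf <- sum(f); sm <- sum(m); n <- 729
  cross <- sum(f * m) - sf * sm / n
  varf <- sum(f^2) - sf^2 / n
  varm <- sum(m^2) - sm^2 / n
  expect_equal(cc[5, 5, 5], cross^2 / (varf * varm + cfg$epsilon),
               tolerance = 1e-12)
})

test_that("gradient-L2 smoothness has its closed-form values", {
  shape <- c(8L, 8L, 8L)
  # any uniform translation scores exactly zero
  u <- array(0, dim = c(shape, 3)); u[, , , 2] <- 1.25
  expect_identical(grad_l2(u), 0)
  # unit slope along one axis in one component scores exactly one
  us <- array(0, dim = c(shape, 3))
  us[, , , 3] <- array(ns$grid_positions(shape)[, 3], dim = shape)
  expect_equal(grad_l2(us), 1)
  # quadratic homogeneity and translation invariance
  set.seed(34)
  ur <- array(rnorm(prod(shape) * 3), dim = c(shape, 3))
  expect_equal(grad_l2(2 * ur), 4 * grad_l2(ur), tolerance = 1e-12)
  shifted <- ur; shifted[, , , 1] <- shifted[, , , 1] + 5
  expect_equal(grad_l2(shifted), grad_l2(ur), tolerance = 1e-10)
})

test_that("registration energy behaves at its anchors", {
  v <- volume3d(rand_vol(c(16, 16, 16), seed = 35))
  cfg <- loss_config()
  z <- zero_field(c(16, 16, 16))
  expect_equal(energy(v, v, z, cfg), 0, tolerance = 1e-6)
  # non-negative for arbitrary fields
  set.seed(36)
  u <- dispfield(array(rnorm(16^3 * 3, sd = 0.5), dim = c(16, 16, 16, 3)))
  expect_gte(energy(v, v, u, cfg), 0)
  # a synthetic pair scores better at the true field than at zero
  case <- tiny_case(c(16L, 16L, 16L), seed = 37)
  e_gt <- energy(case$fixed, case$moving, case$gt_field, cfg)
  e_0 <- energy(case$fixed, case$moving, zero_field(c(16, 16, 16)), cfg)
  expect_lt(e_gt, e_0)
})

test_that("supervised field loss has its closed forms", {
  cfg <- loss_config()
  set.seed(38)
  u <- array(rnorm(6^3 * 3), dim = c(6, 6, 6, 3))
  expect_equal(supervised_loss(u, u, cfg), cfg$lambda_reg * grad_l2(u))
  # uniform 1-voxel offset in one component: MSE term 1/3, reg unchanged
  uc <- array(0.5, dim = c(6, 6, 6, 3))
  v <- uc; v[, , , 2] <- v[, , , 2] + 1
  expect_equal(supervised_loss(v, uc, cfg), 1 / 3)
  expect_equal(supervised_loss(u, uc, loss_config(lambda_reg = 0)),
               mean((u - uc)^2))
  expect_error(supervised_loss(u, array(0, c(5, 5, 5, 3))), "differ")
})

test_that("SSIM scores self-similarity 1 and penalizes anti-correlation", {
  v <- textured_vol(c(10, 10, 10), seed = 39)
  expect_equal(ssim3d(v, v), 1, tolerance = 1e-9)
  anti <- volume3d(max(v$data) + min(v$data) - v$data)
  expect_lt(ssim3d(v, anti), 1)
  expect_gte(ssim3d(v, anti), -1)
})

test_that("SSIM matches a direct windowed evaluation", {
  set.seed(40)
  a <- rand_vol(c(6, 6, 6)); b <- rand_vol(c(6, 6, 6))
  got <- ssim3d(a, b)
  # independent evaluation: explicit Gaussian-weighted sums per voxel
  k <- ns$gauss_kernel(1.5)
  r <- (length(k) - 1) / 2
  C1 <- 1e-4; C2 <- 9e-4
  vals <- array(0, dim = dim(a))
  for (d in 1:6) for (h in 1:6) for (w in 1:6) {
    ws <- 0; ma <- 0; mb <- 0; aa <- 0; bb <- 0; ab <- 0
    for (dd in -r:r) for (dh in -r:r) for (dw in -r:r) {
      i <- c(d + dd, h + dh, w + dw)
      if (any(i < 1) || any(i > 6)) next
      wt <- k[dd + r + 1] * k[dh + r + 1] * k[dw + r + 1]
      ws <- ws + wt
      ma <- ma + wt * a[i[1], i[2], i[3]]
      mb <- mb + wt * b[i[1], i[2], i[3]]
      aa <- aa + wt * a[i[1], i[2], i[3]]^2
      bb <- bb + wt * b[i[1], i[2], i[3]]^2
      ab <- ab + wt * a[i[1], i[2], i[3]] * b[i[1], i[2], i[3]]
    }
    ma <- ma / ws; mb <- mb / ws
    va <- aa / ws - ma^2; vb <- bb / ws - mb^2; cab <- ab / ws - ma * mb
    vals[d, h, w] <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  expect_equal(got, mean(vals), tolerance = 1e-10)
})

test_that("loss gradients agree with finite differences", {
  set.seed(41)
  f <- rand_vol(c(10, 10, 10)); m <- rand_vol(c(10, 10, 10))
  cfg <- loss_config(ncc_window = 5)
  g <- ns$local_ncc_grad(f, m, cfg)
  for (i in sample(length(m), 5)) {
    old <- m[i]
    m[i] <- old + 1e-6; lp <- local_ncc(f, m, cfg)
    m[i] <- old - 1e-6; lm <- local_ncc(f, m, cfg)
    m[i] <- old
    expect_equal(g$grad[i], (lp - lm) / 2e-6, tolerance = 1e-4)
  }
  sg <- ns$ssim3d_grad(f, m)
  for (i in sample(length(m), 5)) {
    old <- m[i]
    m[i] <- old + 1e-6; lp <- ssim3d(f, m)
    m[i] <- old - 1e-6; lm <- ssim3d(f, m)
    m[i] <- old
    expect_equal(sg$grad[i], (lp - lm) / 2e-6, tolerance = 1e-4)
  }
  u <- array(rnorm(10^3 * 3, sd = 0.4), dim = c(10, 10, 10, 3))
  cfg <- loss_config(ncc_window = 5, ssim_weight = 0.3)  # exercise the hook
  eg <- ns$energy_grad(volume3d(f), volume3d(m), dispfield(u), cfg)
  for (i in sample(length(u), 5)) {
    old <- u[i]
    u[i] <- old + 1e-5
    lp <- energy(volume3d(f), volume3d(m), dispfield(u), cfg)
    u[i] <- old - 1e-5
    lm <- energy(volume3d(f), volume3d(m), dispfield(u), cfg)
    u[i] <- old
    expect_equal(eg$grad[i], (lp - lm) / 2e-5, tolerance = 1e-3)
  }
})

test_that("Dice overlap handles identity, disjoint and counted cases", {
  shape <- c(6L, 6L, 6L)
  a <- array(0L, dim = shape); a[2:3, 2:3, 2] <- 1L; a[5, 5, 5] <- 2L
  da <- labelmap3d(a)
  expect_equal(dice_score(da, da)$per_label, c(`1` = 1, `2` = 1))
  expect_equal(dice_score(da, da)$mean, 1)
  # disjoint single-label masks
  b1 <- array(0L, dim = shape); b1[1, 1, 1] <- 1L
  b2 <- array(0L, dim = shape); b2[6, 6, 6] <- 1L
  expect_equal(dice_score(labelmap3d(b1), labelmap3d(b2))$mean, 0)
  # masks of sizes 4 and 6 overlapping in 3 voxels: 2*3/(4+6) = 0.6
  c1 <- array(0L, dim = shape); c1[1:4, 1, 1] <- 1L
  c2 <- array(0L, dim = shape); c2[2:4, 1, 1] <- 1L; c2[1:3, 2, 1] <- 1L
  expect_equal(dice_score(labelmap3d(c1), labelmap3d(c2))$mean, 0.6)
  # symmetry, range, and the no-foreground error
  expect_equal(dice_score(labelmap3d(c1), labelmap3d(c2))$mean,
               dice_score(labelmap3d(c2), labelmap3d(c1))$mean)
  z <- labelmap3d(array(0L, dim = shape))
  expect_error(dice_score(z, z), "foreground")
})
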