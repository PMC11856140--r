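zero_offsets <- function(half = 4L) {
  list(plus = matrix(0, half, 2), minus = matrix(0, half, 2))
}

test_that("snake positions degenerate to straight axis segments", {
  spec <- snake_kernel_spec()
  p <- snake_positions(c(5, 5, 5), zero_offsets(), "x", spec)
  expect_equal(p, cbind(5, 5, 5 + (-4:4)))
  py <- snake_positions(c(5, 5, 5), zero_offsets(), "y", spec)
  expect_equal(py, cbind(5, 5 + (-4:4), 5))
  pz <- snake_positions(c(5, 5, 5), zero_offsets(), "z", spec)
  expect_equal(pz, cbind(5 + (-4:4), 5, 5))
})

test_that("lateral coordinates accumulate offsets outward from the center", {
  spec <- snake_kernel_spec()
  off <- zero_offsets()
  off$plus[, 2] <- c(0.5, -0.25, 0.1, 0.3)   # second lateral of the x-snake
  p <- snake_positions(c(0, 0, 0), off, "x", spec)
  expect_equal(p[6:9, 2], c(0.5, 0.25, 0.35, 0.65))  # running sums
  expect_equal(p[6:9, 1], rep(0, 4))
  # saturated offsets: lateral displacement (c, c), maximal reach (4, 4)
  sat <- list(plus = matrix(1, 4, 2), minus = matrix(1, 4, 2))
  ps <- snake_positions(c(0, 0, 0), sat, "x", spec)
  expect_equal(ps[9, 1:2], c(4, 4))
  expect_equal(ps[1, 1:2], c(4, 4))
  expect_error(snake_positions(c(0, 0, 0),
                               list(plus = matrix(2, 4, 2),
                                    minus = matrix(0, 4, 2)), "x", spec),
               "max_step")
})

test_that("receptive extent formula matches exhaustive enumeration", {
  expect_equal(unname(receptive_extent(snake_kernel_spec())), c(9, 9, 9))
  expect_equal(unname(receptive_extent(snake_kernel_spec(3, 1))), c(3, 3, 3))
  spec <- snake_kernel_spec(9, 0.5)
  expect_equal(unname(receptive_extent(spec)), c(9, 5, 5))
  # enumeration: all positions with offsets saturated at +/- bound
  reach <- c(0, 0, 0)
  for (sgn in c(-1, 1)) {
    sat <- list(plus = matrix(sgn * spec$max_step, spec$half, 2),
                minus = matrix(sgn * spec$max_step, spec$half, 2))
    p <- snake_positions(c(0, 0, 0), sat, "x", spec)
    reach <- pmax(reach, apply(abs(p), 2, max))
  }
  expect_equal(2 * reach + 1, c(5, 5, 9))  # (d, h, w) for the x-snake
})

test_that("offset prediction is bounded, zero for zero weights, deterministic", {
  spec <- snake_kernel_spec()
  feats <- rand_vol(c(4, 4, 4), seed = 5)
  dim(feats) <- c(4, 4, 4, 1)
  nch <- ns$snake_n_offset_channels(spec)
  w0 <- list(w = array(0, dim = c(3, 3, 3, 1, nch)), b = numeric(nch))
  off0 <- predict_offsets(feats, w0, spec)
  expect_true(all(off0$delta == 0))
  set.seed(6)
  wr <- list(w = array(rnorm(27 * nch, sd = 3), dim = c(3, 3, 3, 1, nch)),
             b = rnorm(nch))
  off1 <- predict_offsets(feats, wr, spec)
  expect_true(max(abs(off1$delta)) <= spec$max_step)
  off2 <- predict_offsets(feats, wr, spec)
  expect_identical(off1$delta, off2$delta)
})

test_that("snake convolution reduces to identity and preserves constants", {
  spec <- snake_kernel_spec()
  shape <- c(6L, 6L, 6L)
  x <- rand_vol(shape, seed = 7); dim(x) <- c(shape, 1L)
  nch <- ns$snake_n_offset_channels(spec)
  off <- snake_offsets(array(0, dim = c(shape, nch)), spec)
  # centered delta taps: output equals input after mean fusion
  delta_tap <- array(0, dim = c(9, 1, 1)); delta_tap[5, 1, 1] <- 1
  w_id <- list(x = delta_tap, y = delta_tap, z = delta_tap)
  expect_equal(dsconv3d(x, w_id, off, spec)[, , , 1], x[, , , 1])
  # uniform 1/9 taps on a constant input of 7
  w_u <- list(x = array(1 / 9, c(9, 1, 1)), y = array(1 / 9, c(9, 1, 1)),
              z = array(1 / 9, c(9, 1, 1)))
  const7 <- array(7, dim = c(shape, 1L))
  expect_equal(dsconv3d(const7, w_u, off, spec),
               array(7, dim = c(shape, 1L)), tolerance = 1e-12)
})

test_that("fast path equals the gather-and-sum reference on random cases", {
  spec <- snake_kernel_spec(5, 0.8)
  shape <- c(6L, 6L, 6L)
  nch <- ns$snake_n_offset_channels(spec)
  for (s in 1:5) {
    set.seed(100 + s)
    x <- array(rnorm(prod(shape) * 2), dim = c(shape, 2L))
    off <- snake_offsets(array(rnorm(prod(shape) * nch),
                               dim = c(shape, nch)), spec)
    w <- list(x = array(rnorm(5 * 2 * 2), c(5, 2, 2)),
              y = array(rnorm(5 * 2 * 2), c(5, 2, 2)),
              z = array(rnorm(5 * 2 * 2), c(5, 2, 2)), b = rnorm(2))
    expect_lt(max(abs(dsconv3d(x, w, off, spec) -
                      dsconv3d_reference(x, w, off, spec))), 1e-5)
  }
})

test_that("zero offsets give an exact sum of axis-aligned 1-D convolutions", {
  spec <- snake_kernel_spec(5, 1, fusion = "sum")
  shape <- c(7L, 7L, 7L)
  x <- rand_vol(shape, seed = 11)
  nch <- ns$snake_n_offset_channels(spec)
  off <- snake_offsets(array(0, dim = c(shape, nch)), spec)
  taps <- list(x = rnorm(5), y = rnorm(5), z = rnorm(5))
  w <- lapply(taps, function(t) array(t, c(5, 1, 1)))
  got <- dsconv3d(array(x, c(shape, 1L)), w, off, spec)[, , , 1]
  # independent separable oracle: clamped 1-D convolution along each axis
  conv1d_axis <- function(v, t, axis) {
    out <- array(0, dim = dim(v))
    n <- dim(v)[axis]
    for (k in -2:2) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      sl <- switch(axis, v[idx, , ], v[, idx, ], v[, , idx])
      out <- out + t[k + 3] * sl
    }
    out
  }
  want <- conv1d_axis(x, taps$x, 3) + conv1d_axis(x, taps$y, 2) +
    conv1d_axis(x, taps$z, 1)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("snake convolution is linear in its input", {
  spec <- snake_kernel_spec(5, 0.6)
  shape <- c(5L, 5L, 5L)
  nch <- ns$snake_n_offset_channels(spec)
  set.seed(13)
  off <- snake_offsets(array(rnorm(prod(shape) * nch), c(shape, nch)),
                       spec)
  w <- list(x = array(rnorm(5), c(5, 1, 1)), y = array(rnorm(5), c(5, 1, 1)),
            z = array(rnorm(5), c(5, 1, 1)))
  u <- array(rnorm(prod(shape)), c(shape, 1L))
  v <- array(rnorm(prod(shape)), c(shape, 1L))
  lhs <- dsconv3d(2 * u - 3 * v, w, off, spec)
  rhs <- 2 * dsconv3d(u, w, off, spec) - 3 * dsconv3d(v, w, off, spec)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("interior response is equivariant to integer translation", {
  spec <- snake_kernel_spec(5, 0.5)
  shape <- c(10L, 10L, 10L)
  nch <- ns$snake_n_offset_channels(spec)
  set.seed(14)
  # translation-invariant (constant) offset field
  const_off <- rnorm(nch, sd = 0.3)
  off <- snake_offsets(array(rep(const_off, each = prod(shape)),
                             c(shape, nch)), spec)
  w <- list(x = array(rnorm(5), c(5, 1, 1)), y = array(rnorm(5), c(5, 1, 1)),
            z = array(rnorm(5), c(5, 1, 1)))
  x <- array(0, dim = c(shape, 1L))
  x[, , , 1] <- rand_vol(shape)
  xs <- array(0, dim = c(shape, 1L))
  xs[, , 2:10, 1] <- x[, , 1:9, 1]          # shift content by +1 along w
  y <- dsconv3d(x, w, off, spec)
  ys <- dsconv3d(xs, w, off, spec)
  expect_lt(max(abs(ys[4:7, 4:7, 5:7, 1] - y[4:7, 4:7, 4:6, 1])), 1e-10)
})

test_that("the trainable snake layer has exact gradients", {
  set.seed(15)
  ly <- ns$layer_dsconv3d(2L, 2L, snake_kernel_spec(5, 0.8))
  for (p in ns$collect_params(ly$offconv))
    p$value[] <- rnorm(length(p$value), sd = 0.1)
  x <- array(rnorm(5 * 5 * 5 * 2), dim = c(5, 5, 5, 2))
  errs <- fd_grad_check(ly, x, seed = 16, n_checks = 4)
  expect_lt(max(errs), 1e-3)
  expect_lt(median(errs), 1e-5)
})
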