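test_that("window partition and reverse form a bijection for all shifts", {
  set.seed(20)
  for (grid in list(c(4L, 4L, 4L), c(4L, 2L, 6L))) {
    t <- array(rnorm(prod(grid) * 3), dim = c(grid, 3L))
    for (sd_ in 0:1) for (sh in 0:1) for (sw in 0:1) {
      shift <- c(sd_, sh, sw)
      wt <- window_partition(t, c(2L, 2L, 2L), shift)
      back <- window_reverse(wt, c(2L, 2L, 2L), shift)
      expect_equal(back, t, tolerance = 0)
    }
    # number of windows = prod(dim / window)
    wt <- window_partition(t, c(2L, 2L, 2L))
    expect_equal(dim(wt)[3], prod(grid %/% 2L))
    expect_equal(dim(wt)[1], 8L)
  }
  expect_error(window_partition(array(0, c(3, 4, 4, 1)), c(2, 2, 2)),
               "multiples")
})

test_that("cyclic shift wraps tokens to the expected windows", {
  grid <- c(4L, 4L, 4L)
  t <- array(seq_len(64), dim = c(grid, 1L))
  wt <- window_partition(t, c(2L, 2L, 2L), shift = c(1L, 1L, 1L))
  # shifted grid: position (0,0,0) holds the former (1,1,1); the former
  # (0,0,0) token wraps to shifted position (3,3,3), i.e. the last window
  expect_equal(wt[1, 1, 1], t[2, 2, 2, 1])
  last_window <- wt[, 1, dim(wt)[3]]
  expect_true(t[1, 1, 1, 1] %in% last_window)
  expect_equal(last_window[8], t[1, 1, 1, 1])  # tap (1,1,1) of that window
})

test_that("patch embedding projects flattened 4x4x4 2-channel patches", {
  set.seed(21)
  ly <- ns$layer_patch_embed(16L)
  x <- array(rnorm(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
  tok <- ly$fwd(x)
  expect_equal(dim(tok), c(2L, 2L, 2L, 16L))
  expect_error(ly$fwd(array(0, c(8, 8, 8, 1))), "pair")
  expect_error(ly$fwd(array(0, c(6, 8, 8, 2))), "divisible")
  # patch-loop oracle using the layer's own weights
  w <- ly$conv$params$w$value   # (4,4,4,2,16)
  b <- ly$conv$params$b$value
  for (pd in 1:2) for (ph in 1:2) for (pw in 1:2) {
    patch <- x[(pd - 1) * 4 + 1:4, (ph - 1) * 4 + 1:4,
               (pw - 1) * 4 + 1:4, , drop = FALSE]
    want <- drop(matrix(patch, 1) %*% matrix(w, ncol = 16)) + b
    expect_equal(tok[pd, ph, pw, ], want, tolerance = 1e-12)
  }
  # constant input with any projection: all tokens equal
  xc <- array(1, dim = c(8, 8, 8, 2))
  tc <- ly$fwd(xc)
  expect_lt(max(abs(sweep(matrix(tc, 8, 16), 2, tc[1, 1, 1, ], "-"))),
            1e-12)
})

test_that("attention over a single token is the value-projection path", {
  set.seed(22)
  ly <- ns$layer_wmsa(4L, 2L, c(1L, 1L, 1L), use_bias = FALSE)
  x <- array(rnorm(4), dim = c(1, 4, 1))
  y <- ly$fwd(x)
  wqkv <- ly$params$wqkv$value; bqkv <- ly$params$bqkv$value
  v <- drop(matrix(x[1, , 1], 1) %*% wqkv[, 9:12]) + bqkv[9:12]
  want <- drop(matrix(v, 1) %*% ly$params$wp$value) + ly$params$bp$value
  expect_equal(y[1, , 1], want, tolerance = 1e-12)
})

test_that("attention weights are row-normalized and match a dense oracle", {
  set.seed(23)
  C <- 4L
  ly <- ns$layer_wmsa(C, 1L, c(1L, 1L, 2L), use_bias = FALSE)
  x <- array(rnorm(2 * C * 3), dim = c(2, C, 3))   # 3 windows, 2 tokens
  y <- ly$fwd(x)
  for (k in 1:3) {
    p <- ly$cache[[k]]$hc[[1]]$p
    expect_equal(rowSums(p), c(1, 1))
    # dense oracle
    xm <- x[, , k]
    qkv <- sweep(xm %*% ly$params$wqkv$value, 2, ly$params$bqkv$value, "+")
    q <- qkv[, 1:4]; kk <- qkv[, 5:8]; v <- qkv[, 9:12]
    a <- q %*% t(kk) / sqrt(4)
    pw <- exp(a) / rowSums(exp(a))
    want <- sweep((pw %*% v) %*% ly$params$wp$value, 2,
                  ly$params$bp$value, "+")
    expect_equal(y[, , k], want, tolerance = 1e-6)
  }
})

test_that("attention is permutation-equivariant without position bias", {
  set.seed(24)
  ly <- ns$layer_wmsa(4L, 2L, c(2L, 2L, 1L), use_bias = FALSE)
  x <- array(rnorm(4 * 4), dim = c(4, 4, 1))
  y <- ly$fwd(x)
  perm <- c(3, 1, 4, 2)
  xp <- x[perm, , , drop = FALSE]
  yp <- ly$fwd(xp)
  expect_equal(yp[, , 1], y[perm, , 1], tolerance = 1e-10)
})

test_that("swin block with zeroed sublayer outputs is the identity", {
  set.seed(25)
  ly <- ns$layer_swin_block(4L, 2L, grid = c(4L, 4L, 4L),
                            window = c(2L, 2L, 2L), shifted = TRUE)
  ly$attn$params$wp$value[] <- 0; ly$attn$params$bp$value[] <- 0
  ly$fc2$params$w$value[] <- 0; ly$fc2$params$b$value[] <- 0
  x <- array(rnorm(64 * 4), dim = c(4, 4, 4, 4))
  expect_equal(ly$fwd(x), x, tolerance = 0)
})

test_that("a degenerate shift equals the unshifted block", {
  set.seed(26)
  # grid equal to the window: only one window per axis, shift forced to 0
  mk <- function(shifted) ns$layer_swin_block(4L, 2L, grid = c(2L, 2L, 2L),
                                              window = c(2L, 2L, 2L),
                                              shifted = shifted)
  set.seed(26); a <- mk(FALSE)
  set.seed(26); b <- mk(TRUE)
  x <- array(rnorm(8 * 4), dim = c(2, 2, 2, 4))
  expect_equal(a$fwd(x), b$fwd(x), tolerance = 0)
})

test_that("block output matches the sequential composition of its stages", {
  set.seed(27)
  ly <- ns$layer_swin_block(4L, 2L, grid = c(2L, 2L, 2L),
                            window = c(2L, 2L, 2L), shifted = FALSE)
  x <- array(rnorm(8 * 4), dim = c(2, 2, 2, 4))
  y <- ly$fwd(x)
  # independent step-by-step composition with the block's own parameters
  xm <- matrix(x, 8, 4)
  ln <- function(m, g, b) {
    mu <- rowMeans(m); xc <- m - mu
    istd <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xc * istd, 2, g, "*"), 2, b, "+")
  }
  h1 <- ln(xm, ly$ln1$params$gamma$value, ly$ln1$params$beta$value)
  wt <- window_partition(array(h1, c(2, 2, 2, 4)), c(2, 2, 2))
  at <- ly$attn$fwd(wt)
  x2 <- xm + matrix(window_reverse(at, c(2, 2, 2)), 8, 4)
  h2 <- ln(x2, ly$ln2$params$gamma$value, ly$ln2$params$beta$value)
  m1 <- sweep(h2 %*% ly$fc1$params$w$value, 2, ly$fc1$params$b$value, "+")
  m2 <- sweep(ns$gelu(m1) %*% ly$fc2$params$w$value, 2,
              ly$fc2$params$b$value, "+")
  want <- array(x2 + m2, dim = c(2, 2, 2, 4))
  expect_equal(y, want, tolerance = 1e-10)
})

test_that("patch merging concatenates neighbourhoods in documented scan order", {
  set.seed(28)
  ly <- ns$layer_patch_merge(8L)
  x <- array(rnorm(4 * 4 * 4 * 8), dim = c(4, 4, 4, 8))
  y <- ly$fwd(x)
  expect_equal(dim(y), c(2L, 2L, 2L, 16L))
  w <- ly$conv$params$w$value   # (2,2,2,C,2C): d fastest, channel slowest
  b <- ly$conv$params$b$value
  for (pd in 1:2) for (ph in 1:2) for (pw in 1:2) {
    nb <- x[(pd - 1) * 2 + 1:2, (ph - 1) * 2 + 1:2, (pw - 1) * 2 + 1:2, ,
            drop = FALSE]
    want <- drop(matrix(nb, 1) %*% matrix(w, ncol = 16)) + b
    expect_equal(y[pd, ph, pw, ], want, tolerance = 1e-12)
  }
  expect_error(ly$fwd(array(0, c(3, 4, 4, 8))), "even")
})

test_that("merge then expand with mutually inverse projections is the identity", {
  set.seed(29)
  C <- 4L
  me <- ns$layer_patch_merge(C)
  ex <- ns$layer_patch_expand(2L * C)
  # expand projection Q: 2C -> 8 * C; choose merge projection P as its
  # left inverse and feed tokens from the image of Q
  Q <- ex$lin$params$w$value                      # (2C, 4C=8*C/2... here 8C/2)
  ex$lin$params$b$value[] <- 0
  P <- t(Q) %*% solve(Q %*% t(Q))                 # right inverse: Q' P' ...
  me$conv$params$w$value[] <- P                   # (8C -> 2C) ... see below
  me$conv$params$b$value[] <- 0
  z <- matrix(rnorm(8 * 2 * C), 8, 2 * C)         # low-dim codes per cell
  # tokens = codes expanded through Q, arranged on a 4^3/2 grid of cells
  xg <- ex$fwd(array(z, c(2, 2, 2, 2 * C)))       # (4,4,4,C) in image of Q
  merged <- me$fwd(xg)
  # merging with P recovers the codes; expanding again recovers the tokens
  expect_equal(array(merged, c(8, 2 * C)), z, tolerance = 1e-8)
  expect_equal(ex$fwd(merged), xg, tolerance = 1e-8)
})

test_that("patch expand redistributes channels into 2x2x2 neighbourhoods", {
  set.seed(30)
  ly <- ns$layer_patch_expand(8L)
  x <- array(rnorm(8 * 8), dim = c(2, 2, 2, 8))
  y <- ly$fwd(x)
  expect_equal(dim(y), c(4L, 4L, 4L, 4L))
  lw <- ly$lin$params$w$value; lb <- ly$lin$params$b$value
  proj <- drop(matrix(x[1, 2, 1, ], 1) %*% lw) + lb   # 32 values
  # offset (a,b,e) scans d fastest, channel slowest
  for (a in 0:1) for (b_ in 0:1) for (e in 0:1) {
    idx <- (a + 2 * b_ + 4 * e) + 8 * (0:3) + 1
    expect_equal(y[1 + a, 3 + b_, 1 + e, ], proj[idx], tolerance = 1e-12)
  }
})
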