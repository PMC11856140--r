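# Building-block layers over (D, H, W, C) feature grids, each an environment
# with fwd(x)/bwd(dy) and hand-derived backward passes.  Caches live in the
# layer between fwd and bwd (batch-of-one discipline).

layer_conv3d <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                         zero_init = FALSE) {
  ly <- new.env(parent = emptyenv())
  fan_in <- k^3 * cin
  w <- if (zero_init) array(0, dim = c(k, k, k, cin, cout))
       else init_weight(c(k, k, k, cin, cout), fan_in)
  ly$params <- list(w = new_param(w), b = new_param(numeric(cout)))
  ly$k <- k; ly$stride <- stride; ly$pad <- pad
  ly$cin <- cin; ly$cout <- cout
  ly$fwd <- function(x) {
    dims <- dim(x)
    stopifnot(dims[4] == cin)
    cols <- cpp_im2col(as.vector(x), dims, ly$k, ly$stride, ly$pad)
    wmat <- ly$params$w$value
    dim(wmat) <- c(ly$k^3 * cin, cout)
    y <- cols %*% wmat
    y <- sweep(y, 2L, ly$params$b$value, "+")
    od <- (dims[1:3] + 2L * ly$pad - ly$k) %/% ly$stride + 1L
    ly$cache <- list(cols = cols, dims = dims, od = od)
    array(y, dim = c(od, cout))
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache
    dym <- matrix(dy, nrow = prod(cc$od), ncol = cout)
    ly$params$b$grad <- ly$params$b$grad + colSums(dym)
    dw <- crossprod(cc$cols, dym)
    dim(dw) <- c(ly$k, ly$k, ly$k, cin, cout)
    ly$params$w$grad <- ly$params$w$grad + dw
    wmat <- ly$params$w$value
    dim(wmat) <- c(ly$k^3 * cin, cout)
    dcols <- tcrossprod(dym, wmat)
    dx <- cpp_col2im(dcols, cc$dims, ly$k, ly$stride, ly$pad)
    array(dx, dim = cc$dims)
  }
  ly
}

# Normalization over spatial positions within channel groups; with
# groups = C this is the batch-size-one form of batch normalization.
layer_groupnorm <- function(C, groups = NULL, eps = 1e-5) {
  if (is.null(groups)) {
    groups <- max(which(C %% seq_len(min(8L, C)) == 0L))  # largest divisor <= 8
  }
  stopifnot(C %% groups == 0L)
  ly <- new.env(parent = emptyenv())
  ly$params <- list(gamma = new_param(rep(1, C)),
                    beta = new_param(numeric(C)))
  ly$groups <- groups; ly$C <- C; ly$eps <- eps
  ly$fwd <- function(x) {
    dims <- dim(x)
    nvox <- prod(dims[1:3])
    cg <- C %/% groups
    xm <- matrix(x, nrow = nvox, ncol = C)
    xhat <- matrix(0, nvox, C)
    istd <- numeric(groups)
    for (g in seq_len(groups)) {
      idx <- ((g - 1L) * cg + 1L):(g * cg)
      mu <- mean(xm[, idx])
      v <- mean((xm[, idx] - mu)^2)
      istd[g] <- 1 / sqrt(v + eps)
      xhat[, idx] <- (xm[, idx] - mu) * istd[g]
    }
    y <- sweep(sweep(xhat, 2L, ly$params$gamma$value, "*"), 2L,
               ly$params$beta$value, "+")
    ly$cache <- list(xhat = xhat, istd = istd, dims = dims)
    array(y, dim = dims)
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache
    nvox <- prod(cc$dims[1:3])
    cg <- C %/% groups
    dym <- matrix(dy, nrow = nvox, ncol = C)
    ly$params$gamma$grad <- ly$params$gamma$grad + colSums(dym * cc$xhat)
    ly$params$beta$grad <- ly$params$beta$grad + colSums(dym)
    dxhat <- sweep(dym, 2L, ly$params$gamma$value, "*")
    dx <- matrix(0, nvox, C)
    for (g in seq_len(groups)) {
      idx <- ((g - 1L) * cg + 1L):(g * cg)
      dxh <- dxhat[, idx]; xh <- cc$xhat[, idx]
      dx[, idx] <- cc$istd[g] *
        (dxh - mean(dxh) - xh * mean(dxh * xh))
    }
    array(dx, dim = cc$dims)
  }
  ly
}

layer_relu <- function() {
  ly <- new.env(parent = emptyenv())
  ly$params <- list()
  ly$fwd <- function(x) { ly$cache <- x > 0; x * ly$cache }
  ly$bwd <- function(dy) dy * ly$cache
  ly
}

# conv -> norm -> ReLU, the standard Conv3D block.
layer_conv_block <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                             norm = "group") {
  ly <- new.env(parent = emptyenv())
  ly$conv <- layer_conv3d(cin, cout, k, stride, pad)
  ly$norm <- layer_groupnorm(cout,
                             groups = if (norm == "batch") cout else NULL)
  ly$act <- layer_relu()
  ly$params <- list(conv = ly$conv, norm = ly$norm)
  ly$fwd <- function(x) ly$act$fwd(ly$norm$fwd(ly$conv$fwd(x)))
  ly$bwd <- function(dy) ly$conv$bwd(ly$norm$bwd(ly$act$bwd(dy)))
  ly
}

layer_linear <- function(cin, cout, zero_init = FALSE) {
  ly <- new.env(parent = emptyenv())
  w <- if (zero_init) array(0, dim = c(cin, cout))
       else init_weight(c(cin, cout), cin)
  ly$params <- list(w = new_param(w), b = new_param(numeric(cout)))
  ly$fwd <- function(x) {            # x: N x cin matrix
    ly$cache <- x
    sweep(x %*% ly$params$w$value, 2L, ly$params$b$value, "+")
  }
  ly$bwd <- function(dy) {
    ly$params$w$grad <- ly$params$w$grad + crossprod(ly$cache, dy)
    ly$params$b$grad <- ly$params$b$grad + colSums(dy)
    tcrossprod(dy, ly$params$w$value)
  }
  ly
}

# LayerNorm over the channel axis of an N x C token matrix.
layer_layernorm <- function(C, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$params <- list(gamma = new_param(rep(1, C)),
                    beta = new_param(numeric(C)))
  ly$fwd <- function(x) {
    mu <- rowMeans(x)
    xc <- x - mu
    istd <- 1 / sqrt(rowMeans(xc^2) + eps)
    xhat <- xc * istd
    ly$cache <- list(xhat = xhat, istd = istd)
    sweep(sweep(xhat, 2L, ly$params$gamma$value, "*"), 2L,
          ly$params$beta$value, "+")
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache
    ly$params$gamma$grad <- ly$params$gamma$grad + colSums(dy * cc$xhat)
    ly$params$beta$grad <- ly$params$beta$grad + colSums(dy)
    dxhat <- sweep(dy, 2L, ly$params$gamma$value, "*")
    cc$istd * (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
  }
  ly
}

layer_maxpool2 <- function() {
  ly <- new.env(parent = emptyenv())
  ly$params <- list()
  ly$fwd <- function(x) {
    dims <- dim(x)
    stopifnot(all(dims[1:3] %% 2L == 0L))
    r <- cpp_maxpool2(as.vector(x), dims)
    ly$cache <- list(argmax = r$argmax, dims = dims)
    array(r$out, dim = c(dims[1:3] %/% 2L, dims[4]))
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache
    dx <- numeric(prod(cc$dims))
    # argmax indices are unique per pooled cell but cells can share a source
    # only across channels, which the flat index already separates
    acc <- tapply(as.vector(dy), cc$argmax, sum)
    dx[as.integer(names(acc))] <- acc
    array(dx, dim = cc$dims)
  }
  ly
}

sigmoid <- function(x) 1 / (1 + exp(-x))
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Concurrent spatial and channel squeeze-and-excitation: channel gate from a
# globally pooled descriptor through a bottleneck, spatial gate from a 1x1x1
# convolution, fused by elementwise maximum of the two gated copies.
layer_scse <- function(C, reduction = 2L) {
  ly <- new.env(parent = emptyenv())
  Cr <- max(1L, C %/% reduction)
  ly$params <- list(w1 = new_param(init_weight(c(C, Cr), C)),
                    b1 = new_param(numeric(Cr)),
                    w2 = new_param(init_weight(c(Cr, C), Cr)),
                    b2 = new_param(numeric(C)),
                    ws = new_param(init_weight(c(C, 1L), C)),
                    bs = new_param(0))
  ly$fwd <- function(x) {
    dims <- dim(x); nvox <- prod(dims[1:3])
    xm <- matrix(x, nvox, C)
    z <- colMeans(xm)
    a1pre <- drop(z %*% ly$params$w1$value) + ly$params$b1$value
    a1 <- pmax(a1pre, 0)
    spre <- drop(a1 %*% ly$params$w2$value) + ly$params$b2$value
    s <- sigmoid(spre)
    qpre <- drop(xm %*% ly$params$ws$value) + as.numeric(ly$params$bs$value)
    q <- sigmoid(qpre)
    xc <- sweep(xm, 2L, s, "*")
    xs <- xm * q
    ch <- xc >= xs
    y <- ifelse(ch, xc, xs)
    ly$cache <- list(xm = xm, z = z, a1pre = a1pre, a1 = a1, s = s, q = q,
                     ch = ch, dims = dims)
    array(y, dim = dims)
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache; dims <- cc$dims; nvox <- prod(dims[1:3])
    dym <- matrix(dy, nvox, C)
    dxc <- dym * cc$ch
    dxs <- dym * !cc$ch
    dx <- sweep(dxc, 2L, cc$s, "*") + dxs * cc$q
    ds <- colSums(dxc * cc$xm)
    dq <- rowSums(dxs * cc$xm)
    # spatial gate
    dqpre <- dq * cc$q * (1 - cc$q)
    ly$params$ws$grad <- ly$params$ws$grad + crossprod(cc$xm, dqpre)
    ly$params$bs$grad <- ly$params$bs$grad + sum(dqpre)
    dx <- dx + tcrossprod(dqpre, drop(ly$params$ws$value))
    # channel gate
    dspre <- ds * cc$s * (1 - cc$s)
    ly$params$w2$grad <- ly$params$w2$grad + outer(cc$a1, dspre)
    ly$params$b2$grad <- ly$params$b2$grad + dspre
    da1 <- drop(ly$params$w2$value %*% dspre) * (cc$a1pre > 0)
    ly$params$w1$grad <- ly$params$w1$grad + outer(cc$z, da1)
    ly$params$b1$grad <- ly$params$b1$grad + da1
    dz <- drop(ly$params$w1$value %*% da1)
    dx <- dx + matrix(dz / nvox, nvox, C, byrow = TRUE)
    array(dx, dim = dims)
  }
  ly
}
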