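#' Configuration of the shifted-window transformer backbone
#'
#' @param embed_dim channels `C` after patch embedding.
#' @param window window size per axis at full token resolution; shrunk to
#'   the grid where stages get smaller than the window.
#' @param depths swin blocks per encoder stage (4 stages; the decoder
#'   mirrors them).
#' @param heads attention heads per stage; must divide the stage channels.
#' @param mlp_ratio hidden width multiplier of the token MLP.
#' @param use_bias include a learned relative position bias (standard swin).
#' @return object of class `swin_config`.
#' @export
swin_config <- function(embed_dim = 48L, window = c(2L, 4L, 4L),
                        depths = c(2L, 2L, 4L, 2L),
                        heads = c(4L, 4L, 8L, 8L), mlp_ratio = 2,
                        use_bias = TRUE) {
  stopifnot(embed_dim >= 1, length(window) == 3L, length(depths) == 4L,
            length(heads) == 4L, mlp_ratio > 0)
  for (i in 1:4) {
    ci <- embed_dim * 2^(i - 1)
    if (ci %% heads[i] != 0)
      stop(sprintf("heads[%d] = %d does not divide stage channels %d",
                   i, heads[i], ci))
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 window = as.integer(window), depths = as.integer(depths),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 use_bias = isTRUE(use_bias)),
            class = "swin_config")
}

#' Partition a token grid into (optionally shifted) attention windows
#'
#' Applies a cyclic shift by `-shift` along each axis, then tiles the grid
#' into non-overlapping windows.  Grid dimensions must be multiples of the
#' window (pad first).  [window_reverse()] inverts the operation exactly.
#'
#' @param t `(D, H, W, C)` token array.
#' @param window integer length-3 window size.
#' @param shift integer length-3 cyclic shift (0 = plain tiling).
#' @return array of dim `(T, C, nw)` where `T = prod(window)` and `nw` is
#'   the number of windows, with attribute `grid` recording the grid shape.
#' @export
window_partition <- function(t, window, shift = c(0L, 0L, 0L)) {
  dims <- dim(t)
  window <- as.integer(rep_len(window, 3L))
  shift <- as.integer(rep_len(shift, 3L))
  if (any(dims[1:3] %% window != 0L))
    stop("grid dimensions must be multiples of the window")
  if (any(shift != 0L)) {
    idx <- lapply(1:3, function(a)
      ((seq_len(dims[a]) - 1L + shift[a]) %% dims[a]) + 1L)
    t <- t[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  nwd <- dims[1:3] %/% window
  dim(t) <- c(window[1], nwd[1], window[2], nwd[2], window[3], nwd[3],
              dims[4])
  t <- aperm(t, c(1, 3, 5, 2, 4, 6, 7))
  Tn <- prod(window); nw <- prod(nwd)
  dim(t) <- c(Tn, nw, dims[4])
  t <- aperm(t, c(1, 3, 2))
  attr(t, "grid") <- dims
  t
}

#' Reverse a window partition
#'
#' @param wt output of [window_partition()] (attribute `grid` or explicit
#'   `grid` argument supplies the grid shape).
#' @param window,shift the values used when partitioning.
#' @param grid grid dim `(D, H, W, C)`; defaults to the stored attribute.
#' @return the original `(D, H, W, C)` token array.
#' @export
window_reverse <- function(wt, window, shift = c(0L, 0L, 0L), grid = NULL) {
  dims <- grid %||% attr(wt, "grid")
  window <- as.integer(rep_len(window, 3L))
  shift <- as.integer(rep_len(shift, 3L))
  nwd <- dims[1:3] %/% window
  t <- aperm(wt, c(1, 3, 2))              # T x nw x C
  dim(t) <- c(window[1], window[2], window[3], nwd[1], nwd[2], nwd[3],
              dims[4])
  t <- aperm(t, c(1, 4, 2, 5, 3, 6, 7))
  dim(t) <- dims
  if (any(shift != 0L)) {
    idx <- lapply(1:3, function(a)
      ((seq_len(dims[a]) - 1L - shift[a]) %% dims[a]) + 1L)
    t <- t[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  t
}

# relative position bias index: T x T matrix of 1-based indices into a
# (2w1-1)(2w2-1)(2w3-1) table.
rel_pos_index <- function(window) {
  coords <- as.matrix(expand.grid(d = seq_len(window[1]),
                                  h = seq_len(window[2]),
                                  w = seq_len(window[3])))
  Tn <- nrow(coords)
  idx <- matrix(0L, Tn, Tn)
  span <- 2L * window - 1L
  for (i in seq_len(Tn)) {
    rel <- sweep(coords, 2L, coords[i, ], "-")  # rows: j - i per axis
    idx[i, ] <- (rel[, 1] + window[1] - 1L) +
      span[1] * (rel[, 2] + window[2] - 1L) +
      span[1] * span[2] * (rel[, 3] + window[3] - 1L) + 1L
  }
  idx
}

# attention mask for a padded / shifted grid: tokens from different shift
# regions (or padding) must not mix.  Region ids are laid out in post-roll
# coordinates (the standard shifted-window construction); the padding
# indicator, defined pre-roll, is rolled along with the data.  Returns
# (T, T, nw) with 0 / -1e9 entries, or NULL when no masking is needed.
swin_attn_mask <- function(grid, pad_grid, window, shift) {
  if (all(shift == 0L) && all(grid == pad_grid)) return(NULL)
  ids <- array(0, dim = pad_grid)
  for (a in 1:3) {
    n <- pad_grid[a]; w <- window[a]; s <- shift[a]
    seg <- integer(n)
    if (s > 0L) {
      if (w - s >= 1L) seg[(n - w + 1L):(n - s)] <- 1L
      seg[(n - s + 1L):n] <- 2L
    }
    add <- array(rep(seg, each = prod(pad_grid[seq_len(a - 1L)])),
                 dim = pad_grid)
    ids <- ids * 4 + add
  }
  pad_mask <- array(FALSE, dim = pad_grid)
  if (grid[1] < pad_grid[1]) pad_mask[(grid[1] + 1L):pad_grid[1], , ] <- TRUE
  if (grid[2] < pad_grid[2]) pad_mask[, (grid[2] + 1L):pad_grid[2], ] <- TRUE
  if (grid[3] < pad_grid[3]) pad_mask[, , (grid[3] + 1L):pad_grid[3]] <- TRUE
  if (any(shift != 0L)) {
    idx <- lapply(1:3, function(a)
      ((seq_len(pad_grid[a]) - 1L + shift[a]) %% pad_grid[a]) + 1L)
    pad_mask <- pad_mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  ids[pad_mask] <- -1
  idw <- window_partition(array(ids, dim = c(pad_grid, 1L)), window,
                          shift = c(0L, 0L, 0L))
  Tn <- dim(idw)[1]; nw <- dim(idw)[3]
  mask <- array(0, dim = c(Tn, Tn, nw))
  for (k in seq_len(nw)) {
    v <- idw[, 1, k]
    mask[, , k] <- ifelse(outer(v, v, "!="), -1e9, 0)
  }
  mask
}

#' Window multi-head self-attention layer
#'
#' Standard scaled dot-product attention applied independently inside each
#' window, with an optional learned relative position bias; masks prevent
#' tokens of different shift regions (or padding) from mixing.
#'
#' @param C channels; @param heads number of heads (must divide `C`);
#' @param window integer length-3 window size;
#' @param use_bias include the relative position bias table.
#' @return layer environment with `fwd(wt, mask)` / `bwd(dy)` over
#'   `(T, C, nw)` window arrays.
#' @export
layer_wmsa <- function(C, heads, window, use_bias = TRUE) {
  if (C %% heads != 0L) stop("heads must divide C")
  ly <- new.env(parent = emptyenv())
  dh <- C %/% heads
  Tn <- prod(window)
  ly$params <- list(wqkv = new_param(init_weight(c(C, 3L * C), C)),
                    bqkv = new_param(numeric(3L * C)),
                    wp = new_param(init_weight(c(C, C), C)),
                    bp = new_param(numeric(C)))
  if (use_bias) {
    span <- prod(2L * window - 1L)
    ly$params$bias <- new_param(array(0, dim = c(span, heads)))
    ly$bidx <- rel_pos_index(window)
  }
  ly$heads <- heads; ly$C <- C; ly$Tn <- Tn; ly$use_bias <- use_bias
  ly$fwd <- function(wt, mask = NULL) {
    nw <- dim(wt)[3]
    out <- array(0, dim = dim(wt))
    cache <- vector("list", nw)
    for (k in seq_len(nw)) {
      x <- wt[, , k]
      if (is.null(dim(x))) dim(x) <- c(1L, C)
      qkv <- sweep(x %*% ly$params$wqkv$value, 2L, ly$params$bqkv$value,
                   "+")
      hc <- vector("list", heads)
      o <- matrix(0, nrow(x), C)
      for (h in seq_len(heads)) {
        ci <- (h - 1L) * dh + seq_len(dh)
        q <- qkv[, ci, drop = FALSE]
        kk <- qkv[, C + ci, drop = FALSE]
        v <- qkv[, 2L * C + ci, drop = FALSE]
        a <- tcrossprod(q, kk) / sqrt(dh)
        if (ly$use_bias)
          a <- a + matrix(ly$params$bias$value[cbind(as.vector(ly$bidx),
                                                     h)],
                          nrow(x), nrow(x))
        if (!is.null(mask)) a <- a + mask[, , k]
        a <- a - apply(a, 1L, max)
        p <- exp(a); p <- p / rowSums(p)
        o[, ci] <- p %*% v
        hc[[h]] <- list(p = p, q = q, k = kk, v = v)
      }
      y <- sweep(o %*% ly$params$wp$value, 2L, ly$params$bp$value, "+")
      out[, , k] <- y
      cache[[k]] <- list(x = x, qkv = qkv, o = o, hc = hc)
    }
    ly$cache <- cache
    attr(out, "grid") <- attr(wt, "grid")
    out
  }
  ly$bwd <- function(dy) {
    nw <- dim(dy)[3]
    dwt <- array(0, dim = dy |> dim())
    for (k in seq_len(nw)) {
      cc <- ly$cache[[k]]
      d <- dy[, , k]
      if (is.null(dim(d))) dim(d) <- c(1L, C)
      ly$params$wp$grad <- ly$params$wp$grad + crossprod(cc$o, d)
      ly$params$bp$grad <- ly$params$bp$grad + colSums(d)
      do <- tcrossprod(d, ly$params$wp$value)
      dqkv <- matrix(0, nrow(cc$x), 3L * C)
      for (h in seq_len(ly$heads)) {
        ci <- (h - 1L) * dh + seq_len(dh)
        hcc <- cc$hc[[h]]
        doh <- do[, ci, drop = FALSE]
        dp <- tcrossprod(doh, hcc$v)
        dv <- crossprod(hcc$p, doh)
        da <- hcc$p * (dp - rowSums(dp * hcc$p))
        if (ly$use_bias) {
          acc <- tapply(as.vector(da), as.vector(ly$bidx), sum)
          ii <- as.integer(names(acc))
          ly$params$bias$grad[cbind(ii, h)] <-
            ly$params$bias$grad[cbind(ii, h)] + as.vector(acc)
        }
        dqkv[, ci] <- (da %*% hcc$k) / sqrt(dh)
        dqkv[, C + ci] <- crossprod(da, hcc$q) / sqrt(dh)
        dqkv[, 2L * C + ci] <- dv
      }
      ly$params$wqkv$grad <- ly$params$wqkv$grad + crossprod(cc$x, dqkv)
      ly$params$bqkv$grad <- ly$params$bqkv$grad + colSums(dqkv)
      dwt[, , k] <- tcrossprod(dqkv, ly$params$wqkv$value)
    }
    dwt
  }
  ly
}

#' Swin transformer block
#'
#' Pre-norm windowed attention with a residual connection followed by a
#' pre-norm two-layer GELU MLP with a residual connection; the shifted
#' variant cyclically shifts the grid by half a window before partitioning
#' and masks cross-boundary attention.
#'
#' @param C channels; @param heads attention heads; @param grid token grid
#'   shape the block is built for; @param window requested window size;
#' @param shifted use the shifted-window variant;
#' @param mlp_ratio MLP expansion factor; @param use_bias relative position
#'   bias flag.
#' @return layer environment with `fwd(x)` / `bwd(dy)` over `(D, H, W, C)`
#'   token arrays.
#' @export
layer_swin_block <- function(C, heads, grid, window = c(2L, 4L, 4L),
                             shifted = FALSE, mlp_ratio = 2,
                             use_bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  grid <- as.integer(grid)
  effw <- pmin(as.integer(rep_len(window, 3L)), grid)
  pad_grid <- as.integer(ceiling(grid / effw) * effw)
  nwd <- pad_grid %/% effw
  shift <- if (shifted) ifelse(nwd > 1L, effw %/% 2L, 0L)
           else c(0L, 0L, 0L)
  ly$grid <- grid; ly$effw <- effw; ly$pad_grid <- pad_grid
  ly$shift <- as.integer(shift)
  ly$mask <- swin_attn_mask(grid, pad_grid, effw, ly$shift)
  ly$ln1 <- layer_layernorm(C)
  ly$attn <- layer_wmsa(C, heads, effw, use_bias)
  ly$ln2 <- layer_layernorm(C)
  hidden <- max(1L, as.integer(round(mlp_ratio * C)))
  ly$fc1 <- layer_linear(C, hidden)
  ly$fc2 <- layer_linear(hidden, C)
  ly$params <- list(ly$ln1, ly$attn, ly$ln2, ly$fc1, ly$fc2)
  pad_tokens <- function(x) {
    if (all(dim(x)[1:3] == pad_grid)) return(x)
    y <- array(0, dim = c(pad_grid, dim(x)[4]))
    y[seq_len(grid[1]), seq_len(grid[2]), seq_len(grid[3]), ] <- x
    y
  }
  crop_tokens <- function(x) {
    x[seq_len(grid[1]), seq_len(grid[2]), seq_len(grid[3]), ,
      drop = FALSE]
  }
  ly$fwd <- function(x) {
    dims <- dim(x)
    stopifnot(all(dims[1:3] == grid))
    n <- prod(dims[1:3])
    xm <- matrix(x, n, C)
    h1 <- ly$ln1$fwd(xm)
    hp <- pad_tokens(array(h1, dim = dims))
    wt <- window_partition(hp, effw, ly$shift)
    at <- ly$attn$fwd(wt, ly$mask)
    hg <- crop_tokens(window_reverse(at, effw, ly$shift,
                                     grid = c(pad_grid, C)))
    x2 <- xm + matrix(hg, n, C)
    h2 <- ly$ln2$fwd(x2)
    y <- x2 + ly$fc2$fwd(gelu_store(ly, ly$fc1$fwd(h2)))
    array(y, dim = dims)
  }
  ly$bwd <- function(dy) {
    dims <- dim(dy)
    n <- prod(dims[1:3])
    dym <- matrix(dy, n, C)
    dmid <- ly$fc1$bwd(gelu_bwd(ly, ly$fc2$bwd(dym)))
    dx2 <- dym + ly$ln2$bwd(dmid)
    dhg <- pad_tokens(array(dx2, dim = dims))
    dwt <- window_partition(dhg, effw, ly$shift)
    dat <- ly$attn$bwd(dwt)
    dh1 <- crop_tokens(window_reverse(dat, effw, ly$shift,
                                      grid = c(pad_grid, C)))
    dxm <- dx2 + ly$ln1$bwd(matrix(dh1, n, C))
    array(dxm, dim = dims)
  }
  ly
}

gelu_store <- function(ly, x) { ly$gelu_cache <- x; gelu(x) }
gelu_bwd <- function(ly, dy) dy * gelu_grad(ly$gelu_cache)

#' Patch embedding layer
#'
#' Splits the stacked 2-channel (moving, fixed) input into non-overlapping
#' 4x4x4 patches, flattens each (128 values) and projects linearly to `C`
#' channels, producing a token grid at 1/4 resolution.
#'
#' @param C embedding channels.
#' @return layer environment; `fwd` expects a `(D, H, W, 2)` array with
#'   spatial dims divisible by 4.
#' @export
layer_patch_embed <- function(C) {
  ly <- new.env(parent = emptyenv())
  ly$conv <- layer_conv3d(2L, C, k = 4L, stride = 4L, pad = 0L)
  ly$params <- list(ly$conv)
  ly$fwd <- function(x) {
    dims <- dim(x)
    if (length(dims) != 4L || dims[4] != 2L)
      stop("patch_embed: input must carry the (moving, fixed) channel pair")
    if (any(dims[1:3] %% 4L != 0L))
      stop("patch_embed: spatial dims must be divisible by 4")
    ly$conv$fwd(x)
  }
  ly$bwd <- function(dy) ly$conv$bwd(dy)
  ly
}

#' Patch merging layer (token downsampling)
#'
#' Concatenates each 2x2x2 token neighbourhood (in `(d, h, w)` scan order,
#' channel-slowest) into an 8C vector and projects it to 2C channels,
#' halving the grid.
#'
#' @param C input channels.
#' @return layer environment over token grids with even dimensions.
#' @export
layer_patch_merge <- function(C) {
  ly <- new.env(parent = emptyenv())
  ly$conv <- layer_conv3d(C, 2L * C, k = 2L, stride = 2L, pad = 0L)
  ly$params <- list(ly$conv)
  ly$fwd <- function(x) {
    if (any(dim(x)[1:3] %% 2L != 0L))
      stop("patch_merge: grid dimensions must be even (pad first)")
    ly$conv$fwd(x)
  }
  ly$bwd <- function(dy) ly$conv$bwd(dy)
  ly
}

#' Patch expanding layer (token upsampling)
#'
#' Projects each token from `C` to `8 * C/2` channels and redistributes the
#' result into a 2x2x2 spatial neighbourhood with `C/2` channels, doubling
#' the grid; the output is cropped to `target` when given (inverse of the
#' padding applied on the way down).
#'
#' @param C input channels (even).
#' @return layer environment; `fwd(x, target)` with optional target dims.
#' @export
layer_patch_expand <- function(C) {
  stopifnot(C %% 2L == 0L)
  ly <- new.env(parent = emptyenv())
  C2 <- C %/% 2L
  ly$lin <- layer_linear(C, 8L * C2)
  ly$params <- list(ly$lin)
  ly$fwd <- function(x, target = NULL) {
    dims <- dim(x)
    n <- prod(dims[1:3])
    y <- ly$lin$fwd(matrix(x, n, C))
    dim(y) <- c(dims[1:3], 2L, 2L, 2L, C2)
    y <- aperm(y, c(4, 1, 5, 2, 6, 3, 7))
    dim(y) <- c(2L * dims[1:3], C2)
    full <- dim(y)
    if (!is.null(target)) {
      target <- as.integer(target)
      y <- y[seq_len(target[1]), seq_len(target[2]), seq_len(target[3]), ,
             drop = FALSE]
    }
    ly$cache <- list(dims = dims, full = full)
    y
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache
    if (!all(dim(dy)[1:3] == cc$full[1:3])) {
      g <- array(0, dim = cc$full)
      g[seq_len(dim(dy)[1]), seq_len(dim(dy)[2]), seq_len(dim(dy)[3]), ] <-
        dy
      dy <- g
    }
    dim(dy) <- c(2L, cc$dims[1], 2L, cc$dims[2], 2L, cc$dims[3], C2)
    dy <- aperm(dy, c(2, 4, 6, 1, 3, 5, 7))
    dim(dy) <- c(prod(cc$dims[1:3]), 8L * C2)
    dx <- ly$lin$bwd(dy)
    array(dx, dim = cc$dims)
  }
  ly
}
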