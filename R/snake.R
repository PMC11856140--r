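#' Kernel specification for 3D dynamic snake convolution
#'
#' A dynamic snake convolution linearizes the kernel along one grid axis
#' into `points_per_kernel` taps whose two lateral coordinates bend by
#' cumulatively summed offsets, each per-step offset bounded by `max_step`
#' voxels.  Three axis-variants (one snake per grid axis) are fused into a
#' single response.  With the defaults (9 taps, unit step bound) the
#' deformed kernel can reach anywhere inside a 9x9x9 cube.
#'
#' @param points_per_kernel odd integer >= 3, taps per axis-variant.
#' @param max_step positive bound on each per-step lateral offset (voxels).
#' @param fusion how the three axis-variant responses are combined:
#'   `"mean"` (default), `"sum"` or `"concat"` (concatenation followed by a
#'   pointwise convolution).
#' @return object of class `snake_spec`.
#' @export
snake_kernel_spec <- function(points_per_kernel = 9L, max_step = 1,
                              fusion = c("mean", "sum", "concat")) {
  points_per_kernel <- as.integer(points_per_kernel)
  if (points_per_kernel < 3L || points_per_kernel %% 2L == 0L)
    stop("points_per_kernel must be odd and >= 3")
  if (max_step <= 0) stop("max_step must be positive")
  fusion <- match.arg(fusion)
  structure(list(points_per_kernel = points_per_kernel,
                 max_step = max_step, fusion = fusion,
                 half = (points_per_kernel - 1L) %/% 2L),
            class = "snake_spec")
}

# grid axis each snake runs along, and its two lateral axes, in (d, h, w)
# indexing (1 = d, 2 = h, 3 = w).  "x" runs along w, "y" along h, "z"
# along d, mirroring image-style axis naming.
snake_axis_map <- function(axis) {
  switch(axis,
         x = list(along = 3L, lateral = c(1L, 2L)),
         y = list(along = 2L, lateral = c(1L, 3L)),
         z = list(along = 1L, lateral = c(2L, 3L)),
         stop("axis must be one of 'x', 'y', 'z'"))
}

#' Snake sampling positions for one output voxel
#'
#' Builds the fractional sampling positions of one axis-variant of the
#' snake kernel centered at `center`.  Along the chosen axis the coordinate
#' steps by one voxel per tap; the two lateral coordinates accumulate the
#' per-step offsets outward from the center (the tap at distance `c`
#' carries the running sum of the first `c` offsets on its side); the
#' center tap carries zero offset.
#'
#' @param center length-3 numeric `(d, h, w)` coordinate.
#' @param offsets list with elements `plus` and `minus`, each a
#'   `half x 2` matrix of per-step lateral offsets (columns follow the two
#'   lateral grid axes in ascending `(d, h, w)` order).
#' @param axis `"x"`, `"y"` or `"z"` (along w, h, d respectively).
#' @param spec a [snake_kernel_spec()].
#' @return `points_per_kernel x 3` matrix of positions, ordered from the
#'   `-half` tap to the `+half` tap.
#' @export
snake_positions <- function(center, offsets, axis = "x",
                            spec = snake_kernel_spec()) {
  am <- snake_axis_map(axis)
  half <- spec$half
  for (side in c("plus", "minus")) {
    m <- offsets[[side]]
    if (is.null(m) || !all(dim(as.matrix(m)) == c(half, 2L)))
      stop(sprintf("offsets$%s must be a %d x 2 matrix", side, half))
    if (any(abs(m) > spec$max_step + 1e-12))
      stop("offsets exceed max_step")
  }
  P <- spec$points_per_kernel
  pos <- matrix(rep(as.numeric(center), each = P), nrow = P)
  steps <- (-half):half
  pos[, am$along] <- pos[, am$along] + steps
  cum_p <- apply(as.matrix(offsets$plus), 2L, cumsum)
  cum_m <- apply(as.matrix(offsets$minus), 2L, cumsum)
  dim(cum_p) <- dim(cum_m) <- c(half, 2L)
  for (k in 1:2) {
    lat <- am$lateral[k]
    pos[half + 1 + (1:half), lat] <- pos[half + 1 + (1:half), lat] +
      cum_p[, k]
    pos[half + 1 - (1:half), lat] <- pos[half + 1 - (1:half), lat] +
      cum_m[, k]
  }
  pos
}

#' Axis-aligned extent reachable by one snake variant
#'
#' Side lengths of the bounding box of all sampling positions one
#' axis-variant can reach with offsets saturated at the bound: the
#' along-axis extent is `points_per_kernel`; each lateral extent is
#' `2 * ceiling(max_step * half) + 1`.
#'
#' @param spec a [snake_kernel_spec()].
#' @return named integer vector `(along, lateral, lateral)`.
#' @export
receptive_extent <- function(spec = snake_kernel_spec()) {
  lat <- 2L * as.integer(ceiling(spec$max_step * spec$half)) + 1L
  c(along = spec$points_per_kernel, lateral = lat, lateral2 = lat)
}

# number of offset channels: 3 axis-variants x 2 sides x half steps x 2
# lateral components; layout (component fastest, then step, side, axis).
snake_n_offset_channels <- function(spec) 3L * 2L * spec$half * 2L

#' Squash raw offset predictions into bounded snake offsets
#'
#' Applies the saturating odd squashing `max_step * tanh(raw)` so that every
#' per-step lateral offset lies strictly inside `(-max_step, max_step)`.
#'
#' @param raw numeric `(D, H, W, nchan)` array of raw predictions with
#'   `nchan = 12 * (points_per_kernel - 1) / 2`.
#' @param spec a [snake_kernel_spec()].
#' @return object of class `snake_offsets` (bounded offsets plus layout).
#' @export
snake_offsets <- function(raw, spec = snake_kernel_spec()) {
  raw <- as.array(raw)
  nch <- snake_n_offset_channels(spec)
  if (length(dim(raw)) != 4L || dim(raw)[4] != nch)
    stop(sprintf("raw offsets must have %d channels", nch))
  structure(list(delta = spec$max_step * tanh(raw), spec = spec),
            class = "snake_offsets")
}

#' Predict snake offsets from a feature grid
#'
#' Raw offsets come from a learned 3x3x3 convolution of the operator's own
#' input features and are squashed into `[-max_step, max_step]`.
#'
#' @param features `(D, H, W, C)` feature array.
#' @param offset_params list with `w` (a `(3, 3, 3, C, nchan)` weight array)
#'   and `b` (length-`nchan` bias).
#' @param spec a [snake_kernel_spec()].
#' @return a `snake_offsets` object.
#' @export
predict_offsets <- function(features, offset_params,
                            spec = snake_kernel_spec()) {
  dims <- dim(features)
  nch <- snake_n_offset_channels(spec)
  w <- offset_params$w
  stopifnot(length(dim(w)) == 5L, dim(w)[4] == dims[4], dim(w)[5] == nch)
  cols <- cpp_im2col(as.vector(features), dims, 3L, 1L, 1L)
  dim(w) <- c(27L * dims[4], nch)
  raw <- cols %*% w
  raw <- sweep(raw, 2L, offset_params$b %||% numeric(nch), "+")
  snake_offsets(array(raw, dim = c(dims[1:3], nch)), spec)
}

# Extract the (plus, minus) half x 2 offset matrices of one axis-variant at
# one voxel (1-based index) from a snake_offsets object.
offsets_at <- function(off, voxel, axis) {
  spec <- off$spec; half <- spec$half
  ai <- match(axis, c("x", "y", "z"))
  d <- off$delta
  dims <- dim(d)
  dim(d) <- c(prod(dims[1:3]), 2L, half, 2L, 3L)
  n <- voxel[1] + dims[1] * (voxel[2] - 1L) +
    dims[1] * dims[2] * (voxel[3] - 1L)
  list(plus = t(matrix(d[n, , , 1L, ai], nrow = 2L)),
       minus = t(matrix(d[n, , , 2L, ai], nrow = 2L)))
}

# All snake sampling positions of one axis-variant for every voxel of the
# grid, tap-major: row (t - 1) * N + n is tap t of voxel n (taps ordered
# -half..+half).  Returns an (N * P) x 3 matrix of 0-based positions.
snake_positions_grid <- function(shape, off, axis) {
  spec <- off$spec; half <- spec$half; P <- spec$points_per_kernel
  am <- snake_axis_map(axis)
  ai <- match(axis, c("x", "y", "z"))
  N <- prod(shape)
  base <- grid_positions(shape)
  d <- off$delta
  dim(d) <- c(N, 2L, half, 2L, 3L)
  # cumulative sums outward from the center on each side
  cum <- d[, , , , ai, drop = FALSE]
  dim(cum) <- c(N, 2L, half, 2L)
  if (half > 1L)
    for (s in 2:half) cum[, , s, ] <- cum[, , s, ] + cum[, , s - 1L, ]
  pos <- matrix(0, N * P, 3L)
  for (t in seq_len(P)) {
    rows <- (t - 1L) * N + seq_len(N)
    step <- t - half - 1L
    p <- base
    p[, am$along] <- p[, am$along] + step
    if (step != 0L) {
      side <- if (step > 0L) 1L else 2L
      for (k in 1:2)
        p[, am$lateral[k]] <- p[, am$lateral[k]] + cum[, k, abs(step), side]
    }
    pos[rows, ] <- p
  }
  pos
}

#' Apply a 3D dynamic snake convolution
#'
#' Evaluates the full operator: for each axis-variant, every output voxel is
#' the weighted sum of trilinear samples of the input taken at the snake
#' positions bent by `offsets`; the three axis-variant responses are fused
#' according to `spec$fusion` (for `"concat"` fusion supply
#' `weights$fuse`, a `(3 * cout, cout)` pointwise matrix).
#'
#' @param input `(D, H, W, Cin)` feature array (a bare 3D array is treated
#'   as single-channel).
#' @param weights list with per-axis tap weights `x`, `y`, `z`, each a
#'   `(P, Cin, Cout)` array, optional bias `b` (length `Cout`) and optional
#'   `fuse` matrix for concat fusion.
#' @param offsets a `snake_offsets` object on the same grid.
#' @param spec a [snake_kernel_spec()].
#' @return `(D, H, W, Cout)` array.
#' @export
dsconv3d <- function(input, weights, offsets, spec = snake_kernel_spec()) {
  if (length(dim(input)) == 3L) dim(input) <- c(dim(input), 1L)
  dims <- dim(input)
  if (!identical(dim(offsets$delta)[1:3], dims[1:3]))
    stop("dsconv3d: offsets grid does not match input")
  N <- prod(dims[1:3]); P <- spec$points_per_kernel; cin <- dims[4]
  outs <- lapply(c("x", "y", "z"), function(axis) {
    pos <- snake_positions_grid(dims[1:3], offsets, axis)
    g <- cpp_trilinear_gather(as.vector(input), dims, pos)   # (N*P) x cin
    dim(g) <- c(N, P * cin)
    wa <- weights[[axis]]
    cout <- dim(wa)[3]
    dim(wa) <- c(P * cin, cout)
    g %*% wa
  })
  cout <- ncol(outs[[1]])
  y <- switch(spec$fusion,
              mean = (outs[[1]] + outs[[2]] + outs[[3]]) / 3,
              sum = outs[[1]] + outs[[2]] + outs[[3]],
              concat = cbind(outs[[1]], outs[[2]], outs[[3]]) %*%
                weights$fuse)
  if (!is.null(weights$b)) y <- sweep(y, 2L, weights$b, "+")
  array(y, dim = c(dims[1:3], ncol(y)))
}

#' Reference implementation of the snake convolution (slow, loop-based)
#'
#' Explicitly builds every snake position with [snake_positions()] and sums
#' weighted [trilinear_sample()] values voxel by voxel.  Used as the
#' independent cross-check of the fast path; do not use on large grids.
#'
#' @inheritParams dsconv3d
#' @return `(D, H, W, Cout)` array.
#' @export
dsconv3d_reference <- function(input, weights, offsets,
                               spec = snake_kernel_spec()) {
  if (length(dim(input)) == 3L) dim(input) <- c(dim(input), 1L)
  dims <- dim(input)
  cin <- dims[4]
  cout <- dim(weights$x)[3]
  P <- spec$points_per_kernel
  nf <- if (spec$fusion == "concat") 3L * cout else cout
  out <- array(0, dim = c(dims[1:3], nf))
  for (w in seq_len(dims[3])) for (h in seq_len(dims[2]))
    for (d in seq_len(dims[1])) {
      acc <- NULL
      for (axis in c("x", "y", "z")) {
        offv <- offsets_at(offsets, c(d, h, w), axis)
        pos <- snake_positions(c(d, h, w) - 1, offv, axis, spec)
        resp <- numeric(cout)
        for (ci in seq_len(cin)) {
          vals <- trilinear_sample(array(input[, , , ci], dims[1:3]), pos)
          for (co in seq_len(cout))
            resp[co] <- resp[co] + sum(weights[[axis]][, ci, co] * vals)
        }
        acc <- switch(spec$fusion,
                      mean = , sum = if (is.null(acc)) resp else acc + resp,
                      concat = c(acc, resp))
      }
      if (spec$fusion == "mean") acc <- acc / 3
      out[d, h, w, ] <- acc
    }
  if (spec$fusion == "concat") {
    y <- matrix(out, ncol = 3L * cout) %*% weights$fuse
    out <- array(y, dim = c(dims[1:3], cout))
  }
  if (!is.null(weights$b))
    out <- out + rep(weights$b, each = prod(dims[1:3]))
  out
}

# Trainable snake convolution layer: offsets predicted from the layer's own
# input by a 3x3x3 convolution, squashed to [-max_step, max_step].
layer_dsconv3d <- function(cin, cout, spec = snake_kernel_spec()) {
  ly <- new.env(parent = emptyenv())
  P <- spec$points_per_kernel
  nch <- snake_n_offset_channels(spec)
  ly$spec <- spec; ly$cin <- cin; ly$cout <- cout
  ly$offconv <- layer_conv3d(cin, nch, k = 3L, stride = 1L, pad = 1L,
                             zero_init = TRUE)
  mk <- function() new_param(init_weight(c(P, cin, cout), P * cin * 3))
  ly$params <- list(wx = mk(), wy = mk(), wz = mk(),
                    b = new_param(numeric(cout)),
                    offconv = ly$offconv)
  if (spec$fusion == "concat")
    ly$params$fuse <- new_param(init_weight(c(3L * cout, cout), 3L * cout))
  ly$fwd <- function(x) {
    dims <- dim(x); N <- prod(dims[1:3])
    raw <- ly$offconv$fwd(x)
    off <- snake_offsets(raw, spec)
    axes <- c("x", "y", "z")
    pos <- lapply(axes, function(a) snake_positions_grid(dims[1:3], off, a))
    gs <- lapply(pos, function(p)
      cpp_trilinear_gather(as.vector(x), dims, p))
    outs <- lapply(1:3, function(i) {
      g <- gs[[i]]; dim(g) <- c(N, P * cin)
      wa <- ly$params[[c("wx", "wy", "wz")[i]]]$value
      dim(wa) <- c(P * cin, cout)
      g %*% wa
    })
    y <- switch(spec$fusion,
                mean = (outs[[1]] + outs[[2]] + outs[[3]]) / 3,
                sum = outs[[1]] + outs[[2]] + outs[[3]],
                concat = cbind(outs[[1]], outs[[2]], outs[[3]]) %*%
                  ly$params$fuse$value)
    y <- sweep(y, 2L, ly$params$b$value, "+")
    ly$cache <- list(x = x, dims = dims, raw = raw, off = off, pos = pos,
                     gs = gs, outs = outs)
    array(y, dim = c(dims[1:3], cout))
  }
  ly$bwd <- function(dy) {
    cc <- ly$cache; dims <- cc$dims; N <- prod(dims[1:3])
    half <- spec$half
    dym <- matrix(dy, N, cout)
    ly$params$b$grad <- ly$params$b$grad + colSums(dym)
    douts <- switch(spec$fusion,
                    mean = rep(list(dym / 3), 3),
                    sum = rep(list(dym), 3),
                    concat = {
                      ly$params$fuse$grad <- ly$params$fuse$grad +
                        crossprod(cbind(cc$outs[[1]], cc$outs[[2]],
                                        cc$outs[[3]]), dym)
                      dall <- tcrossprod(dym, ly$params$fuse$value)
                      list(dall[, 1:cout, drop = FALSE],
                           dall[, cout + 1:cout, drop = FALSE],
                           dall[, 2 * cout + 1:cout, drop = FALSE])
                    })
    dx <- array(0, dim = dims)
    draw <- array(0, dim = dim(cc$raw))
    ddelta <- array(0, dim = c(N, 2L, half, 2L, 3L))
    wnames <- c("wx", "wy", "wz")
    for (i in 1:3) {
      axis <- c("x", "y", "z")[i]
      am <- snake_axis_map(axis)
      g <- cc$gs[[i]]; dim(g) <- c(N, P * cin)
      wa <- ly$params[[wnames[i]]]$value
      dwa <- crossprod(g, douts[[i]])
      dim(dwa) <- c(P, cin, cout)
      ly$params[[wnames[i]]]$grad <- ly$params[[wnames[i]]]$grad + dwa
      dim(wa) <- c(P * cin, cout)
      dg <- tcrossprod(douts[[i]], wa)      # N x (P*cin)
      dim(dg) <- c(N * P, cin)
      gr <- cpp_trilinear_gather_grad(as.vector(cc$x), dims, cc$pos[[i]],
                                      dg)
      dx <- dx + array(gr$grad_vol, dim = dims)
      gp <- gr$grad_pos                      # (N*P) x 3, tap-major rows
      # lateral position grads -> per-step offset grads via reversed cumsum
      for (k in 1:2) {
        lat <- am$lateral[k]
        for (side in 1:2) {
          acc <- numeric(N)
          for (s in half:1) {
            step <- if (side == 1L) s else -s
            rows <- (step + half) * N + seq_len(N)
            acc <- acc + gp[rows, lat]
            ddelta[, k, s, side, i] <- ddelta[, k, s, side, i] + acc
          }
        }
      }
    }
    # through the tanh squash into the raw offset predictions
    dim(ddelta) <- dim(cc$raw)
    draw <- ddelta * spec$max_step * (1 - tanh(cc$raw)^2)
    dx <- dx + ly$offconv$bwd(draw)
    dx
  }
  ly
}
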