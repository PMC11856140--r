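#' Trilinear sampling of a volume at fractional positions
#'
#' Samples `vol` at 0-based fractional voxel coordinates.  Each sample is the
#' separable 8-corner sum with hat weights `b(a, a') = max(0, 1 - |a - a'|)`;
#' lattice points outside the grid contribute their border-clamped
#' (replicated-edge) value, so weights always form a partition of unity.
#'
#' @param vol a [volume3d()] or bare 3D array.
#' @param positions numeric matrix with 3 columns `(d, h, w)` (or a length-3
#'   vector for a single position), 0-based, finite; out-of-bounds allowed.
#' @return numeric vector of sampled values, one per position.
#' @export
trilinear_sample <- function(vol, positions) {
  data <- vol_data(vol)
  positions <- as_positions(positions)
  if (any(!is.finite(positions)))
    stop("trilinear_sample: positions must be finite")
  drop(cpp_trilinear_gather(as.vector(data), c(dim(data), 1L), positions))
}

as_positions <- function(positions) {
  if (is.null(dim(positions))) {
    if (length(positions) != 3L)
      stop("positions must have 3 columns (d, h, w)")
    positions <- matrix(positions, ncol = 3L)
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns (d, h, w)")
  storage.mode(positions) <- "double"
  positions
}

#' Warp a volume or label map by a displacement field
#'
#' Spatial-transformer resampling: `out(p) = moving(p + u(p))` with trilinear
#' interpolation for intensity volumes and nearest-neighbour lookup for
#' label maps.  Label maps must use `mode = "nearest"` (labels are
#' categorical and must never be averaged).
#'
#' @param moving [volume3d()] or [labelmap3d()].
#' @param field [dispfield()] with the same grid shape.
#' @param mode `"trilinear"` or `"nearest"`; defaults to the type-appropriate
#'   mode (`trilinear` for volumes, `nearest` for label maps).
#' @return warped object of the same class as `moving`.
#' @export
warp_volume <- function(moving, field,
                        mode = if (inherits(moving, "labelmap3d"))
                          "nearest" else "trilinear") {
  mode <- match.arg(mode, c("trilinear", "nearest"))
  stopifnot(inherits(field, "dispfield"))
  shape <- vol_shape(moving)
  if (!identical(shape, vol_shape(field)))
    stop("warp_volume: field shape does not match moving")
  if (inherits(moving, "labelmap3d") && mode == "trilinear")
    stop("warp_volume: label maps must be warped with mode = \"nearest\"")
  pos <- grid_positions(shape) + matrix(field$vectors, ncol = 3L)
  if (mode == "trilinear") {
    data <- vol_data(moving)
    out <- drop(cpp_trilinear_gather(as.vector(data), c(shape, 1L), pos))
    volume3d(array(out, dim = shape),
             spacing = if (inherits(moving, "volume3d")) moving$spacing
                       else c(1, 1, 1))
  } else {
    data <- vol_data(moving)
    out <- cpp_nearest_gather(as.vector(data), shape, pos)
    out <- array(out, dim = shape)
    if (inherits(moving, "labelmap3d")) labelmap3d(out)
    else volume3d(out, spacing = if (inherits(moving, "volume3d"))
      moving$spacing else c(1, 1, 1))
  }
}

# 0-based voxel coordinates of every grid point, as an N x 3 matrix in the
# array's column-major order (d fastest).
grid_positions <- function(shape) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  cbind(rep.int(0:(D - 1), H * W),
        rep.int(rep(0:(H - 1), each = D), W),
        rep(0:(W - 1), each = D * H))
}

#' Jacobian determinant map of a deformation
#'
#' Computes `det(I3 + grad(u))` of the mapping `p -> p + u(p)` at every
#' voxel, with central differences in the interior and one-sided differences
#' at the boundary.  The identity field yields a determinant of exactly 1
#' everywhere; negative or zero values flag folding (loss of local
#' invertibility).
#'
#' @param field [dispfield()]; all grid dimensions must be at least 2.
#' @return object of class `jacobianmap` with element `det`, a 3D array.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "dispfield"))
  u <- field$vectors
  shape <- dim(u)[1:3]
  if (any(shape < 2L))
    stop("jacobian_determinant: all dimensions must be >= 2")
  # J[ , , , i, j] = d u_i / d x_j
  J <- array(0, dim = c(shape, 3L, 3L))
  for (i in 1:3)
    for (j in 1:3)
      J[, , , i, j] <- axis_gradient(u[, , , i], j)
  d11 <- 1 + J[, , , 1, 1]; d12 <- J[, , , 1, 2]; d13 <- J[, , , 1, 3]
  d21 <- J[, , , 2, 1]; d22 <- 1 + J[, , , 2, 2]; d23 <- J[, , , 2, 3]
  d31 <- J[, , , 3, 1]; d32 <- J[, , , 3, 2]; d33 <- 1 + J[, , , 3, 3]
  det <- d11 * (d22 * d33 - d23 * d32) -
         d12 * (d21 * d33 - d23 * d31) +
         d13 * (d21 * d32 - d22 * d31)
  structure(list(det = array(det, dim = shape)), class = "jacobianmap")
}

# Central differences in the interior, one-sided at the two boundary slices.
axis_gradient <- function(a, axis) {
  shape <- dim(a)
  n <- shape[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  h <- idx_p - idx_m  # 2 interior, 1 at the boundary
  slice <- function(idx) {
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  g <- slice(idx_p) - slice(idx_m)
  hs <- switch(axis,
               array(h, dim = shape),
               aperm(array(h, dim = shape[c(2, 1, 3)]), c(2, 1, 3)),
               aperm(array(h, dim = shape[c(3, 1, 2)]), c(2, 3, 1)))
  g / hs
}

#' Fraction of non-diffeomorphic voxels
#'
#' Fraction of voxels whose Jacobian determinant is `<= 0`, i.e. where the
#' deformation folds and stops being locally invertible.  Multiply by 100
#' for the percentage convention used in registration result tables.
#'
#' @param jac a `jacobianmap` from [jacobian_determinant()], or a
#'   [dispfield()] (which is analysed first).
#' @return scalar fraction in `[0, 1]`.
#' @export
pct_nondiffeomorphic <- function(jac) {
  if (inherits(jac, "dispfield")) jac <- jacobian_determinant(jac)
  stopifnot(inherits(jac, "jacobianmap"))
  mean(jac$det <= 0)
}

#' @export
print.jacobianmap <- function(x, ...) {
  cat(sprintf("<jacobianmap, det range [%.4g, %.4g], %% det<=0 = %.4g>\n",
              min(x$det), max(x$det), 100 * mean(x$det <= 0)))
  invisible(x)
}
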