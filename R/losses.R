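#' Loss configuration
#'
#' @param ncc_window odd window side for the local NCC (default 9 voxels,
#'   the usual choice for brain MRI).
#' @param lambda_reg weight of the gradient-L2 smoothness penalty
#'   (default 0.02).
#' @param ssim_weight weight of the optional SSIM term in the optimization
#'   energy (default 0 = off).
#' @param epsilon variance guard of the NCC denominator.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(ncc_window = 9L, lambda_reg = 0.02,
                        ssim_weight = 0, epsilon = 1e-5) {
  ncc_window <- as.integer(ncc_window)
  if (ncc_window < 3L || ncc_window %% 2L == 0L)
    stop("ncc_window must be odd and >= 3")
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  structure(list(ncc_window = ncc_window, lambda_reg = lambda_reg,
                 ssim_weight = ssim_weight, epsilon = epsilon),
            class = "loss_config")
}

# windowed sums needed by the local correlation, with truncated
# (border-shrinking) windows.
ncc_terms <- function(f, m, r) {
  shape <- dim(f)
  bs <- function(x) array(cpp_boxsum3(as.vector(x), shape, r), dim = shape)
  n <- bs(array(1, dim = shape))
  list(n = n, sf = bs(f), sm = bs(m), sff = bs(f * f), smm = bs(m * m),
       sfm = bs(f * m))
}

#' Local normalized cross-correlation similarity
#'
#' Mean over voxels of the standard windowed squared correlation
#' coefficient `cc = cross^2 / (varF * varM + eps)` where `cross`, `varF`,
#' `varM` are window-sum covariance/variance terms over an `n^3`
#' neighbourhood (windows shrink at the border); `eps` guards the
#' denominator, so locally flat (zero-variance) windows score 0 and
#' identical images with non-degenerate local variance score 1 to within
#' `eps / var^2`.  Invariant to positive affine intensity rescaling of
#' either image.
#'
#' @param fixed,warped [volume3d()] objects (or bare arrays) of equal shape.
#' @param cfg a [loss_config()].
#' @return scalar similarity in `[0, 1]`.
#' @export
local_ncc <- function(fixed, warped, cfg = loss_config()) {
  mean(local_ncc_map(fixed, warped, cfg))
}

#' Per-voxel local squared correlation map
#' @inheritParams local_ncc
#' @return 3D array of per-voxel `cc` values.
#' @export
local_ncc_map <- function(fixed, warped, cfg = loss_config()) {
  f <- vol_data(fixed); m <- vol_data(warped)
  if (!identical(dim(f), dim(m))) stop("local_ncc: shapes differ")
  if (cfg$ncc_window > min(dim(f)))
    stop("local_ncc: window larger than the volume")
  r <- (cfg$ncc_window - 1L) %/% 2L
  tm <- ncc_terms(f, m, r)
  cross <- tm$sfm - tm$sf * tm$sm / tm$n
  varf <- pmax(tm$sff - tm$sf^2 / tm$n, 0)
  varm <- pmax(tm$smm - tm$sm^2 / tm$n, 0)
  cross^2 / (varf * varm + cfg$epsilon)
}

# value and analytic gradient of local_ncc w.r.t. the warped image.
local_ncc_grad <- function(fixed, warped, cfg = loss_config()) {
  f <- vol_data(fixed); m <- vol_data(warped)
  shape <- dim(f)
  r <- (cfg$ncc_window - 1L) %/% 2L
  tm <- ncc_terms(f, m, r)
  cross <- tm$sfm - tm$sf * tm$sm / tm$n
  varf <- pmax(tm$sff - tm$sf^2 / tm$n, 0)
  varm <- pmax(tm$smm - tm$sm^2 / tm$n, 0)
  D <- varf * varm + cfg$epsilon
  cc <- cross^2 / D
  P <- prod(shape)
  A <- 2 * cross / D
  B <- 2 * cross^2 * varf / D^2
  bs <- function(x) array(cpp_boxsum3(as.vector(x), shape, r), dim = shape)
  grad <- (f * bs(A) - bs(A * tm$sf / tm$n) -
           m * bs(B) + bs(B * tm$sm / tm$n)) / P
  list(value = mean(cc), grad = grad)
}

#' Gradient-L2 smoothness of a displacement field
#'
#' Sum over the three displacement components and the three axes of the
#' mean squared forward difference; a uniform translation scores exactly 0
#' and a unit-slope component scores exactly 1.
#'
#' @param field a [dispfield()] (or bare `(D, H, W, 3)` array).
#' @return non-negative scalar.
#' @export
grad_l2 <- function(field) {
  u <- if (inherits(field, "dispfield")) field$vectors else field
  cpp_grad_l2(as.vector(u), dim(u)[1:3], FALSE)$value
}

fwd_diff <- function(a, axis) {
  switch(axis,
         a[-1, , , drop = FALSE] - a[-dim(a)[1], , , drop = FALSE],
         a[, -1, , drop = FALSE] - a[, -dim(a)[2], , drop = FALSE],
         a[, , -1, drop = FALSE] - a[, , -dim(a)[3], drop = FALSE])
}

# gradient of grad_l2 w.r.t. the field (adjoint of the forward differences)
grad_l2_grad <- function(u) {
  array(cpp_grad_l2(as.vector(u), dim(u)[1:3], TRUE)$grad, dim = dim(u))
}

#' Registration energy of a displacement field
#'
#' The instance-optimization objective
#' `(1 - NCC(fixed, moving o field)) + lambda * grad_l2(field)`, optionally
#' plus `ssim_weight * (1 - SSIM(fixed, moving o field))`.  Zero exactly
#' when the warped moving image equals the fixed image and the field is
#' uniform.
#'
#' @param fixed,moving [volume3d()] objects.
#' @param field [dispfield()].
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
energy <- function(fixed, moving, field, cfg = loss_config()) {
  energy_grad(fixed, moving, field, cfg, want_grad = FALSE)$value
}

# energy and its analytic gradient w.r.t. the field: the NCC (and optional
# SSIM) image gradient is chained through the trilinear sampler's position
# derivative (the sampled spatial gradient of the moving image).
energy_grad <- function(fixed, moving, field, cfg = loss_config(),
                        want_grad = TRUE) {
  u <- if (inherits(field, "dispfield")) field$vectors else field
  shape <- dim(u)[1:3]
  mov <- vol_data(moving)
  pos <- grid_positions(shape) + matrix(u, ncol = 3L)
  warped <- array(drop(cpp_trilinear_gather(as.vector(mov), c(shape, 1L),
                                            pos)), dim = shape)
  ng <- local_ncc_grad(fixed, warped, cfg)
  value <- (1 - ng$value) + cfg$lambda_reg * grad_l2(dispfield(u))
  dwarped <- -ng$grad
  if (cfg$ssim_weight > 0) {
    sg <- ssim3d_grad(vol_data(fixed), warped)
    value <- value + cfg$ssim_weight * (1 - sg$value)
    dwarped <- dwarped - cfg$ssim_weight * sg$grad
  }
  if (!want_grad) return(list(value = value))
  gr <- cpp_trilinear_gather_grad(as.vector(mov), c(shape, 1L), pos,
                                  matrix(dwarped, ncol = 1L))
  grad <- array(gr$grad_pos, dim = c(shape, 3L)) +
    cfg$lambda_reg * grad_l2_grad(u)
  list(value = value, grad = grad)
}

#' Weakly supervised field loss
#'
#' Mean squared difference between a predicted field and its pseudo-ground
#' truth over all voxel-components, plus `lambda * grad_l2(field)`.  The
#' pseudo field is a constant target: no gradient flows into it.
#'
#' @param field predicted [dispfield()].
#' @param pseudo pseudo-ground-truth [dispfield()] of equal shape.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
supervised_loss <- function(field, pseudo, cfg = loss_config()) {
  u <- if (inherits(field, "dispfield")) field$vectors else field
  v <- if (inherits(pseudo, "dispfield")) pseudo$vectors else pseudo
  if (!identical(dim(u), dim(v))) stop("supervised_loss: shapes differ")
  mean((u - v)^2) + cfg$lambda_reg * grad_l2(dispfield(u))
}

supervised_loss_grad <- function(u, v, cfg = loss_config()) {
  list(value = mean((u - v)^2) + cfg$lambda_reg * grad_l2(dispfield(u)),
       grad = 2 * (u - v) / length(u) + cfg$lambda_reg * grad_l2_grad(u))
}

# separable Gaussian smoothing with border renormalization
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm((-r):r, sd = sigma)
  k / sum(k)
}

smooth_axis <- function(a, axis, k) {
  r <- (length(k) - 1L) %/% 2L
  shape <- dim(a)
  out <- array(0, dim = shape)
  n <- shape[axis]
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- pmax(pmin(seq_len(n) + off, n + 1L), 0L)  # out of range -> drop
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst_idx <- which(keep)
    src_idx <- src[keep]
    if (axis == 1L) out[dst_idx, , ] <- out[dst_idx, , , drop = FALSE] +
        k[t] * a[src_idx, , , drop = FALSE]
    else if (axis == 2L) out[, dst_idx, ] <- out[, dst_idx, , drop = FALSE] +
        k[t] * a[, src_idx, , drop = FALSE]
    else out[, , dst_idx] <- out[, , dst_idx, drop = FALSE] +
        k[t] * a[, , src_idx, drop = FALSE]
  }
  out
}

gsmooth0 <- function(a, k) {
  smooth_axis(smooth_axis(smooth_axis(a, 1L, k), 2L, k), 3L, k)
}

#' Structural similarity of two volumes
#'
#' Gaussian-windowed SSIM (window sd 1.5 voxels, stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`), averaged over the volume.
#' Intensities are assumed pre-scaled to the declared dynamic range `L`.
#'
#' @param a,b [volume3d()] objects or arrays of equal shape.
#' @param dynamic_range declared intensity range `L` (default 1).
#' @param sigma Gaussian window standard deviation in voxels.
#' @return scalar in `[-1, 1]`.
#' @export
ssim3d <- function(a, b, dynamic_range = 1, sigma = 1.5) {
  ssim3d_grad(vol_data(a), vol_data(b), dynamic_range, sigma,
              want_grad = FALSE)$value
}

ssim3d_grad <- function(a, b, dynamic_range = 1, sigma = 1.5,
                        want_grad = TRUE) {
  if (!identical(dim(a), dim(b))) stop("ssim3d: shapes differ")
  k <- gauss_kernel(sigma)
  ones <- gsmooth0(array(1, dim = dim(a)), k)
  G <- function(x) gsmooth0(x, k) / ones
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mua <- G(a); mub <- G(b)
  va <- G(a * a) - mua^2
  vb <- G(b * b) - mub^2
  cab <- G(a * b) - mua * mub
  A1 <- 2 * mua * mub + C1; A2 <- 2 * cab + C2
  B1 <- mua^2 + mub^2 + C1; B2 <- va + vb + C2
  S <- (A1 * A2) / (B1 * B2)
  if (!want_grad) return(list(value = mean(S)))
  # adjoint of the renormalized filter: Gt(z) = G0(z / ones)
  Gt <- function(z) gsmooth0(z / ones, k)
  dS_dmub <- 2 * mua * A2 / (B1 * B2) - 2 * mub * S / B1
  dS_dcab <- 2 * A1 / (B1 * B2)
  dS_dvb <- -S / B2
  P <- length(a)
  grad <- (Gt(dS_dmub) + a * Gt(dS_dcab) - Gt(dS_dcab * mua) +
           2 * b * Gt(dS_dvb) - 2 * Gt(dS_dvb * mub)) / P
  list(value = mean(S), grad = grad)
}

#' Dice overlap of two label maps
#'
#' Per foreground label `2 |A n B| / (|A| + |B|)`; labels absent from both
#' maps are excluded and the mean is over the labels present in at least
#' one map.
#'
#' @param a,b [labelmap3d()] objects (or integer arrays) of equal shape.
#' @return list with `per_label` (named vector) and `mean`.
#' @export
dice_score <- function(a, b) {
  la <- if (inherits(a, "labelmap3d")) a$labels else a
  lb <- if (inherits(b, "labelmap3d")) b$labels else b
  if (!identical(dim(la), dim(lb))) stop("dice_score: shapes differ")
  labs <- sort(union(unique(as.vector(la)), unique(as.vector(lb))))
  labs <- labs[labs > 0]
  if (length(labs) == 0L)
    stop("dice_score: no foreground labels present in either map")
  per <- vapply(labs, function(l) {
    ia <- la == l; ib <- lb == l
    2 * sum(ia & ib) / (sum(ia) + sum(ib))
  }, numeric(1))
  names(per) <- labs
  list(per_label = per, mean = mean(per))
}

# weighted SSIM term of a warped pair as a function of the field, with its
# gradient chained through the trilinear sampler (the optional hook of the
# weakly supervised training loss; inactive at the default weight 0).
ssim_field_term <- function(fixed, moving, u, cfg) {
  shape <- dim(u)[1:3]
  mov <- vol_data(moving)
  pos <- grid_positions(shape) + matrix(u, ncol = 3L)
  warped <- array(drop(cpp_trilinear_gather(as.vector(mov), c(shape, 1L),
                                            pos)), dim = shape)
  sg <- ssim3d_grad(vol_data(fixed), warped)
  gr <- cpp_trilinear_gather_grad(as.vector(mov), c(shape, 1L), pos,
                                  matrix(-cfg$ssim_weight * sg$grad,
                                         ncol = 1L))
  list(value = cfg$ssim_weight * (1 - sg$value),
       grad = array(gr$grad_pos, dim = c(shape, 3L)))
}
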