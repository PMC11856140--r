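#' Phantom specification
#'
#' Describes a brain-like labelled phantom: a set of strictly nested
#' randomized ellipsoidal shells (emulating cortex / white-matter /
#' ventricle-like structures) sharing a jittered center, with distinct
#' per-structure mean intensities, additive Gaussian noise and optional
#' Gaussian smoothing.
#'
#' @param shape grid shape (default 32^3).
#' @param n_structures number of nested shells (default 4).
#' @param intensities per-structure means (innermost last); defaults to an
#'   evenly spaced, strictly increasing ramp.
#' @param noise_sd additive Gaussian noise sd (default 0.02).
#' @param smooth_sd Gaussian smoothing sd in voxels (default 0.5; 0 = off).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), n_structures = 4L,
                         intensities = NULL, noise_sd = 0.02,
                         smooth_sd = 0.5) {
  shape <- as.integer(rep_len(shape, 3L))
  n_structures <- as.integer(n_structures)
  if (n_structures < 1L) stop("need at least one structure")
  if (is.null(intensities))
    intensities <- seq(0.3, 1, length.out = n_structures)
  if (length(intensities) != n_structures ||
      anyDuplicated(intensities))
    stop("intensities must be one distinct value per structure")
  if (noise_sd < 0 || smooth_sd < 0) stop("sd values must be >= 0")
  structure(list(shape = shape, n_structures = n_structures,
                 intensities = intensities, noise_sd = noise_sd,
                 smooth_sd = smooth_sd), class = "phantom_spec")
}

#' Generate a labelled phantom
#'
#' Rasterizes the nested ellipsoids into a label map (label `k` = inside
#' exactly the `k` outermost shells; background 0) and renders intensities
#' as per-label means plus noise, optionally smoothed.  Deterministic per
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `volume` ([volume3d()]) and `labels` ([labelmap3d()]).
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  set.seed(seed)
  shape <- spec$shape
  center <- (shape - 1) / 2 + runif(3, -1, 1) * shape / 16
  semi_max <- pmin(center, shape - 1 - center) - 1
  if (any(semi_max < spec$n_structures))
    stop("make_phantom: grid too small for the requested structures")
  semi1 <- semi_max * runif(3, 0.85, 0.98)
  fracs <- seq(1, 0.3, length.out = spec$n_structures) *
    (1 + runif(spec$n_structures, -0.04, 0.04))
  fracs <- sort(fracs, decreasing = TRUE)
  fracs[1] <- min(fracs[1], 1)
  pos <- grid_positions(shape)
  labels <- integer(nrow(pos))
  for (k in seq_len(spec$n_structures)) {
    semi <- semi1 * fracs[k]
    if (any(center + semi > shape - 1) || any(center - semi < 0))
      stop("make_phantom: ellipsoid exceeds the grid")
    inside <- ((pos[, 1] - center[1]) / semi[1])^2 +
      ((pos[, 2] - center[2]) / semi[2])^2 +
      ((pos[, 3] - center[3]) / semi[3])^2 <= 1
    labels[inside] <- labels[inside] + 1L
  }
  labels <- array(labels, dim = shape)
  if (!any(labels == spec$n_structures))
    stop("make_phantom: innermost structure is empty")
  intens <- c(0, spec$intensities)[labels + 1L]
  vol <- array(intens, dim = shape)
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd),
                       dim = shape)
  if (spec$smooth_sd > 0)
    vol <- gsmooth0(vol, gauss_kernel(spec$smooth_sd)) /
      gsmooth0(array(1, dim = shape), gauss_kernel(spec$smooth_sd))
  list(volume = volume3d(vol), labels = labelmap3d(labels))
}

#' Ground-truth field specification
#'
#' @param amplitude maximum displacement magnitude in voxels (default 2).
#' @param smoothness Gaussian smoothing sd of the field in voxels
#'   (default 4); together with the amplitude this keeps displacement
#'   gradients below the folding threshold.
#' @param max_tries amplitude-reduction retries if folding occurs.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(amplitude = 2, smoothness = 4, max_tries = 5L) {
  if (amplitude < 0 || smoothness <= 0) stop("invalid field_spec")
  structure(list(amplitude = amplitude, smoothness = smoothness,
                 max_tries = as.integer(max_tries)),
            class = "field_spec")
}

#' Generate a smooth, fold-free random displacement field
#'
#' Per-component white noise is Gaussian-smoothed and rescaled so the
#' largest displacement vector has magnitude `amplitude`; the result is
#' verified fold-free by an exhaustive Jacobian-determinant scan and
#' regenerated at reduced amplitude if needed.  Deterministic per seed.
#'
#' @param shape grid shape.
#' @param spec a [field_spec()].
#' @param seed integer seed.
#' @return a [dispfield()] with strictly positive Jacobian determinant.
#' @export
make_smooth_field <- function(shape, spec = field_spec(), seed = 1L) {
  set.seed(seed)
  shape <- as.integer(rep_len(shape, 3L))
  if (spec$amplitude == 0) return(zero_field(shape))
  k <- gauss_kernel(spec$smoothness)
  raw <- array(rnorm(prod(shape) * 3), dim = c(shape, 3L))
  sm <- array(0, dim = c(shape, 3L))
  for (i in 1:3) sm[, , , i] <- gsmooth0(raw[, , , i], k)
  amp <- spec$amplitude
  for (try in seq_len(spec$max_tries)) {
    mag <- sqrt(sm[, , , 1]^2 + sm[, , , 2]^2 + sm[, , , 3]^2)
    u <- sm * (amp / max(mag))
    f <- dispfield(u)
    if (min(jacobian_determinant(f)$det) > 0) return(f)
    amp <- amp * 0.8
  }
  stop("make_smooth_field: could not generate a fold-free field")
}

#' Generate a synthetic registration case
#'
#' The moving image is a phantom; the fixed image is the moving image
#' warped by a smooth fold-free ground-truth field (so the truth is exact
#' by construction), with labels warped in nearest mode.
#'
#' @param pspec a [phantom_spec()]; @param fspec a [field_spec()].
#' @param seed integer seed (phantom and field derive sub-seeds from it).
#' @return a `regcase` with `gt_field` set.
#' @export
make_pair <- function(pspec = phantom_spec(), fspec = field_spec(),
                      seed = 1L) {
  ph <- make_phantom(pspec, seed = seed)
  gt <- make_smooth_field(pspec$shape, fspec,
                          seed = (seed + 1000003L) %% .Machine$integer.max)
  fixed <- warp_volume(ph$volume, gt, "trilinear")
  fixed_labels <- warp_volume(ph$labels, gt, "nearest")
  registration_case(moving = ph$volume, fixed = fixed,
                    moving_labels = ph$labels,
                    fixed_labels = fixed_labels,
                    gt_field = gt, seed = as.integer(seed))
}

#' Generate a suite of seeded cases
#'
#' @param n number of cases.
#' @param pspec,fspec phantom and field specifications.
#' @param seed base seed; case `i` uses `seed + i - 1`.
#' @return list of `regcase` objects.
#' @export
make_suite <- function(n, pspec = phantom_spec(), fspec = field_spec(),
                       seed = 1L) {
  lapply(seq_len(n), function(i) make_pair(pspec, fspec,
                                           seed = seed + i - 1L))
}
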