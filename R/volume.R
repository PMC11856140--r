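#' 3D scalar volume
#'
#' A `volume3d` wraps a 3-dimensional numeric array of intensities indexed
#' `(d, h, w)` together with a per-axis voxel spacing.  All geometry in the
#' package is expressed in 0-based voxel units; spacing is carried for I/O
#' round-trips only and never used for resampling.
#'
#' @param data numeric 3D array, all values finite.
#' @param spacing numeric length-3 voxel size per axis (default 1).
#' @return object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3d(data)
  if (any(!is.finite(data))) stop("volume3d: intensities must be finite")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("volume3d: spacing must be positive")
  structure(list(data = data, spacing = spacing), class = "volume3d")
}

#' Integer label map companion to a volume
#'
#' Non-negative integer labels on the same grid as a [volume3d()];
#' background is label 0.
#'
#' @param labels integer-valued 3D array of non-negative labels.
#' @return object of class `labelmap3d`.
#' @export
labelmap3d <- function(labels) {
  labels <- as_array3d(labels)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labelmap3d: labels must be finite non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "labelmap3d")
}

#' Per-voxel displacement field
#'
#' A dense displacement field `u` on a `(d, h, w)` grid with 3-vector values
#' ordered `(delta_d, delta_h, delta_w)` in voxel units.  The warping
#' convention is `warped(p) = moving(p + u(p))` with `p` a 0-based voxel
#' coordinate.
#'
#' @param vectors numeric 4D array with dim `(D, H, W, 3)`.
#' @return object of class `dispfield`.
#' @export
dispfield <- function(vectors) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("dispfield: vectors must be a (D, H, W, 3) array")
  if (any(!is.finite(vectors))) stop("dispfield: components must be finite")
  structure(list(vectors = vectors), class = "dispfield")
}

#' Zero displacement field for a grid shape
#' @param shape integer length-3 grid dimensions.
#' @return a [dispfield()] of zeros.
#' @export
zero_field <- function(shape) {
  dispfield(array(0, dim = c(shape, 3L)))
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array, got a vector")
  x <- as.array(x)
  if (length(dim(x)) != 3L)
    stop(sprintf("expected a 3D array, got rank %d", length(dim(x))))
  if (any(dim(x) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(x) <- "double"
  x
}

vol_data <- function(x) {
  if (inherits(x, "volume3d")) x$data
  else if (inherits(x, "labelmap3d")) {
    y <- x$labels; storage.mode(y) <- "double"; y
  } else as_array3d(x)
}

vol_shape <- function(x) {
  if (inherits(x, "volume3d")) dim(x$data)
  else if (inherits(x, "labelmap3d")) dim(x$labels)
  else if (inherits(x, "dispfield")) dim(x$vectors)[1:3]
  else dim(as.array(x))[1:3]
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d %dx%dx%d, spacing %s, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.labelmap3d <- function(x, ...) {
  d <- dim(x$labels)
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<labelmap3d %dx%dx%d, labels {%s}>\n", d[1], d[2], d[3],
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' @export
print.dispfield <- function(x, ...) {
  d <- dim(x$vectors)
  cat(sprintf("<dispfield %dx%dx%d, |u| max %.4g voxels>\n", d[1], d[2],
              d[3], max(abs(x$vectors))))
  invisible(x)
}

#' Bundle of a registration case
#'
#' Groups a moving/fixed volume pair with optional label maps and an
#' optional ground-truth displacement field (present for synthetic cases).
#'
#' @param moving,fixed [volume3d()] objects of equal shape.
#' @param moving_labels,fixed_labels optional [labelmap3d()] objects.
#' @param gt_field optional [dispfield()] mapping moving onto fixed.
#' @param seed integer seed the case was generated from (or `NA`).
#' @return object of class `regcase`.
#' @export
registration_case <- function(moving, fixed, moving_labels = NULL,
                              fixed_labels = NULL, gt_field = NULL,
                              seed = NA_integer_) {
  stopifnot(inherits(moving, "volume3d"), inherits(fixed, "volume3d"))
  if (!identical(vol_shape(moving), vol_shape(fixed)))
    stop("registration_case: moving and fixed shapes differ")
  for (lm in list(moving_labels, fixed_labels))
    if (!is.null(lm) && !identical(vol_shape(lm), vol_shape(moving)))
      stop("registration_case: label shape differs from volumes")
  if (!is.null(gt_field) && !identical(vol_shape(gt_field),
                                       vol_shape(moving)))
    stop("registration_case: gt_field shape differs from volumes")
  structure(list(moving = moving, fixed = fixed,
                 moving_labels = moving_labels,
                 fixed_labels = fixed_labels,
                 gt_field = gt_field, seed = seed),
            class = "regcase")
}

#' @export
print.regcase <- function(x, ...) {
  d <- vol_shape(x$moving)
  cat(sprintf("<regcase %dx%dx%d%s%s, seed %s>\n", d[1], d[2], d[3],
              if (!is.null(x$moving_labels)) " +labels" else "",
              if (!is.null(x$gt_field)) " +gt_field" else "",
              as.character(x$seed)))
  invisible(x)
}
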