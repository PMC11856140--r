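# NIfTI-1 input/output via RNifti.  The affine header is stored on write
# and carried through on read, but never used for resampling: all geometry
# in this package is voxel-indexed.

#' Read / write a 3D volume as NIfTI
#'
#' Accepts plain `.nii` and gzipped `.nii.gz`; the round trip preserves the
#' data, shape and voxel spacing.
#'
#' @param path file path.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("read_volume: expected a 3D image, got rank %d",
                 length(d)))
  volume3d(array(as.numeric(img), dim = d),
           spacing = abs(RNifti::pixdim(img))[1:3])
}

#' @rdname read_volume
#' @param vol a [volume3d()] to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a label map as NIfTI
#' @param path file path.
#' @return a [labelmap3d()].
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("read_labels: expected a 3D image, got rank %d",
                 length(d)))
  labelmap3d(array(as.integer(round(img)), dim = d))
}

#' @rdname read_labels
#' @param labels a [labelmap3d()] to write.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "labelmap3d"))
  RNifti::writeNifti(RNifti::asNifti(labels$labels), path)
  invisible(path)
}

FIELD_TAG <- "disp (dd,dh,dw) voxel"

#' Read / write a displacement field as 4D NIfTI
#'
#' Fields are stored as 4D images with the vector dimension last and
#' component order `(delta_d, delta_h, delta_w)` in voxel units, recorded
#' in the header description field.  Reading a 4D field without the tag
#' assumes this default order with a warning.
#'
#' @param path file path.
#' @return a [dispfield()].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf(
      "read_field: expected a 4D (D,H,W,3) image, got dims [%s]",
      paste(d, collapse = ", ")))
  descrip <- RNifti::niftiHeader(img)$descrip
  if (!identical(descrip, FIELD_TAG))
    warning("read_field: component-order tag missing; assuming ",
            FIELD_TAG)
  dispfield(array(as.numeric(img), dim = d))
}

#' @rdname read_field
#' @param field a [dispfield()] to write.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "dispfield"))
  img <- RNifti::asNifti(field$vectors, list(descrip = FIELD_TAG))
  RNifti::writeNifti(img, path)
  invisible(path)
}
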