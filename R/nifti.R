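#' Read a NIfTI volume
#'
#' Thin wrapper around \pkg{RNifti} returning the image as a plain array
#' with the NIfTI header retained in attributes.
#'
#' @param path path to a .nii / .nii.gz file.
#' @return An \code{niftiImage} array.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path, call. = FALSE)
  RNifti::readNifti(path)
}

#' Write a NIfTI volume
#'
#' Writes a 3-D or 4-D array as NIfTI-1, optionally inheriting the grid
#' (affine, voxel sizes) from a template image.
#'
#' @param data numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param template optional \code{niftiImage} (e.g. the analysis mask as read
#'   by [read_volume()]) whose geometry is copied.
#' @param voxel_size voxel edge lengths in mm (used when no template given).
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, template = NULL, voxel_size = NULL) {
  img <- if (!is.null(template)) {
    RNifti::asNifti(data, reference = template)
  } else {
    RNifti::asNifti(data)
  }
  if (is.null(template) && !is.null(voxel_size)) {
    RNifti::pixdim(img) <- rep_len(voxel_size, length(dim(data)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes live on the same grid
#'
#' Errors unless dimensions, voxel sizes and affines agree (paired data/mask
#' contract).
#'
#' @param a,b arrays or \code{niftiImage}s.
#' @param tol numerical tolerance on voxel sizes / affine entries.
#' @return \code{TRUE}, invisibly.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!all(da == db)) {
    stop("volume grids differ in dimension: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), call. = FALSE)
  }
  pa <- tryCatch(RNifti::pixdim(a)[1:3], error = function(e) NULL)
  pb <- tryCatch(RNifti::pixdim(b)[1:3], error = function(e) NULL)
  if (!is.null(pa) && !is.null(pb) && any(abs(pa - pb) > tol)) {
    stop("volume grids differ in voxel size", call. = FALSE)
  }
  xa <- tryCatch(RNifti::xform(a), error = function(e) NULL)
  xb <- tryCatch(RNifti::xform(b), error = function(e) NULL)
  if (!is.null(xa) && !is.null(xb) && any(abs(xa - xb) > tol)) {
    stop("volume affines differ", call. = FALSE)
  }
  invisible(TRUE)
}
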