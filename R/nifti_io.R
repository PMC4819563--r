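#' Write a 3D/4D array as NIfTI-1
#'
#' Thin wrapper over [RNifti::writeNifti()] that stamps the voxel
#' dimensions (mm) into the header; 4D images get a unit time step.
#'
#' @param x 3D or 4D numeric array.
#' @param pixdim numeric length 3, voxel dimensions in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeNiftiVolume <- function(x, pixdim, path) {
  stopifnot(length(pixdim) == 3L, all(pixdim > 0))
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("x must be a 3D or 4D array")
  im <- RNifti::asNifti(x)
  RNifti::pixdim(im) <- if (nd == 4L) c(pixdim, 1) else pixdim
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume as an array with voxel dimensions
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return list with `data` (plain numeric array) and `pixdim`
#'   (numeric length 3, mm).
#' @export
readNiftiVolume <- function(path) {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)[1:3]
  arr <- array(as.numeric(im), dim(im))
  list(data = arr, pixdim = pd)
}
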