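#' Write a volume image as NIfTI-1
#'
#' RAS voxel-to-world affine preserved in the sform/qform.
#'
#' @param vol a [volume_image()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a volume_image
#'
#' @param path a NIfTI file path.
#' @return a [volume_image()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  volume_image(array(as.numeric(img), dim(img)), unclass(aff))
}
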