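# NIfTI ingestion/emission. World orientation is ignored beyond the voxel
# size; the B0 direction is configuration, not header-derived.

#' Read a NIfTI volume
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return List with `values` (3D array) and `voxelSize` (numeric(3), mm,
#'   from the header pixdim).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim(img))
  if (length(dim(values)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path))
  vox <- RNifti::pixdim(img)[1:3]
  list(values = values, voxelSize = as.numeric(vox))
}

#' Write a 3D array as NIfTI
#'
#' @param values 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize numeric voxel size in mm (scalar recycled).
#' @return The path, invisibly.
#' @export
writeVolume <- function(values, path, voxelSize = 1) {
  stopifnot3d(values)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep_len(voxelSize, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
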