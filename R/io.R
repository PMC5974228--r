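# NIfTI-1 input/output via RNifti.

#' Write a label atlas as an integer NIfTI volume
#' @param atlas A `label_atlas`.
#' @param path Output .nii or .nii.gz path.
#' @return Invisibly, `path`.
#' @export
write_atlas_nifti <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$voxel_size
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "int16"), path)
  invisible(path)
}

#' Read a label atlas from a NIfTI volume
#' @param path NIfTI path with integer labels (0 background).
#' @return A `label_atlas`.
#' @export
read_atlas_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  label_atlas(round(as.array(img)), voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a BOLD series as a 4D NIfTI volume
#' @param series A `bold_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bold_nifti <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "float"), path)
  invisible(path)
}

#' Read a 4D BOLD series from NIfTI
#' @param path NIfTI path.
#' @param brain_mask Optional 3D logical mask; defaults to nonzero-variance
#'   voxels being included (all TRUE if NULL).
#' @param tr Repetition time override (s); taken from the header if NULL.
#' @return A `bold_series`.
#' @export
read_bold_nifti <- function(path, brain_mask = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  dat <- as.array(img)
  dat <- array(as.numeric(dat), dim = dim(dat))
  bold_series(dat, tr = tr, voxel_size = pd[1:3], brain_mask = brain_mask)
}

#' Write a connectivity matrix as CSV with a region-id header
#' @param cm A `connectivity_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_connectivity_csv <- function(cm, path) {
  v <- cm$values
  colnames(v) <- rownames(v) <- seq_len(nrow(v))
  utils::write.csv(v, path, row.names = TRUE)
  invisible(path)
}
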