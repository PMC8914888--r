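#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D array (numeric or logical; logical is written as 0/1).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel spacing recorded in the header.
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(vol, path, voxel_size_mm = 0.5) {
  if (is.logical(vol)) vol <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep_len(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List with `vol` (3D array) and `voxel_size_mm`.
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  list(vol = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Write a table as TSV with a header row
#'
#' Deterministic formatting (15 significant digits) so identical inputs give
#' byte-identical files.
#'
#' @param table Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(table, path) {
  tf <- table
  for (j in seq_along(tf)) {
    if (is.numeric(tf[[j]])) tf[[j]] <- formatC(tf[[j]], digits = 15,
                                                format = "g")
  }
  utils::write.table(tf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
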