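#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti for exchanging maps and masks. Write-then-read
#' round-trips preserve values to float32 precision and the geometry
#' exactly; masks containing 0/1 are preserved bit-exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume Numeric or logical array (3-D, or 4-D with trials/volumes
#'   along the fourth axis).
#' @return `read_volume()` returns the image as an array
#'   (`niftiImage`); `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_pitrel("no such file: ", path)
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  if (is.logical(volume)) volume <- array(as.numeric(volume), dim(volume))
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Read a set of volumes that must share geometry
#'
#' @param paths Character vector of NIfTI file paths.
#' @return A list of arrays; an error lists every file whose dimensions
#'   disagree with the first.
#' @export
read_volume_set <- function(paths) {
  vols <- lapply(paths, read_volume)
  ref <- dim(vols[[1]])
  bad <- paths[!vapply(vols, function(v) identical(dim(v), ref), TRUE)]
  if (length(bad))
    stop_pitrel("geometry mismatch relative to ", paths[1], ": ",
                paste(bad, collapse = ", "),
                class = "pitrel_geometry_error")
  vols
}
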