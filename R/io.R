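#' Read a 3-D volume from TIFF or NIfTI
#'
#' Accepts a multi-page TIFF stack, a directory of same-shape per-slice
#' TIFFs (sorted by file name; one z-slice per file), or a NIfTI-1 file
#' (`.nii` / `.nii.gz`). TIFF pages are read at their stored integer scale,
#' so integer volumes round-trip bit-exactly through [write_volume()].
#'
#' NIfTI files store spacing in mm; it is converted to micrometres and
#' overrides the `spacing_um` argument. NIfTI arrays are stored (x, y, z)
#' and are transposed to the package's (z, y, x) axis order on read.
#'
#' @param path file or directory path.
#' @param spacing_um voxel spacing in micrometres (used for TIFF input,
#'   which carries no reliable 3-D spacing).
#' @return A [volume()].
#' @export
read_volume <- function(path, spacing_um = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in directory: ", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    shapes <- vapply(slices, function(s) paste(dim(s), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop("inconsistent slice shapes: ", paste(unique(shapes), collapse = " vs "))
    d <- dim(slices[[1]])
    arr <- array(0, c(length(slices), d[1], d[2]))
    for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
    return(volume(arr, spacing_um))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    return(volume(arr, spacing_um = sp[1] * 1000))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(s) paste(dim(s), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("inconsistent slice shapes: ", paste(unique(shapes), collapse = " vs "))
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  volume(arr, spacing_um)
}

#' Write a 3-D volume to TIFF or NIfTI
#'
#' Multi-page 16-bit TIFF when `path` ends in `.tif`/`.tiff` (intensities
#' are clamped to the 16-bit range and rounded), NIfTI-1 otherwise.
#' NIfTI output is transposed to the (x, y, z) on-disk order and carries
#' the spacing as mm pixdim.
#'
#' @param vol a [volume()] (or [label_volume()], written as integers).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_lab <- inherits(vol, "fos_labels")
  arr <- if (is_lab) vol$labels else vol_data(as_volume(vol))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    nz <- dim(arr)[1]
    vals <- pmin(pmax(round(arr), 0), 65535)
    pages <- lapply(seq_len(nz), function(z) vals[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    disk <- aperm(arr, c(3, 2, 1))
    img <- RNifti::asNifti(disk)
    RNifti::pixdim(img) <- rep(vol$spacing_um / 1000, 3)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read / write label volumes as NIfTI
#'
#' Label maps are stored as integer NIfTI volumes with the same axis and
#' spacing conventions as [read_volume()].
#'
#' @param path NIfTI file path.
#' @param ontology optional [ontology()] attached to the result.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, ontology = NULL) {
  v <- read_volume(path)
  label_volume(array(as.integer(round(v$data)), dim(v$data)),
               spacing_um = v$spacing_um, ontology = ontology)
}

#' @rdname read_label_volume
#' @param labels a [label_volume()] to write.
#' @export
write_label_volume <- function(labels, path) {
  write_volume(labels, path)
}
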