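#' 3-D image volume
#'
#' The universal image currency of the package: a 3-D grid of non-negative
#' scalar intensities with isotropic voxel spacing in micrometres. The array
#' axis order is fixed to `(z, y, x)` throughout the package — the first
#' (fastest-varying) array index is z, matching slice-stack acquisition —
#' and voxel coordinates are 0-based and voxel-centred, so the physical
#' position of voxel `(z, y, x)` is `c(z, y, x) * spacing_um`.
#'
#' Intensities are conventionally in the 16-bit range (the canonical on-disk
#' type is unsigned 16-bit TIFF/NIfTI); internal computation uses doubles.
#'
#' @param data numeric 3-D array, non-negative finite intensities,
#'   axis order `(z, y, x)`.
#' @param spacing_um isotropic voxel edge length in micrometres (> 0).
#' @return An object of class `fos_volume` with elements `data` and
#'   `spacing_um`.
#' @export
volume <- function(data, spacing_um = 20) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  structure(list(data = data, spacing_um = as.numeric(spacing_um)),
            class = "fos_volume")
}

#' @export
dim.fos_volume <- function(x) dim(x$data)

#' @export
print.fos_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fos_volume> %d x %d x %d (z, y, x) @ %g um/voxel\n",
              d[1], d[2], d[3], x$spacing_um))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Labelled region volume
#'
#' An integer region map on the same grid convention as [volume()]:
#' label 0 is reserved for background (outside the tissue mask); every
#' non-zero label must appear as a `region_id` in the accompanying ontology.
#' Optional binary tissue and ventricular masks share the label grid shape.
#'
#' @param labels integer 3-D array `(z, y, x)` of non-negative region ids.
#' @param spacing_um isotropic voxel spacing in micrometres.
#' @param ontology an object from [ontology()]; may be `NULL` for
#'   intermediate label maps.
#' @param tissue_mask,ventricular_mask optional logical arrays, same shape.
#' @return An object of class `fos_labels`.
#' @export
label_volume <- function(labels, spacing_um = 20, ontology = NULL,
                         tissue_mask = NULL, ventricular_mask = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array (z, y, x)")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  if (!is.null(ontology)) {
    present <- setdiff(unique(as.vector(labels)), 0L)
    missing_ids <- setdiff(present, ontology$region_id)
    if (length(missing_ids))
      stop("labels absent from ontology: ", paste(missing_ids, collapse = ", "))
  }
  for (m in list(tissue_mask, ventricular_mask)) {
    if (!is.null(m) && !identical(dim(m), dim(labels)))
      stop("masks must share the label grid shape")
  }
  structure(list(labels = labels, spacing_um = as.numeric(spacing_um),
                 ontology = ontology, tissue_mask = tissue_mask,
                 ventricular_mask = ventricular_mask),
            class = "fos_labels")
}

#' @export
dim.fos_labels <- function(x) dim(x$labels)

#' @export
print.fos_labels <- function(x, ...) {
  d <- dim(x$labels)
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf("<fos_labels> %d x %d x %d (z, y, x) @ %g um/voxel, %d regions\n",
              d[1], d[2], d[3], x$spacing_um, n))
  invisible(x)
}

as_volume <- function(x, spacing_um = 20) {
  if (inherits(x, "fos_volume")) return(x)
  volume(x, spacing_um)
}

vol_data <- function(x) if (inherits(x, "fos_volume")) x$data else x
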