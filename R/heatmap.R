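# Cell-density heatmaps in atlas space.

#' Render a sphere-density heatmap of cell centres
#'
#' For each cell centre (atlas voxel coordinates), adds 1 to every voxel
#' whose centre lies within `radius_um` (Euclidean distance in physical
#' units, closed ball) of the cell centre; overlapping spheres sum and
#' spheres are clipped at the volume border. At the default 20 um radius
#' on a 20 um grid each interior cell contributes exactly 7 voxels (the
#' centre and its six face neighbours).
#'
#' @param cell_centers_atlas n x 3 matrix (z, y, x, 0-based voxel
#'   coordinates in atlas space) or a [cell_set()].
#' @param shape atlas grid shape (nz, ny, nx).
#' @param spacing_um atlas voxel spacing.
#' @param radius_um sphere radius in micrometres (>= 0).
#' @return A `fos_heatmap`: list with `density` (array), `spacing_um`,
#'   `n_cells_rendered`, `n_skipped` (centres outside the volume).
#' @export
render_heatmap <- function(cell_centers_atlas, shape, spacing_um = 20,
                           radius_um = 20) {
  if (inherits(cell_centers_atlas, "fos_cells"))
    cell_centers_atlas <-
      as.matrix(as.data.frame(cell_centers_atlas)[c("z", "y", "x")])
  centers <- matrix(as.numeric(cell_centers_atlas), ncol = 3)
  if (radius_um < 0) stop("radius_um must be >= 0")
  res <- cpp_sphere_splat(centers, as.integer(shape), radius_um / spacing_um)
  if (res$n_skipped > 0)
    warning(res$n_skipped, " cell centre(s) outside the volume skipped")
  structure(list(density = array(res$density, shape),
                 spacing_um = spacing_um,
                 n_cells_rendered = nrow(centers) - res$n_skipped,
                 n_skipped = res$n_skipped),
            class = "fos_heatmap")
}

#' @export
print.fos_heatmap <- function(x, ...) {
  cat(sprintf("<fos_heatmap> %s @ %g um, %d cells rendered, total mass %g\n",
              paste(dim(x$density), collapse = "x"), x$spacing_um,
              x$n_cells_rendered, sum(x$density)))
  invisible(x)
}

#' Voxelwise group-difference map of heatmaps
#'
#' `mean(A) - mean(B)` voxel by voxel; positive values mark higher density
#' in group A.
#'
#' @param heatmaps_A,heatmaps_B lists of `fos_heatmap`s (or density
#'   arrays) of equal shape, at least one per group.
#' @return A signed difference array with attribute `spacing_um`.
#' @export
group_difference <- function(heatmaps_A, heatmaps_B) {
  dens <- function(h) if (inherits(h, "fos_heatmap")) h$density else h
  a <- lapply(heatmaps_A, dens); b <- lapply(heatmaps_B, dens)
  if (!length(a) || !length(b)) stop("need >= 1 heatmap per group")
  d <- dim(a[[1]])
  if (!all(vapply(c(a, b), function(m) identical(dim(m), d), TRUE)))
    stop("shape mismatch among heatmaps")
  ma <- Reduce(`+`, a) / length(a)
  mb <- Reduce(`+`, b) / length(b)
  out <- ma - mb
  sp <- if (inherits(heatmaps_A[[1]], "fos_heatmap"))
    heatmaps_A[[1]]$spacing_um else NA_real_
  attr(out, "spacing_um") <- sp
  out
}
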