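# Registration-quality metrics: deformation magnitude, regional intensity
# variance across registered volumes, landmark distances with Welch
# comparison.

#' Voxelwise deformation magnitude
#'
#' The per-voxel Euclidean norm of a displacement field, in voxel units:
#' the magnitude of displacement needed to map each voxel of the fixed
#' grid into the moving image.
#'
#' @param field displacement array `(nz, ny, nx, 3)` or a `fos_transform`.
#' @param spacing_um spacing recorded on the output volume.
#' @return A [volume()] of magnitudes (voxel units).
#' @export
deformation_magnitude <- function(field, spacing_um = 20) {
  if (inherits(field, "fos_transform")) field <- as_field(field)
  if (length(dim(field)) != 4L || dim(field)[4] != 3L)
    stop("field must be (nz, ny, nx, 3)")
  if (any(!is.finite(field))) stop("field components must be finite")
  mag <- sqrt(field[, , , 1]^2 + field[, , , 2]^2 + field[, , , 3]^2)
  volume(mag, spacing_um)
}

#' Per-region intensity variance across registered volumes
#'
#' For a set of volumes registered to a common template, computes the
#' unbiased (n-1) sample variance of intensity at every voxel, then
#' averages the voxelwise variance over each region's voxels (mean IV).
#' Low IV means the registered volumes agree; it is the standard
#' intensity-based registration consistency measure. Optional blocks
#' (e.g. major brain divisions) aggregate as the mean of their member
#' regions' IVs.
#'
#' @param registered_vols list of >= 2 [volume()]s on the label grid.
#' @param labels a [label_volume()].
#' @param blocks optional named list of region-id vectors.
#' @return A `fos_region_iv`: data.frame `region_id`, `iv`, with
#'   attribute `"block_iv"` (named numeric) when blocks are given.
#' @export
intensity_variance <- function(registered_vols, labels, blocks = NULL) {
  if (length(registered_vols) < 2) stop("need >= 2 registered volumes")
  stopifnot(inherits(labels, "fos_labels"))
  d <- dim(labels)
  arrs <- lapply(registered_vols, function(v) {
    v <- as_volume(v)
    if (!identical(dim(v), d)) stop("volume/label grid mismatch")
    as.vector(v$data)
  })
  n <- length(arrs)
  m <- rowMeans(matrix(unlist(arrs), ncol = n))
  ss <- rowSums((matrix(unlist(arrs), ncol = n) - m)^2)
  vv <- ss / (n - 1)
  lab <- as.vector(labels$labels)
  ids <- sort(setdiff(unique(lab), 0L))
  iv <- vapply(ids, function(id) mean(vv[lab == id]), 0)
  out <- data.frame(region_id = ids, iv = iv)
  class(out) <- c("fos_region_iv", "data.frame")
  if (!is.null(blocks)) {
    block_iv <- vapply(blocks, function(members)
      mean(out$iv[out$region_id %in% members]), 0)
    attr(out, "block_iv") <- block_iv
  }
  out
}

#' Landmark distances between registered subjects and an atlas
#'
#' Matches landmarks by name and returns the per-landmark Euclidean
#' distance in micrometres (voxel coordinates scaled by `spacing_um`).
#'
#' @param subject_landmarks_registered,atlas_landmarks [landmark_set()]s
#'   with identical name sets.
#' @param spacing_um voxel spacing used to convert to micrometres.
#' @return data.frame `name`, `distance_um`.
#' @export
landmark_eval <- function(subject_landmarks_registered, atlas_landmarks,
                          spacing_um = 20) {
  s <- as.data.frame(subject_landmarks_registered)
  a <- as.data.frame(atlas_landmarks)
  if (!setequal(s$name, a$name))
    stop("landmark name mismatch: ",
         paste(union(setdiff(s$name, a$name), setdiff(a$name, s$name)),
               collapse = ", "))
  a <- a[match(s$name, a$name), ]
  d <- sqrt((s$z - a$z)^2 + (s$y - a$y)^2 + (s$x - a$x)^2) * spacing_um
  data.frame(name = s$name, distance_um = d)
}

#' Two-tailed Welch's t-test on per-landmark distance samples
#'
#' Compares, landmark by landmark, the distance samples obtained under two
#' atlas conditions (rows = subjects, columns = landmarks) with a
#' two-tailed Welch's t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom).
#'
#' @param distances_A,distances_B numeric matrices, subjects x landmarks,
#'   with matching column names.
#' @return data.frame `name`, `mean_A`, `mean_B`, `t`, `df`, `p`.
#' @export
landmark_compare <- function(distances_A, distances_B) {
  if (!identical(colnames(distances_A), colnames(distances_B)))
    stop("landmark name mismatch between conditions")
  res <- lapply(seq_len(ncol(distances_A)), function(j) {
    tt <- t.test(distances_A[, j], distances_B[, j], var.equal = FALSE)
    data.frame(name = colnames(distances_A)[j],
               mean_A = mean(distances_A[, j]),
               mean_B = mean(distances_B[, j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, res)
}
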