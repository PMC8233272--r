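# Dual-channel c-Fos positive cell detection, an adapted ClearMap-style
# chain: 2-D per-slice channel alignment, morphological background
# subtraction, autofluorescence false-positive removal, cube-filter maxima
# seeding, seeded watershed, size filtering, atlas region assignment.

#' Cell detection configuration
#'
#' Defaults follow the published parameterisation of the adapted chain:
#' a 5 x 5 x 3 maxima filter cube (z-extent 3, because axial resolution is
#' lower than in-plane), watershed background intensity cut-off 800
#' applied to the corrected specific channel, and segment size bounds
#' 8-194 voxels (segments smaller than 8 or bigger than 194 voxels are
#' removed; the bounds themselves survive).
#'
#' @param filter_cube integer (z, y, x) cube extents, all odd; default
#'   `c(3, 5, 5)`, i.e. 5 x 5 in-plane and 3 slices axially.
#' @param intensity_cutoff watershed background cut-off on the corrected
#'   specific channel.
#' @param min_size_vox,max_size_vox inclusive segment size bounds.
#' @param opening_disk_radius_vox disk radius of the per-slice top-hat.
#' @param autofluor_removal remove signal shared with the autofluorescence
#'   channel.
#' @param autofluor_scale `"robust"` (median specific/autofluorescence
#'   ratio over voxels where the autofluorescence exceeds its 99th
#'   percentile) or a fixed numeric scale.
#' @param align logical: run per-slice 2-D affine channel alignment.
#' @return A `fos_detect_config` list.
#' @export
detect_config <- function(filter_cube = c(3, 5, 5), intensity_cutoff = 800,
                          min_size_vox = 8, max_size_vox = 194,
                          opening_disk_radius_vox = 7,
                          autofluor_removal = TRUE,
                          autofluor_scale = "robust", align = TRUE) {
  filter_cube <- as.integer(filter_cube)
  if (any(filter_cube < 1L) || any(filter_cube %% 2L == 0L))
    stop("filter cube dims must be odd and >= 1")
  if (min_size_vox <= 0 || min_size_vox > max_size_vox)
    stop("need 0 < min_size_vox <= max_size_vox")
  if (intensity_cutoff < 0) stop("intensity_cutoff must be >= 0")
  structure(list(filter_cube = filter_cube,
                 intensity_cutoff = intensity_cutoff,
                 min_size_vox = as.integer(min_size_vox),
                 max_size_vox = as.integer(max_size_vox),
                 opening_disk_radius_vox = as.integer(opening_disk_radius_vox),
                 autofluor_removal = isTRUE(autofluor_removal),
                 autofluor_scale = autofluor_scale, align = isTRUE(align)),
            class = "fos_detect_config")
}

# 2-D affine registration of one slice pair by mutual information;
# slices are (y, x) matrices; returns list(A2 (2x2), t2, warped).
# The metric is evaluated on lightly smoothed copies (sub-voxel accuracy
# of linear-binned MI improves markedly); the raw slice is resampled.
register_slice_2d <- function(fixed, moving, nbins = 32, max_shift_frac = 0.15) {
  d <- dim(fixed)
  m3raw <- array(moving, c(1L, d))
  sm <- function(m) {
    a <- array(m, c(1L, dim(m)))
    array(cpp_gauss3(a, dim(a), c(0, 0.8, 0.8)), dim(m))
  }
  fixed <- sm(fixed); moving <- sm(moving)
  fr <- range(fixed); mr <- range(moving)
  if (diff(fr) == 0 || diff(mr) == 0)
    return(list(A2 = diag(2), t2 = c(0, 0),
                warped = array(m3raw, c(1, d))[1, , ]))
  f3 <- array(fixed, c(1L, d)); m3 <- array(moving, c(1L, d))
  obj <- function(par) {
    A <- diag(3); A[2:3, 2:3] <- matrix(par[1:4], 2, 2, byrow = TRUE)
    tv <- c(0, par[5:6])
    w <- cpp_sample_affine(m3, c(1L, d), as.numeric(t(A)), tv, c(1L, d), 0L)
    -mi_from_hist(cpp_joint_hist(as.numeric(f3), as.numeric(w), nbins,
                                 fr[1], fr[2], mr[1], mr[2]))
  }
  # coarse translation search on 2x down-sampled slices
  ds <- function(m) {
    dd <- (dim(m) %/% 2L) * 2L
    m <- m[seq_len(dd[1]), seq_len(dd[2]), drop = FALSE]
    (m[seq(1, dd[1], 2), seq(1, dd[2], 2)] + m[seq(2, dd[1], 2), seq(1, dd[2], 2)] +
     m[seq(1, dd[1], 2), seq(2, dd[2], 2)] + m[seq(2, dd[1], 2), seq(2, dd[2], 2)]) / 4
  }
  fd <- ds(fixed); md <- ds(moving)
  dd <- dim(fd)
  f3d <- array(fd, c(1L, dd)); m3d <- array(md, c(1L, dd))
  ext <- pmax(2, round(max_shift_frac * dd))
  best <- Inf; best_t <- c(0, 0)
  for (ty in seq(-ext[1], ext[1], by = 2))
    for (tx in seq(-ext[2], ext[2], by = 2)) {
      w <- cpp_sample_affine(m3d, c(1L, dd), as.numeric(t(diag(3))),
                             c(0, ty, tx), c(1L, dd), 0L)
      v <- -mi_from_hist(cpp_joint_hist(as.numeric(f3d), as.numeric(w), nbins,
                                        fr[1], fr[2], mr[1], mr[2]))
      if (v < best) { best <- v; best_t <- c(ty, tx) }
    }
  par <- c(1, 0, 0, 1, 2 * best_t)
  opt <- optim(par, obj, method = "BFGS",
               control = list(maxit = 25, reltol = 1e-6,
                              parscale = c(rep(0.02, 4), 1, 1)))
  A <- diag(3); A[2:3, 2:3] <- matrix(opt$par[1:4], 2, 2, byrow = TRUE)
  tv <- c(0, opt$par[5:6])
  mi_id <- obj(c(1, 0, 0, 1, 0, 0))
  if (opt$value > mi_id) { A <- diag(3); tv <- c(0, 0, 0); opt$par <- c(1, 0, 0, 1, 0, 0) }
  w <- cpp_sample_affine(m3raw, c(1L, d), as.numeric(t(A)), tv, c(1L, d), 0L)
  list(A2 = A[2:3, 2:3], t2 = tv[2:3], warped = array(w, c(1, d))[1, , ])
}

#' Align the specific channel to the autofluorescence channel
#'
#' Registers each z-slice of the specific channel to the matching
#' autofluorescence slice with a 2-D affine transform under a mutual
#' information criterion, then re-slices the specific volume. Slices are
#' processed independently.
#'
#' @param auto,spec [volume()]s of equal shape.
#' @return The re-sliced specific [volume()]; the per-slice affine
#'   parameters are attached as attribute `"slice_transforms"` (list of
#'   `list(A2, t2)` per slice).
#' @export
align_channels <- function(auto, spec) {
  auto <- as_volume(auto); spec <- as_volume(spec)
  if (!identical(dim(auto), dim(spec))) stop("shape mismatch between channels")
  d <- dim(auto)
  out <- array(0, d)
  tfs <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    r <- register_slice_2d(auto$data[z, , ], spec$data[z, , ])
    out[z, , ] <- pmax(r$warped, 0)
    tfs[[z]] <- list(A2 = r$A2, t2 = r$t2)
  }
  res <- volume(out, spec$spacing_um)
  attr(res, "slice_transforms") <- tfs
  res
}

#' Morphological background subtraction (per-slice top-hat)
#'
#' Subtracts, slice by slice, the grayscale opening with a disk element of
#' radius `disk_radius`: a 2-D white top-hat that isolates bright objects
#' smaller than the disk. The output satisfies `0 <= out <= vol`.
#'
#' @param vol a [volume()].
#' @param disk_radius disk radius in voxels (>= 1).
#' @return A [volume()].
#' @export
subtract_background <- function(vol, disk_radius = 7) {
  vol <- as_volume(vol)
  if (disk_radius < 1) stop("disk_radius must be >= 1")
  opened <- cpp_open_disk(vol$data, as.integer(dim(vol)),
                          as.integer(disk_radius))
  volume(array(vol$data - opened, dim(vol)), vol$spacing_um)
}

#' Remove signal shared with the autofluorescence channel
#'
#' False-positive signal that appears in both channels (elevated tissue
#' autofluorescence) is removed from the specific channel by scaled,
#' zero-clamped subtraction: `out = max(spec - s * auto, 0)`. The scale
#' `s` is estimated robustly as the median voxelwise specific/auto ratio
#' over voxels where the autofluorescence exceeds its 99th percentile, or
#' fixed via the config.
#'
#' @param spec_bg,auto_bg background-subtracted, aligned [volume()]s.
#' @param config a [detect_config()].
#' @return A [volume()] with `0 <= out <= spec_bg`; the scale used is
#'   attached as attribute `"autofluor_scale"`.
#' @export
remove_autofluorescence <- function(spec_bg, auto_bg,
                                    config = detect_config()) {
  spec_bg <- as_volume(spec_bg); auto_bg <- as_volume(auto_bg)
  stopifnot(identical(dim(spec_bg), dim(auto_bg)))
  a <- auto_bg$data; s_ch <- spec_bg$data
  if (is.numeric(config$autofluor_scale)) {
    s <- config$autofluor_scale
  } else if (all(a == 0)) {
    warning("autofluorescence channel is all zero; using scale 1")
    s <- 1
  } else {
    q <- quantile(a, 0.99)
    sel <- a > q
    if (!any(sel)) sel <- a == max(a)
    s <- median(s_ch[sel] / a[sel])
  }
  out <- volume(pmax(s_ch - s * a, 0), spec_bg$spacing_um)
  attr(out, "autofluor_scale") <- s
  out
}

#' Detect local intensity maxima with a moving filter cube
#'
#' A voxel is a seed iff its value is positive, equals the maximum of its
#' cube neighbourhood (truncated at borders), and it is the
#' lexicographically-first (z, y, x) voxel of its plateau-connected
#' component of equal-valued maxima.
#'
#' @param vol a [volume()] (typically the corrected specific channel).
#' @param filter_cube odd (z, y, x) cube extents.
#' @return Integer matrix of seed coordinates (columns z, y, x; 0-based),
#'   sorted lexicographically.
#' @export
detect_maxima <- function(vol, filter_cube = c(3, 5, 5)) {
  vol <- as_volume(vol)
  filter_cube <- as.integer(filter_cube)
  if (any(filter_cube %% 2L == 0L)) stop("filter cube dims must be odd")
  m <- cpp_local_maxima(vol$data, as.integer(dim(vol)), filter_cube)
  colnames(m) <- c("z", "y", "x")
  m
}

#' Seeded watershed segmentation above an intensity cut-off
#'
#' Grows segments from the seeds over the mask `{vol >= cutoff}` by
#' priority flood on the inverted intensity landscape (highest intensities
#' claimed first, 26-connectivity, deterministic FIFO tie-break). Voxels
#' below the cut-off keep label 0; seeds below the cut-off are dropped
#' with a warning.
#'
#' @param vol a [volume()].
#' @param seeds integer matrix (z, y, x), 0-based, e.g. [detect_maxima()].
#' @param intensity_cutoff background cut-off.
#' @return Integer label array; label k belongs to seed row k. Dropped
#'   seed rows are recorded in attribute `"dropped_seeds"`.
#' @export
watershed_segment <- function(vol, seeds, intensity_cutoff = 800) {
  vol <- as_volume(vol)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (nrow(seeds) &&
      (any(seeds < 0) || any(seeds >= matrix(dim(vol), nrow(seeds), 3, byrow = TRUE))))
    stop("seeds must lie within the volume")
  vals <- vol$data[seeds + 1L]
  dropped <- which(vals < intensity_cutoff)
  if (length(dropped))
    warning(length(dropped), " seed(s) below the intensity cut-off dropped")
  lab <- cpp_watershed(vol$data, as.integer(dim(vol)), seeds,
                       intensity_cutoff)
  lab <- array(lab, dim(vol))
  attr(lab, "dropped_seeds") <- dropped
  lab
}

#' Filter watershed segments by size
#'
#' Keeps exactly the segments whose voxel count lies in
#' `[min_size, max_size]` (inclusive); others are erased to 0.
#'
#' @param segments integer label array from [watershed_segment()].
#' @param min_size,max_size inclusive bounds in voxels.
#' @return Label array with only surviving segments; surviving label ids
#'   and sizes in attributes `"kept_labels"` and `"sizes"`.
#' @export
filter_by_size <- function(segments, min_size = 8, max_size = 194) {
  labs <- as.vector(segments)
  if (!any(labs > 0L)) {
    out <- segments
    attr(out, "kept_labels") <- integer(0)
    attr(out, "sizes") <- integer(0)
    return(out)
  }
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_size & sizes <= max_size)
  out <- array(ifelse(segments %in% keep, segments, 0L), dim(segments))
  storage.mode(out) <- "integer"
  attr(out, "kept_labels") <- keep
  attr(out, "sizes") <- sizes
  out
}

#' Full dual-channel cell detection
#'
#' Runs the complete adapted detection chain on one subject's channel
#' pair: per-slice channel alignment, per-slice top-hat background
#' subtraction of both channels, autofluorescence false-positive removal,
#' cube-filter maxima seeding, seeded watershed with the intensity
#' cut-off, and size filtering. One cell record is produced per surviving
#' segment, with the seed (peak) coordinate as the cell centre.
#'
#' @param auto,spec the autofluorescence and specific channel [volume()]s.
#' @param config a [detect_config()].
#' @return A [cell_set()] (region ids all 0 until [assign_cells()]); the
#'   corrected specific volume is attached as attribute `"corrected"`.
#' @export
detect_cells <- function(auto, spec, config = detect_config()) {
  auto <- as_volume(auto); spec <- as_volume(spec)
  if (!identical(dim(auto), dim(spec))) stop("shape mismatch between channels")
  spec_al <- if (config$align) align_channels(auto, spec) else spec
  spec_bg <- subtract_background(spec_al, config$opening_disk_radius_vox)
  auto_bg <- subtract_background(auto, config$opening_disk_radius_vox)
  corrected <- if (config$autofluor_removal) {
    remove_autofluorescence(spec_bg, auto_bg, config)
  } else spec_bg
  seeds <- detect_maxima(corrected, config$filter_cube)
  segs <- suppressWarnings(
    watershed_segment(corrected, seeds, config$intensity_cutoff))
  filt <- filter_by_size(segs, config$min_size_vox, config$max_size_vox)
  keep <- attr(filt, "kept_labels")
  sizes <- attr(filt, "sizes")
  if (length(keep)) {
    sk <- seeds[keep, , drop = FALSE]
    cells <- cell_set(data.frame(z = sk[, 1], y = sk[, 2], x = sk[, 3],
                                 size = sizes[keep],
                                 intensity = corrected$data[sk + 1L],
                                 region_id = 0L))
  } else {
    cells <- cell_set(data.frame(z = numeric(0), y = numeric(0),
                                 x = numeric(0), size = integer(0),
                                 intensity = numeric(0),
                                 region_id = integer(0)))
  }
  attr(cells, "corrected") <- corrected
  cells
}

#' Assign detected cells to atlas regions and count per region
#'
#' Each cell's seed coordinate (subject space) is looked up in the region
#' label map: either directly, when `atlas_labels` is already in subject
#' space, or after mapping the coordinate through `transform_to_subject`
#' (the pull-back transform whose fixed grid is the subject volume, i.e.
#' the one that resamples the atlas into subject space). Cells falling on
#' label 0 are counted in an explicit unassigned row, never dropped:
#' region counts plus unassigned always sum to the number of cells.
#'
#' @param cells a [cell_set()] in subject voxel coordinates.
#' @param atlas_labels a [label_volume()].
#' @param transform_to_subject optional `fos_transform` (subject -> atlas
#'   coordinates, resampling convention); `NULL` means `atlas_labels` is
#'   already on the subject grid.
#' @return List with `cells` (region ids filled in) and `counts`
#'   (data.frame `region_id`, `count`; region 0 = unassigned).
#' @export
assign_cells <- function(cells, atlas_labels, transform_to_subject = NULL) {
  stopifnot(inherits(atlas_labels, "fos_labels"))
  pts <- as.matrix(as.data.frame(cells)[c("z", "y", "x")])
  if (nrow(pts)) {
    if (!is.null(transform_to_subject))
      pts <- transform_points(transform_to_subject, pts)
    d <- dim(atlas_labels)
    idx <- round(pts)
    inb <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
      idx[, 3] >= 0 & idx[, 3] < d[3]
    rid <- integer(nrow(pts))
    rid[inb] <- atlas_labels$labels[idx[inb, , drop = FALSE] + 1L]
    cells$region_id <- as.integer(rid)
  }
  tab <- table(factor(cells$region_id))
  counts <- data.frame(region_id = as.integer(names(tab)),
                       count = as.integer(tab))
  counts <- counts[order(counts$region_id), , drop = FALSE]
  rownames(counts) <- NULL
  list(cells = cells, counts = counts)
}
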