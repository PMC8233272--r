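# Multi-regional atlas annotation transfer: whole-brain registration,
# per-parental-block refinement, and label recombination.

#' Parental partition of an ontology
#'
#' Groups region ids into named parental blocks for multi-regional
#' registration. The canonical brain partition has six blocks: cerebral
#' cortex, cerebral nuclei, hindbrain, cerebellum, septal regions, and
#' interbrain together with midbrain. Blocks must be disjoint; together
#' they must cover every label that is to be transferred.
#'
#' @param blocks named list; each element an integer vector of region ids.
#' @return A `fos_partition` object.
#' @export
parental_partition <- function(blocks) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be named")
  ids <- unlist(blocks)
  if (anyDuplicated(ids)) stop("partition blocks must be disjoint")
  structure(lapply(blocks, as.integer), class = "fos_partition")
}

#' @rdname parental_partition
#' @param ont an [ontology()].
#' @param block_ids region ids of the parental block nodes; each block is
#'   that node plus all of its descendants.
#' @export
partition_from_ontology <- function(ont, block_ids) {
  blocks <- lapply(block_ids, function(id) c(id, descendant_ids(ont, id)))
  names(blocks) <- ont$name[match(block_ids, ont$region_id)]
  parental_partition(blocks)
}

dilate_mask <- function(mask, r) {
  d <- dim(mask)
  sm <- cpp_gauss3(array(as.numeric(mask), d), as.integer(d), rep(r / 2, 3))
  # any voxel within ~r voxels of the mask gets substantial smoothed mass
  array(sm > exp(-2) * max(sm) * 0.05, d) | mask
}

#' Resolve label claims from several blocks into one label map
#'
#' Voxels claimed by exactly one block keep that label. Voxels claimed by
#' several blocks, or claimed by none while inside the tissue mask, take
#' the label of the nearest single-claim voxel (Euclidean distance in
#' voxels; ties broken by the smaller region id).
#'
#' @param block_label_volumes list of integer label arrays or
#'   [label_volume()]s on a common grid (0 = no claim).
#' @param tissue_mask logical array, same grid; voxels outside stay 0.
#' @param spacing_um voxel spacing of the result.
#' @param ontology optional [ontology()] for the result.
#' @return A [label_volume()] with every in-mask voxel labelled.
#' @export
resolve_overlaps <- function(block_label_volumes, tissue_mask,
                             spacing_um = 20, ontology = NULL) {
  if (!length(block_label_volumes)) stop("no block label volumes")
  arrs <- lapply(block_label_volumes, function(b)
    if (inherits(b, "fos_labels")) b$labels else b)
  d <- dim(arrs[[1]])
  claims <- array(0L, d)
  winner <- array(0L, d)
  for (b in arrs) {
    nz <- b != 0L
    claims <- claims + as.integer(nz)
    winner[nz] <- b[nz]
  }
  if (all(claims == 0L)) stop("all blocks empty")
  single <- array(0L, d)
  one <- claims == 1L
  single[one] <- winner[one]
  if (!any(single > 0L)) stop("no single-claim voxels to resolve against")
  unresolved <- which((claims > 1L) | (claims == 0L & tissue_mask))
  out <- single
  if (length(unresolved))
    out[unresolved] <- cpp_nearest_label(single, as.integer(d),
                                         as.integer(unresolved - 1L))
  label_volume(out, spacing_um, ontology = ontology,
               tissue_mask = tissue_mask)
}

#' Transfer atlas annotations onto a target template
#'
#' Three steps: (1) whole-brain registration of the source template to the
#' target; (2) for each parental block, both templates are masked to the
#' (dilated) block support and the masked pair is registered again,
#' refining the whole-brain alignment within the block; (3) each block's
#' labels are warped with its block transform (nearest-neighbour) and the
#' blocks are recombined with [resolve_overlaps()], so every in-mask
#' target voxel receives exactly one label.
#'
#' All transforms follow the pull-back convention (target coordinates to
#' source coordinates), so labels are resampled directly onto the target
#' grid.
#'
#' @param source_template,target_template [volume()]s on a common spacing.
#' @param source_labels [label_volume()] on the source template grid.
#' @param partition a [parental_partition()]; `NULL` transfers all labels
#'   in a single whole-brain block.
#' @param tissue_mask logical array on the target grid; defaults to the
#'   positive support of the target template.
#' @param dilate_vox dilation radius of block masks in voxels, so block
#'   registrations keep boundary context.
#' @param register_args extra arguments passed to [register()].
#' @return A [label_volume()] on the target grid.
#' @export
transfer_annotations <- function(source_template, source_labels,
                                 target_template, partition = NULL,
                                 tissue_mask = NULL, dilate_vox = 5,
                                 register_args = list()) {
  source_template <- as_volume(source_template)
  target_template <- as_volume(target_template)
  stopifnot(inherits(source_labels, "fos_labels"))
  d <- dim(target_template)
  if (is.null(tissue_mask)) tissue_mask <- target_template$data > 0
  present <- setdiff(unique(as.vector(source_labels$labels)), 0L)
  if (is.null(partition))
    partition <- parental_partition(list(whole_brain = present))
  covered <- unlist(partition)
  if (length(setdiff(present, covered)))
    stop("partition does not cover source labels: ",
         paste(setdiff(present, covered), collapse = ", "))
  whole <- do.call(register, c(list(moving = source_template,
                                    fixed = target_template,
                                    model = "bspline"), register_args))
  warped_src <- apply_transform(source_template, whole$transform, "linear",
                                out_dim = d)
  warped_lab <- apply_transform(source_labels, whole$transform, "nearest",
                                out_dim = d)
  block_maps <- vector("list", length(partition))
  for (k in seq_along(partition)) {
    ids <- partition[[k]]
    src_block <- array(source_labels$labels %in% ids, dim(source_labels$labels))
    if (!any(src_block)) stop("empty block after masking: ", names(partition)[k])
    tgt_block <- array(warped_lab$labels %in% ids, d)
    if (!any(tgt_block)) tgt_block <- tissue_mask
    msrc <- dilate_mask(src_block, dilate_vox)
    mtgt <- dilate_mask(tgt_block, dilate_vox)
    mov <- volume(warped_src$data * mtgt, warped_src$spacing_um)
    fix <- volume(target_template$data * mtgt, target_template$spacing_um)
    refine <- do.call(register, c(list(moving = mov, fixed = fix,
                                       model = "bspline"), register_args))
    total <- compose_transforms(whole$transform, refine$transform)
    lab_k <- source_labels$labels
    lab_k[!(lab_k %in% ids)] <- 0L
    lv <- label_volume(lab_k, source_labels$spacing_um)
    block_maps[[k]] <- apply_transform(lv, total, "nearest", out_dim = d)$labels
    block_maps[[k]][!mtgt] <- 0L
    rm(msrc)
  }
  resolve_overlaps(block_maps, tissue_mask,
                   spacing_um = target_template$spacing_um,
                   ontology = source_labels$ontology)
}
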