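#' Hierarchical region ontology
#'
#' The region table of an annotated atlas: one row per brain region with a
#' unique positive integer `region_id`, an acronym, a full name and a
#' `parent_id` linking it into a rooted forest (roots have `parent_id = NA`).
#' Leaves (nodes with no children) are the finest segmentation level and are
#' recomputed on construction.
#'
#' @param df data.frame with columns `region_id`, `acronym`, `name`,
#'   `parent_id`.
#' @return A validated `fos_ontology` data.frame with an `is_leaf` column.
#' @export
ontology <- function(df) {
  req <- c("region_id", "acronym", "name", "parent_id")
  if (!all(req %in% names(df)))
    stop("ontology needs columns: ", paste(req, collapse = ", "))
  df <- df[req]
  df$region_id <- as.integer(df$region_id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  if (anyNA(df$region_id) || any(df$region_id <= 0L))
    stop("region_ids must be positive integers")
  if (anyDuplicated(df$region_id))
    stop("duplicate region_ids: ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  nonroot <- !is.na(df$parent_id)
  dangling <- setdiff(df$parent_id[nonroot], df$region_id)
  if (length(dangling))
    stop("dangling parent_id: ", paste(dangling, collapse = ", "))
  # cycle check: follow parent links; a walk longer than the table => cycle
  pid <- df$parent_id[match(df$region_id, df$region_id)]
  names(pid) <- as.character(df$region_id)
  for (r in df$region_id) {
    cur <- r; steps <- 0L
    while (!is.na(pid[[as.character(cur)]])) {
      cur <- pid[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > nrow(df)) stop("cyclic parent links involving region ", r)
    }
  }
  df$is_leaf <- !(df$region_id %in% df$parent_id[nonroot])
  class(df) <- c("fos_ontology", "data.frame")
  df
}

#' @export
print.fos_ontology <- function(x, ...) {
  cat(sprintf("<fos_ontology> %d regions, %d leaves, %d root(s)\n",
              nrow(x), sum(x$is_leaf), sum(is.na(x$parent_id))))
  invisible(x)
}

#' Number of leaf regions in an ontology
#' @param ont an [ontology()].
#' @return Integer count of nodes with no children.
#' @export
n_leaf_regions <- function(ont) sum(ont$is_leaf)

#' Read a region ontology from CSV or JSON
#'
#' CSV input needs columns `region_id` (or `id`), `acronym`, `name` and
#' `parent_id` (or `parent`; empty/NA for roots). JSON input is a nested
#' tree (or list of trees) with fields `id`, `acronym`, `name` and a
#' `children` array, as used by common atlas ontology distributions.
#'
#' @param path file path.
#' @return A validated [ontology()].
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tree <- jsonlite::read_json(path)
    rows <- list()
    walk <- function(node, parent_id) {
      rows[[length(rows) + 1L]] <<- data.frame(
        region_id = as.integer(node$id),
        acronym = as.character(node$acronym %||% node$id),
        name = as.character(node$name %||% node$acronym %||% node$id),
        parent_id = if (is.null(parent_id)) NA_integer_ else as.integer(parent_id),
        stringsAsFactors = FALSE)
      for (ch in node$children %||% list()) walk(ch, node$id)
    }
    if (!is.null(tree$id)) walk(tree, NULL) else for (t in tree) walk(t, NULL)
    return(ontology(do.call(rbind, rows)))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !"region_id" %in% names(df))
    names(df)[names(df) == "id"] <- "region_id"
  if ("parent" %in% names(df) && !"parent_id" %in% names(df))
    names(df)[names(df) == "parent"] <- "parent_id"
  ontology(df)
}

#' @rdname read_ontology
#' @param ont an [ontology()] to write.
#' @export
write_ontology <- function(ont, path) {
  write.csv(as.data.frame(ont)[c("region_id", "acronym", "name", "parent_id")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All descendant region ids of a node (excluding the node itself)
#' @param ont an [ontology()].
#' @param id region id.
#' @return Integer vector of descendant ids.
#' @export
descendant_ids <- function(ont, id) {
  out <- integer()
  frontier <- id
  while (length(frontier)) {
    kids <- ont$region_id[!is.na(ont$parent_id) & ont$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

ancestor_chain <- function(ont, id) {
  chain <- integer()
  cur <- id
  repeat {
    p <- ont$parent_id[match(cur, ont$region_id)]
    if (is.na(p)) break
    chain <- c(chain, p)
    cur <- p
  }
  chain
}

#' Collapse leaf-level counts or labels to ancestor regions
#'
#' Re-maps leaf regions to designated ancestor ("parental") regions using a
#' level map, the hierarchical collapse used before per-region statistics.
#' For count tables the per-leaf counts are summed within each ancestor
#' (total count conserved exactly); for label volumes voxels are relabelled.
#'
#' @param x a count data.frame with a `region_id` column (any other columns
#'   are treated as grouping keys, `count` is summed), or a [label_volume()].
#' @param ont the [ontology()] the ids refer to.
#' @param level_map named integer vector: `level_map[[as.character(leaf_id)]]`
#'   is the ancestor id the leaf collapses to. Every id present in `x` must
#'   be mapped; mapped targets must be the id itself or one of its ancestors.
#' @return Same kind as `x`, with `region_id`s replaced by ancestor ids.
#' @export
collapse_to_parents <- function(x, ont, level_map) {
  ids_used <- if (inherits(x, "fos_labels")) {
    setdiff(unique(as.vector(x$labels)), 0L)
  } else unique(x$region_id)
  key <- as.character(ids_used)
  unmapped <- ids_used[!key %in% names(level_map)]
  if (length(unmapped))
    stop("leaf regions with no mapped ancestor: ",
         paste(unmapped, collapse = ", "))
  for (id in ids_used) {
    tgt <- level_map[[as.character(id)]]
    if (tgt != id && !(tgt %in% ancestor_chain(ont, id)))
      stop("level_map target ", tgt, " is not an ancestor of region ", id)
  }
  if (inherits(x, "fos_labels")) {
    lut <- x$labels
    map_from <- c(0L, ids_used)
    map_to <- c(0L, as.integer(level_map[key]))
    new_labels <- array(map_to[match(as.vector(lut), map_from)], dim(lut))
    return(label_volume(new_labels, x$spacing_um, ontology = x$ontology,
                        tissue_mask = x$tissue_mask,
                        ventricular_mask = x$ventricular_mask))
  }
  x$region_id <- as.integer(level_map[as.character(x$region_id)])
  keys <- setdiff(names(x), "count")
  if ("count" %in% names(x)) {
    agg <- aggregate(x["count"], x[keys], FUN = sum)
    agg <- agg[do.call(order, agg[keys]), , drop = FALSE]
    rownames(agg) <- NULL
    return(agg[c(keys, "count")])
  }
  x
}

#' Synthetic stand-in atlas ontology
#'
#' Builds a synthetic region hierarchy with the documented shape of the
#' LSFM atlas ontology: 666 leaf segmentations organised under six parental
#' blocks (cerebral cortex, cerebral nuclei, hindbrain, cerebellum, septal
#' regions, interbrain + midbrain), collapsing to 284 analysis regions under
#' the returned level map. This is a synthetic stand-in for the real atlas
#' hierarchy file (which ships with the atlas, not with this package); names
#' and acronyms are generated, only the tree shape is meaningful.
#'
#' @param n_leaves number of leaf regions (default 666).
#' @param n_analysis number of analysis regions after collapse (default 284).
#' @return List with elements `ontology` (an [ontology()]) and `level_map`
#'   (named integer vector mapping each leaf id to its analysis region id).
#' @export
synthetic_atlas_ontology <- function(n_leaves = 666, n_analysis = 284) {
  stopifnot(n_leaves >= n_analysis, n_analysis >= 6)
  blocks <- c("cerebral cortex", "cerebral nuclei", "hindbrain",
              "cerebellum", "septal regions", "interbrain and midbrain")
  root_id <- 1L
  block_ids <- 1L + seq_along(blocks)
  analysis_ids <- max(block_ids) + seq_len(n_analysis)
  leaf_ids <- max(analysis_ids) + seq_len(n_leaves)
  # distribute analysis regions over blocks, leaves over analysis regions
  block_of <- rep(block_ids, length.out = n_analysis)
  kids <- rep(n_leaves %/% n_analysis, n_analysis)
  extra <- n_leaves - sum(kids)
  if (extra > 0) kids[seq_len(extra)] <- kids[seq_len(extra)] + 1L
  leaf_parent <- rep(analysis_ids, times = kids)
  df <- rbind(
    data.frame(region_id = root_id, acronym = "root", name = "synthetic root",
               parent_id = NA_integer_),
    data.frame(region_id = block_ids,
               acronym = paste0("BLK", seq_along(blocks)),
               name = blocks, parent_id = root_id),
    data.frame(region_id = analysis_ids,
               acronym = sprintf("AR%03d", seq_len(n_analysis)),
               name = sprintf("synthetic analysis region %d", seq_len(n_analysis)),
               parent_id = block_of),
    data.frame(region_id = leaf_ids,
               acronym = sprintf("LF%03d", seq_len(n_leaves)),
               name = sprintf("synthetic leaf region %d", seq_len(n_leaves)),
               parent_id = leaf_parent))
  lm <- setNames(as.integer(leaf_parent), as.character(leaf_ids))
  list(ontology = ontology(df), level_map = lm)
}
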