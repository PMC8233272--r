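#' Landmark coordinate sets
#'
#' Named anatomical landmark positions in voxel coordinates (z, y, x;
#' possibly fractional, 0-based) of an associated volume. Used for
#' registration-quality evaluation against atlas landmarks.
#'
#' @param df data.frame with columns `name`, `z`, `y`, `x`.
#' @return A validated `fos_landmarks` data.frame.
#' @export
landmark_set <- function(df) {
  req <- c("name", "z", "y", "x")
  if (!all(req %in% names(df)))
    stop("landmark table needs columns: ", paste(req, collapse = ", "))
  df <- df[req]
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name))
    stop("duplicate landmark names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (col in c("z", "y", "x")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric coordinate in row ", bad[1], " column ", col)
    df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("fos_landmarks", "data.frame")
  df
}

#' Read / write landmark tables (CSV, header `name,z,y,x`)
#' @param path CSV file path.
#' @return A [landmark_set()]; empty file with header only gives an empty set.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  landmark_set(df)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  write.csv(as.data.frame(lm), path, row.names = FALSE)
  invisible(path)
}

#' Detected-cell tables
#'
#' One row per detected cell: seed (peak) voxel coordinate, watershed
#' segment size in voxels, peak intensity, and assigned region id
#' (0 = unassigned).
#'
#' @param df data.frame with columns `z`, `y`, `x`, `size`, `intensity`,
#'   `region_id`.
#' @return A validated `fos_cells` data.frame.
#' @export
cell_set <- function(df) {
  req <- c("z", "y", "x", "size", "intensity", "region_id")
  for (col in setdiff(req, names(df))) df[[col]] <- numeric(nrow(df))
  df <- df[req]
  for (col in req) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) stop("non-numeric value in row ", bad[1], " column ", col)
    df[[col]] <- as.numeric(df[[col]])
  }
  df$size <- as.integer(df$size)
  df$region_id <- as.integer(df$region_id)
  class(df) <- c("fos_cells", "data.frame")
  df
}

#' Read / write detected-cell tables (CSV)
#' @param path CSV file path with header `z,y,x,size,intensity,region_id`.
#' @return A [cell_set()].
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cell_set(df)
}

#' @rdname read_cell_table
#' @param cells a [cell_set()].
#' @export
write_cell_table <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-region per-animal count tables and design tables
#'
#' Count tables have one row per animal and region
#' (`animal_id, group, region_id, count`); design tables map animals to
#' groups (`animal_id, group`).
#'
#' @param path CSV file path.
#' @return data.frame with validated column types.
#' @export
read_count_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "region_id", "count")
  if (!all(req %in% names(df)))
    stop("count table needs columns: ", paste(req, collapse = ", "))
  df$region_id <- as.integer(df$region_id)
  df$count <- as.integer(df$count)
  if (anyNA(df$count) || any(df$count < 0))
    stop("counts must be non-negative integers")
  if (anyDuplicated(df[c("animal_id", "region_id")]))
    stop("count table must have one row per animal x region")
  df[req]
}

#' @rdname read_count_table
#' @param counts a count data.frame.
#' @export
write_count_table <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_count_table
#' @export
read_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("animal_id", "group") %in% names(df)))
    stop("design table needs columns: animal_id, group")
  if (anyDuplicated(df$animal_id)) stop("duplicate animal_id in design")
  df[c("animal_id", "group")]
}
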