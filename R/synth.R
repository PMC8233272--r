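# Phantom generators: every downstream stage of the pipeline is testable
# against these, with exact ground truth. All generators are pure functions
# of (parameters, seed); the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth of a synthetic phantom
#'
#' Records the known truth implanted in a phantom: cell centres with their
#' region ids, shared-artifact centres, the applied displacement field (if
#' any) and the generator seed.
#' @keywords internal
phantom_truth <- function(cell_centers = NULL, cell_region_ids = NULL,
                          artifact_centers = NULL, applied_field = NULL,
                          rng_seed = NA_integer_) {
  if (!is.null(cell_centers) &&
      nrow(cell_centers) != length(cell_region_ids %||% integer()))
    stop("cell centre and region-id lists must be aligned")
  structure(list(cell_centers = cell_centers,
                 cell_region_ids = cell_region_ids,
                 artifact_centers = artifact_centers,
                 applied_field = applied_field, rng_seed = rng_seed),
            class = "fos_truth")
}

voxel_grid <- function(shape) {
  list(z = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), shape),
       x = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape))
}

#' Generate a smooth ellipsoidal phantom brain
#'
#' Builds an ellipsoidal tissue mask partitioned into `n_regions` adjacent
#' labelled subregions (Voronoi cells of random interior sites, each
#' guaranteed at least 100 voxels), an autofluorescence-like volume (smooth
#' base intensity, mild per-region offsets, smooth low-frequency variation
#' and Gaussian noise) and a minimal ontology (one root plus one node per
#' region). Deterministic given `(shape, n_regions, seed)`.
#'
#' @param shape integer vector (nz, ny, nx), each at least 32.
#' @param n_regions number of labelled subregions (>= 2).
#' @param seed integer RNG seed.
#' @param spacing_um nominal voxel spacing (default 20).
#' @return List with `auto` ([volume()]), `labels` ([label_volume()]) and
#'   `ontology` ([ontology()]).
#' @export
make_phantom <- function(shape = c(96, 128, 128), n_regions = 6, seed = 1,
                         spacing_um = 20) {
  if (length(shape) != 3L || any(shape < 32))
    stop("shape must be (nz, ny, nx) with every dimension >= 32")
  if (n_regions < 2) stop("n_regions must be >= 2")
  with_seed(seed + 1000L, {
    g <- voxel_grid(shape)
    ctr <- (shape - 1) / 2
    semi <- 0.42 * shape
    r2 <- ((g$z - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
      ((g$x - ctr[3]) / semi[3])^2
    mask <- r2 <= 1
    inside <- which(mask)
    if (length(inside) < 100 * n_regions)
      stop("shape too small to host ", n_regions, " regions of >= 100 voxels")
    labels <- array(0L, shape)
    for (attempt in 1:25) {
      sites <- inside[sample.int(length(inside), n_regions)]
      sz <- arrayInd(sites, shape) - 1
      d2 <- matrix(0, length(inside), n_regions)
      ii <- arrayInd(inside, shape) - 1
      for (k in seq_len(n_regions))
        d2[, k] <- (ii[, 1] - sz[k, 1])^2 + (ii[, 2] - sz[k, 2])^2 +
          (ii[, 3] - sz[k, 3])^2
      lab <- max.col(-d2, ties.method = "first")
      if (min(tabulate(lab, n_regions)) >= 100) {
        labels[inside] <- lab + 1L  # region ids 2..n+1; root is 1
        break
      }
      if (attempt == 25) stop("could not place ", n_regions,
                              " regions of >= 100 voxels")
    }
    ont <- ontology(data.frame(
      region_id = c(1L, 1L + seq_len(n_regions)),
      acronym = c("root", sprintf("R%d", seq_len(n_regions))),
      name = c("phantom root", sprintf("phantom region %d", seq_len(n_regions))),
      parent_id = c(NA_integer_, rep(1L, n_regions))))
    base <- 1200
    offsets <- base * 0.1 * sin(seq_len(n_regions))  # fixed mild per-region offsets
    lowfreq <- cpp_gauss3(array(rnorm(prod(shape), 0, 1), shape),
                          as.integer(shape), rep(8, 3))
    lowfreq <- lowfreq / max(abs(lowfreq)) * 100
    auto <- array(0, shape)
    auto[mask] <- base + offsets[labels[mask] - 1L] + lowfreq[mask]
    auto <- auto + rnorm(prod(shape), 0, 10) * as.numeric(mask)
    auto <- pmax(auto, 0)
    list(auto = volume(array(auto, shape), spacing_um),
         labels = label_volume(labels, spacing_um, ontology = ont,
                               tissue_mask = mask),
         ontology = ont)
  })
}

gaussian_blob <- function(arr, center, peak, sigma) {
  shape <- dim(arr)
  r <- ceiling(3 * sigma)
  zr <- max(0, center[1] - r):min(shape[1] - 1, center[1] + r)
  yr <- max(0, center[2] - r):min(shape[2] - 1, center[2] + r)
  xr <- max(0, center[3] - r):min(shape[3] - 1, center[3] + r)
  dz <- (zr - center[1])^2
  dy <- (yr - center[2])^2
  dx <- (xr - center[3])^2
  blob <- peak * exp(-(outer(outer(dz, dy, "+"), dx, "+")) / (2 * sigma^2))
  arr[zr + 1, yr + 1, xr + 1] <- arr[zr + 1, yr + 1, xr + 1] + blob
  arr
}

#' Implant point-like cells into a phantom
#'
#' Produces the marker-specific channel: a dim tissue background plus
#' isotropic Gaussian-profile cells (peak `peak_intensity`, sd
#' `radius_vox`) at rejection-sampled integer centres that lie inside their
#' requested region and are pairwise at least `min_sep` voxels apart.
#'
#' @param labels a [label_volume()] from [make_phantom()].
#' @param per_region_counts named vector: requested cells per region id.
#' @param peak_intensity peak added intensity of one cell (default 3000).
#' @param radius_vox Gaussian sd of the cell profile in voxels.
#' @param min_sep minimal pairwise centre distance in voxels.
#' @param seed integer RNG seed.
#' @param background tissue background level of the specific channel.
#' @param noise_sd Gaussian noise sd.
#' @return List with `spec` ([volume()]) and `truth` (phantom truth with
#'   `cell_centers` (n x 3, 0-based z,y,x) and `cell_region_ids`).
#' @export
implant_cells <- function(labels, per_region_counts, peak_intensity = 3000,
                          radius_vox = 1.5, min_sep = 6, seed = 1,
                          background = 200, noise_sd = 10) {
  stopifnot(inherits(labels, "fos_labels"))
  shape <- dim(labels)
  with_seed(seed + 2000L, {
    lab <- labels$labels
    # background drawn before centre sampling, so the background is the
    # same function of (labels, seed) whatever cells are requested
    spec <- array(background * as.numeric(lab > 0), shape) +
      rnorm(prod(shape), 0, noise_sd) * as.numeric(lab > 0)
    spec <- pmax(spec, 0)
    centers <- matrix(0, 0, 3)
    region_ids <- integer()
    for (rid in names(per_region_counts)) {
      want <- per_region_counts[[rid]]
      if (want == 0) next
      cand <- which(lab == as.integer(rid))
      if (!length(cand)) stop("region ", rid, " has no voxels")
      placed <- 0L
      tries <- 0L
      while (placed < want) {
        tries <- tries + 1L
        if (tries > 2000L * want)
          stop("infeasible packing: could not place ", want,
               " cells in region ", rid, " with min_sep ", min_sep)
        p <- arrayInd(cand[sample.int(length(cand), 1L)], shape) - 1
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, as.numeric(p))^2))) >= min_sep) {
          centers <- rbind(centers, as.numeric(p))
          region_ids <- c(region_ids, as.integer(rid))
          placed <- placed + 1L
        }
      }
    }
    if (nrow(centers) && peak_intensity > 0)
      for (i in seq_len(nrow(centers)))
        spec <- gaussian_blob(spec, centers[i, ], peak_intensity, radius_vox)
    list(spec = volume(array(spec, shape), labels$spacing_um),
         truth = phantom_truth(cell_centers = centers,
                               cell_region_ids = region_ids,
                               rng_seed = seed))
  })
}

#' Add bright artifacts shared by both channels
#'
#' Emulates increased tissue autofluorescence: `n` Gaussian blobs added at
#' identical coordinates in both the autofluorescence and the specific
#' channel, so downstream autofluorescence-based false-positive removal can
#' be exercised against known artifact locations.
#'
#' @param auto,spec the two channel [volume()]s (same shape).
#' @param n number of artifacts (>= 0).
#' @param intensity peak added intensity.
#' @param seed integer RNG seed.
#' @param sigma_vox Gaussian sd of the artifact profile.
#' @param min_sep minimal pairwise artifact distance in voxels.
#' @return List with `auto`, `spec` (both [volume()]) and `truth`
#'   (artifact centres, n x 3).
#' @export
add_shared_artifacts <- function(auto, spec, n, intensity = 2500, seed = 1,
                                 sigma_vox = 2, min_sep = 10) {
  stopifnot(identical(dim(auto), dim(spec)))
  if (n == 0)
    return(list(auto = auto, spec = spec,
                truth = phantom_truth(artifact_centers = matrix(0, 0, 3),
                                      rng_seed = seed)))
  shape <- dim(auto)
  with_seed(seed + 3000L, {
    a <- vol_data(auto); s <- vol_data(spec)
    tissue <- which(a > 0.5 * max(a))
    if (!length(tissue)) stop("no tissue support to place artifacts in")
    centers <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 2000L * n) stop("infeasible artifact placement")
      p <- arrayInd(tissue[sample.int(length(tissue), 1L)], shape) - 1
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, as.numeric(p))^2))) >= min_sep)
        centers <- rbind(centers, as.numeric(p))
    }
    for (i in seq_len(n)) {
      a <- gaussian_blob(a, centers[i, ], intensity, sigma_vox)
      s <- gaussian_blob(s, centers[i, ], intensity, sigma_vox)
    }
    list(auto = volume(a, auto$spacing_um), spec = volume(s, spec$spacing_um),
         truth = phantom_truth(artifact_centers = centers, rng_seed = seed))
  })
}

#' Warp a volume with a smooth random displacement field
#'
#' Draws three white-noise component fields, smooths them with a Gaussian of
#' sd `smoothness` voxels, scales the field so its maximum Euclidean
#' magnitude equals `amplitude_vox`, and applies it to `vol` by trilinear
#' pull-back interpolation (`out(x) = vol(x + u(x))`). The exact field is
#' returned so registration recovery can be scored against truth.
#'
#' @param vol a [volume()].
#' @param amplitude_vox maximum displacement magnitude in voxels (>= 0).
#' @param smoothness Gaussian sd of field smoothing, voxels.
#' @param seed integer RNG seed.
#' @return List with `warped` ([volume()]) and `field` (array
#'   `(nz, ny, nx, 3)`, voxel units, components ordered z, y, x).
#' @export
warp_phantom <- function(vol, amplitude_vox, smoothness = 8, seed = 1) {
  vol <- as_volume(vol)
  if (amplitude_vox < 0) stop("amplitude_vox must be >= 0")
  shape <- dim(vol)
  if (amplitude_vox == 0) {
    u <- array(0, c(shape, 3))
    return(list(warped = vol, field = u))
  }
  with_seed(seed + 4000L, {
    u <- array(0, c(shape, 3))
    for (c in 1:3)
      u[, , , c] <- cpp_gauss3(array(rnorm(prod(shape)), shape),
                               as.integer(shape), rep(smoothness, 3))
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    u <- u * (amplitude_vox / max(mag))
    warped <- cpp_sample_field(vol$data, as.integer(shape),
                               as.numeric(u), 0L)
    list(warped = volume(pmax(array(warped, shape), 0), vol$spacing_um),
         field = u)
  })
}

#' Simulate negative-binomial per-region cell counts
#'
#' For every region and animal, draws a count from a negative binomial with
#' mean `mu = baseline_mean * 2^log2fc(group)` and variance
#' `mu + mu^2 / dispersion` (mean/dispersion parameterisation, matching the
#' statistics module's estimator).
#'
#' @param region_ids integer vector of regions to simulate.
#' @param design data.frame with columns `animal_id`, `group`.
#' @param baseline_mean expected control count (> 0).
#' @param log2fc_map named numeric vector of log2 fold changes per group;
#'   groups not named get 0.
#' @param dispersion NB dispersion theta (> 0); larger is closer to Poisson.
#' @param seed integer RNG seed.
#' @return Count data.frame (`animal_id, group, region_id, count`).
#' @export
simulate_counts <- function(region_ids, design, baseline_mean, log2fc_map = NULL,
                            dispersion = 5, seed = 1) {
  stopifnot(baseline_mean > 0, dispersion > 0)
  groups <- unique(design$group)
  if (length(groups) < 2) stop("design must contain >= 2 groups")
  if (any(table(design$group) == 0)) stop("group with 0 animals")
  with_seed(seed + 5000L, {
    df <- expand.grid(animal_id = design$animal_id, region_id = region_ids,
                      stringsAsFactors = FALSE)
    df$group <- design$group[match(df$animal_id, design$animal_id)]
    fc <- rep(0, nrow(df))
    if (!is.null(log2fc_map)) {
      hit <- df$group %in% names(log2fc_map)
      fc[hit] <- log2fc_map[df$group[hit]]
    }
    mu <- baseline_mean * 2^fc
    df$count <- rnbinom(nrow(df), mu = mu, size = dispersion)
    df[c("animal_id", "group", "region_id", "count")]
  })
}
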