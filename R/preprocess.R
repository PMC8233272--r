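# Volume conditioning before registration. Fixed pipeline order:
# downsample -> bias correction -> histogram normalization / CLAHE.

#' Preprocessing configuration
#'
#' @param target_spacing_um isotropic target spacing (default 20).
#' @param bias_correction_on run multiplicative bias-field correction.
#' @param clahe_tile_vox CLAHE tile edge length in voxels (>= 4).
#' @param clahe_clip clip limit as a fraction of tile histogram mass.
#' @param reference_histogram optional reference for histogram matching: a
#'   [volume()] or numeric sample of intensities.
#' @return A `fos_preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_um = 20, bias_correction_on = TRUE,
                              clahe_tile_vox = 8, clahe_clip = 0.01,
                              reference_histogram = NULL) {
  stopifnot(target_spacing_um > 0, clahe_tile_vox >= 4, clahe_clip > 0)
  structure(list(target_spacing_um = target_spacing_um,
                 bias_correction_on = bias_correction_on,
                 clahe_tile_vox = as.integer(clahe_tile_vox),
                 clahe_clip = clahe_clip,
                 reference_histogram = reference_histogram),
            class = "fos_preprocess_config")
}

#' Anti-aliased isotropic down-sampling
#'
#' Resamples to an isotropic grid at `target_spacing_um`. Integer
#' down-sampling factors use exact block averaging (mean-preserving);
#' fractional factors use Gaussian anti-alias smoothing followed by linear
#' resampling at block centres. Up-sampling is refused.
#'
#' @param vol a [volume()].
#' @param target_spacing_um target spacing, must be >= the input spacing.
#' @return A [volume()] at the target spacing.
#' @export
downsample_isotropic <- function(vol, target_spacing_um = 20) {
  vol <- as_volume(vol)
  f <- target_spacing_um / vol$spacing_um
  if (f < 1 - 1e-9) stop("upsampling requested (target spacing ",
                         target_spacing_um, " < ", vol$spacing_um, ")")
  if (abs(f - round(f)) < 1e-9) {
    fi <- as.integer(round(f))
    if (fi == 1L) return(vol)
    d <- dim(vol)
    crop <- (d %/% fi) * fi
    arr <- vol$data[seq_len(crop[1]), seq_len(crop[2]), seq_len(crop[3]), drop = FALSE]
    out <- cpp_block_mean(arr, as.integer(dim(arr)), rep(fi, 3L))
    return(volume(array(out, dim(out)), target_spacing_um))
  }
  d <- dim(vol)
  sm <- cpp_gauss3(vol$data, as.integer(d), rep(0.5 * f, 3))
  odim <- as.integer(floor(d / f))
  A <- diag(3) * f
  t0 <- rep((f - 1) / 2, 3)
  out <- cpp_sample_affine(array(sm, d), as.integer(d), as.numeric(t(A)),
                           t0, odim, 0L)
  volume(pmax(array(out, odim), 0), target_spacing_um)
}

#' Multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity field in the
#' log domain by normalized (mask-weighted) Gaussian convolution over the
#' foreground, divides it out, and rescales so the foreground mean matches
#' the input. This targets the low-frequency shading light-sheet
#' acquisitions pick up; it is a smooth-field estimator, not a histogram
#' sharpening method.
#'
#' @param vol a [volume()] with strictly positive foreground.
#' @param sigma_vox Gaussian sd of the field smoothness, voxels; default a
#'   quarter of the smallest volume edge.
#' @param foreground_quantile voxels above this quantile of positive
#'   intensities define the foreground mask; the default 0 keeps every
#'   positive voxel (zeros mark outside-volume background).
#' @return A [volume()]; the estimated multiplicative field is attached as
#'   attribute `"bias_field"` (1 outside the foreground).
#' @export
correct_bias <- function(vol, sigma_vox = NULL, foreground_quantile = 0) {
  vol <- as_volume(vol)
  v <- vol$data
  if (all(v == 0)) stop("all-zero volume")
  d <- dim(v)
  if (is.null(sigma_vox)) sigma_vox <- max(min(d) / 4, 4)
  mask <- if (foreground_quantile > 0) {
    v >= quantile(v[v > 0], foreground_quantile)
  } else v > 0
  lg <- array(0, d)
  lg[mask] <- log(v[mask])
  m <- array(as.numeric(mask), d)
  num <- cpp_gauss3(lg, as.integer(d), rep(sigma_vox, 3))
  den <- cpp_gauss3(m, as.integer(d), rep(sigma_vox, 3))
  logbias <- array(0, d)
  logbias[mask] <- num[mask] / pmax(den[mask], 1e-9)
  logbias[mask] <- logbias[mask] - mean(logbias[mask])
  bias <- array(1, d)
  bias[mask] <- exp(logbias[mask])
  out <- v
  out[mask] <- v[mask] / bias[mask]
  out[mask] <- out[mask] * (mean(v[mask]) / mean(out[mask]))
  res <- volume(pmax(out, 0), vol$spacing_um)
  attr(res, "bias_field") <- bias
  res
}

#' Match a volume's intensity histogram to a reference
#'
#' Monotone quantile mapping: each intensity is sent to the reference
#' quantile at its own empirical cumulative probability.
#'
#' @param vol a [volume()].
#' @param reference a [volume()] or numeric sample of reference intensities.
#' @param n_quantiles resolution of the mapping.
#' @return A [volume()].
#' @export
match_histogram <- function(vol, reference, n_quantiles = 1024) {
  vol <- as_volume(vol)
  refv <- if (inherits(reference, "fos_volume")) as.vector(reference$data)
          else as.numeric(reference)
  v <- as.vector(vol$data)
  if (length(unique(v)) < 2L || length(unique(refv)) < 2L) return(vol)
  probs <- seq(0, 1, length.out = n_quantiles)
  qin <- quantile(v, probs, names = FALSE)
  qref <- quantile(refv, probs, names = FALSE)
  mapped <- approx(qin, qref, xout = v, ties = "ordered", rule = 2)$y
  volume(array(pmax(mapped, 0), dim(vol$data)), vol$spacing_um)
}

#' Histogram normalization and contrast-limited adaptive equalization
#'
#' Optionally matches the volume's histogram to a reference (the common
#' target used during template building), then applies tile-based CLAHE
#' slice by slice. Output intensities span `[0, 65535]`. A degenerate
#' (single-valued) volume is returned unchanged apart from range mapping.
#'
#' @param vol a [volume()].
#' @param config a [preprocess_config()].
#' @return A [volume()] in the 16-bit range.
#' @export
equalize <- function(vol, config = preprocess_config()) {
  vol <- as_volume(vol)
  if (!is.null(config$reference_histogram))
    vol <- match_histogram(vol, config$reference_histogram)
  v <- vol$data
  rng <- range(v)
  if (diff(rng) == 0) return(vol)  # degenerate histogram: identity
  d <- dim(v)
  scaled <- (v - rng[1]) / diff(rng)
  ntx <- max(2L, as.integer(ceiling(d[3] / config$clahe_tile_vox)))
  nty <- max(2L, as.integer(ceiling(d[2] / config$clahe_tile_vox)))
  limit <- max(config$clahe_clip * 256, 0.1)
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    sl <- t(scaled[z, , ])  # EBImage expects (x, y)
    eq <- EBImage::clahe(EBImage::Image(sl), nx = ntx, ny = nty,
                         bins = 256L, limit = limit)
    out[z, , ] <- t(EBImage::imageData(eq))
  }
  out <- pmin(pmax(out, 0), 1) * 65535
  volume(out, vol$spacing_um)
}

#' Full pre-registration conditioning
#'
#' Fixed order: isotropic down-sampling, bias correction, histogram
#' normalization / CLAHE.
#'
#' @param vol a [volume()].
#' @param config a [preprocess_config()].
#' @return A [volume()].
#' @export
preprocess_volume <- function(vol, config = preprocess_config()) {
  vol <- as_volume(vol)
  if (config$target_spacing_um > vol$spacing_um + 1e-9)
    vol <- downsample_isotropic(vol, config$target_spacing_um)
  if (config$bias_correction_on) vol <- correct_bias(vol)
  equalize(vol, config)
}
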