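# Iterative population-average template construction and symmetrization.

#' Template building configuration
#'
#' The default schedule follows the six-step iterative scheme used for
#' LSFM brain atlas construction: one affine registration step followed by
#' five B-spline steps, each aligning every original volume to the average
#' from the previous step.
#'
#' @param n_iterations number of register-and-average iterations.
#' @param iteration_models character vector (length `n_iterations`) of
#'   registration models per iteration, `"affine"` or `"bspline"`.
#' @param reference_index index of the reference brain for iteration 1, or
#'   `"random"` to draw it with `reference_seed`.
#' @param reference_seed seed used when `reference_index = "random"`.
#' @param normalize_histograms match every registered volume's histogram to
#'   the current target before averaging.
#' @param register_args list of extra arguments passed to [register()].
#' @return A `fos_template_config` list.
#' @export
template_config <- function(n_iterations = 6,
                            iteration_models = c("affine", rep("bspline", 5)),
                            reference_index = 1, reference_seed = 1,
                            normalize_histograms = TRUE,
                            register_args = list()) {
  if (length(iteration_models) != n_iterations)
    stop("n_iterations must equal length(iteration_models)")
  if (n_iterations < 1) stop("need at least one iteration")
  structure(list(n_iterations = n_iterations,
                 iteration_models = iteration_models,
                 reference_index = reference_index,
                 reference_seed = reference_seed,
                 normalize_histograms = normalize_histograms,
                 register_args = register_args),
            class = "fos_template_config")
}

#' Build an iterative population-average template
#'
#' Iteration 1 registers every volume to a chosen reference brain and
#' averages the registered volumes (voxelwise arithmetic mean); iteration
#' k >= 2 registers every *original* volume to the iteration-(k-1) average
#' with that iteration's model and re-averages. Histograms of registered
#' volumes are matched to the current target before averaging so no single
#' acquisition dominates the mean.
#'
#' @param volumes list of preprocessed [volume()]s on a common grid.
#' @param config a [template_config()].
#' @param verbose print per-iteration progress.
#' @return List of class `fos_template`: `template` ([volume()]),
#'   `transforms` (final per-subject transforms, fixed = template grid),
#'   `variance_trace` (mean voxelwise variance among registered volumes per
#'   iteration, a convergence diagnostic).
#' @export
build_template <- function(volumes, config = template_config(),
                           verbose = FALSE) {
  if (!length(volumes)) stop("empty input list")
  volumes <- lapply(volumes, as_volume)
  d <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), d), TRUE)))
    stop("volumes must share a common grid")
  ref_idx <- config$reference_index
  if (identical(ref_idx, "random"))
    ref_idx <- with_seed(config$reference_seed,
                         sample.int(length(volumes), 1L))
  target <- volumes[[min(ref_idx, length(volumes))]]
  transforms <- vector("list", length(volumes))
  variance_trace <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    model <- config$iteration_models[it]
    registered <- vector("list", length(volumes))
    for (i in seq_along(volumes)) {
      reg <- do.call(register, c(list(moving = volumes[[i]], fixed = target,
                                      model = model),
                                 config$register_args))
      transforms[[i]] <- reg$transform
      w <- apply_transform(volumes[[i]], reg$transform, "linear",
                           out_dim = dim(target))
      if (config$normalize_histograms) w <- match_histogram(w, target)
      registered[[i]] <- w
    }
    stack <- vapply(registered, function(v) as.vector(v$data),
                    numeric(prod(dim(target))))
    avg <- rowMeans(stack)
    vtr <- if (length(volumes) > 1) {
      mean(rowMeans(stack^2) - rowMeans(stack)^2) * length(volumes) /
        (length(volumes) - 1)
    } else 0
    variance_trace <- c(variance_trace, vtr)
    target <- volume(array(pmax(avg, 0), dim(target)), target$spacing_um)
    if (verbose)
      message(sprintf("template iteration %d (%s): mean voxel variance %.2f",
                      it, model, vtr))
  }
  structure(list(template = target, transforms = transforms,
                 variance_trace = variance_trace),
            class = "fos_template")
}

#' @export
print.fos_template <- function(x, ...) {
  cat(sprintf("<fos_template> %s, %d subjects, %d iterations\n",
              paste(dim(x$template), collapse = "x"),
              length(x$transforms), length(x$variance_trace)))
  invisible(x)
}

#' Symmetrize a template about a midplane
#'
#' Mirrors one hemisphere onto the other and blends the two with a
#' logistic (sigmoidal) weight centred on the midplane:
#' `out = w * template + (1 - w) * mirror(template)`, with `w = 0.5`
#' exactly at the midplane. Because the mirrored weight is `1 - w`, the
#' output is exactly invariant under mirroring about the midplane.
#'
#' @param template a [volume()].
#' @param midplane_axis axis index (1 = z, 2 = y, 3 = x) of the mirror
#'   normal; default 3, the left-right axis in (z, y, x) order.
#' @param blend_slope logistic scale in voxels (the 10-90 percent blend
#'   transition spans about 4.4 times this).
#' @param mirror_low_onto_high if `TRUE` (default) the low-index hemisphere
#'   dominates the low-index half of the output.
#' @return A mirror-symmetric [volume()].
#' @export
symmetrize <- function(template, midplane_axis = 3, blend_slope = 1,
                       mirror_low_onto_high = TRUE) {
  template <- as_volume(template)
  v <- template$data
  d <- dim(v)
  ax <- as.integer(midplane_axis)
  if (ax < 1 || ax > 3) stop("midplane_axis must be 1, 2 or 3")
  n <- d[ax]
  if (n < 2) stop("template must have width >= 2 on the midplane axis")
  idx_rev <- rev(seq_len(n))
  m <- switch(ax, v[idx_rev, , , drop = FALSE], v[, idx_rev, , drop = FALSE],
              v[, , idx_rev, drop = FALSE])
  mid <- (n - 1) / 2
  w1 <- 1 / (1 + exp(-((seq_len(n) - 1) - mid) / blend_slope))
  # enforce exact antisymmetry w(n-1-i) = 1 - w(i) so the blend is
  # bit-exactly mirror-invariant; odd widths get w = 0.5 at the midplane
  half <- seq_len(n %/% 2)
  w1[n + 1 - half] <- 1 - w1[half]
  if (n %% 2 == 1) w1[(n + 1) %/% 2] <- 0.5
  if (mirror_low_onto_high) w1 <- 1 - w1
  wshape <- c(1, 1, 1); wshape[ax] <- n
  w <- array(rep(1, prod(d)), d)
  w <- switch(ax,
              array(rep(w1, times = d[2] * d[3]), d),
              aperm(array(rep(w1, times = d[1] * d[3]), d[c(2, 1, 3)]), c(2, 1, 3)),
              aperm(array(rep(w1, times = d[1] * d[2]), d[c(3, 1, 2)]), c(2, 3, 1)))
  volume(w * v + (1 - w) * m, template$spacing_um)
}
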