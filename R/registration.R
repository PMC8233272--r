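# Pairwise volume registration: affine and multi-level cubic B-spline
# free-form deformation driven by Mattes-style mutual information (linear
# Parzen binning), optimised coarse-to-fine on an image pyramid.
#
# Convention (stated on every interface): a transform maps FIXED-image
# voxel coordinates into MOVING-image voxel coordinates (pull-back /
# resampling convention). A dense displacement field u is the transform
# minus identity, in voxel units of the fixed image, so resampling is
# out(x) = moving(x + u(x)).

#' Transform constructors
#'
#' `affine_transform(A, t)` maps fixed voxel coordinate `x` (z, y, x order)
#' to `A %*% x + t` in the moving image. `bspline_transform()` holds one or
#' more cubic B-spline control grids (a multi-resolution pyramid of
#' displacement increments whose densifications sum). `field_transform()`
#' wraps a dense displacement field. All carry the fixed-image shape `dim`.
#'
#' @param A 3x3 matrix (z, y, x row/column order).
#' @param t length-3 offset in voxels.
#' @param dim fixed-image shape (nz, ny, nx).
#' @return A `fos_transform` object.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0), dim = NULL) {
  stopifnot(all(dim(A) == c(3, 3)), length(t) == 3)
  if (abs(det(A)) < 1e-12) stop("affine matrix must be invertible")
  structure(list(kind = "affine", A = A, t = as.numeric(t), dim = dim),
            class = c("fos_affine", "fos_transform"))
}

#' @rdname affine_transform
#' @param grids list of control grids, each
#'   `list(coef = array(cz, cy, cx, 3), origin, spacing)` with origin and
#'   spacing in fixed-image voxels; densified displacements sum.
#' @export
bspline_transform <- function(grids, dim) {
  structure(list(kind = "bspline", grids = grids, dim = as.integer(dim)),
            class = c("fos_bspline", "fos_transform"))
}

#' @rdname affine_transform
#' @param u dense displacement array `(nz, ny, nx, 3)`, voxel units.
#' @export
field_transform <- function(u, dim = NULL) {
  if (any(!is.finite(u))) stop("displacement components must be finite")
  if (is.null(dim)) dim <- base::dim(u)[1:3]
  structure(list(kind = "field", u = u, dim = as.integer(dim)),
            class = c("fos_field", "fos_transform"))
}

#' @rdname affine_transform
#' @export
identity_transform <- function(dim = NULL) affine_transform(diag(3), c(0, 0, 0), dim)

#' @export
print.fos_transform <- function(x, ...) {
  cat(sprintf("<fos_transform: %s> fixed -> moving, domain %s\n", x$kind,
              paste(x$dim %||% "?", collapse = "x")))
  invisible(x)
}

#' Densify a transform into a displacement field
#'
#' Samples the transform on every voxel of the fixed grid and subtracts the
#' identity, giving per-voxel (z, y, x) displacements in voxel units.
#'
#' @param tf a `fos_transform`.
#' @param dim fixed-image shape; defaults to the transform's domain.
#' @return Array `(nz, ny, nx, 3)`.
#' @export
as_field <- function(tf, dim = NULL) {
  dim <- as.integer(dim %||% tf$dim)
  if (is.null(dim)) stop("transform has no domain; pass `dim`")
  if (inherits(tf, "fos_affine"))
    return(array(cpp_affine_field(as.numeric(t(tf$A)), tf$t, dim), c(dim, 3)))
  if (inherits(tf, "fos_field")) {
    if (identical(as.integer(dim(tf$u)[1:3]), dim)) return(tf$u)
    stop("field transform domain mismatch")
  }
  if (inherits(tf, "fos_bspline")) {
    u <- array(0, c(dim, 3))
    for (g in tf$grids) {
      cd <- dim(g$coef)[1:3]
      u <- u + array(cpp_bspline_densify(as.numeric(g$coef), as.integer(cd),
                                         as.numeric(g$origin),
                                         as.numeric(g$spacing), dim),
                     c(dim, 3))
    }
    return(u)
  }
  stop("unknown transform kind")
}

#' Map points through a transform
#'
#' @param tf a `fos_transform`.
#' @param pts n x 3 matrix of fixed-image voxel coordinates (z, y, x).
#' @return n x 3 matrix of moving-image voxel coordinates.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (inherits(tf, "fos_affine"))
    return(t(tf$A %*% t(pts) + tf$t))
  u <- as_field(tf)
  disp <- sapply(1:3, function(c) interp3(u[, , , c], pts, clamp = TRUE))
  pts + matrix(disp, ncol = 3)
}

# trilinear interpolation of a 3-D array at fractional (z, y, x) points
interp3 <- function(arr, pts, clamp = TRUE) {
  d <- dim(arr)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (clamp) p <- pmin(pmax(p, 0), d - 1)
    p0 <- pmin(floor(p), d - 2); p0 <- pmax(p0, 0)
    f <- p - p0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dz) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dx) f[3] else 1 - f[3])
      if (w > 0) acc <- acc + w * arr[p0[1] + dz + 1, p0[2] + dy + 1, p0[3] + dx + 1]
    }
    out[i] <- acc
  }
  out
}

#' Resample a volume or label volume through a transform
#'
#' Pulls the moving image back onto the fixed grid: `out(x) = vol(t(x))`.
#' Intensity volumes use trilinear interpolation, label volumes must use
#' nearest-neighbour (linear interpolation on labels is refused); values
#' outside the moving domain are 0.
#'
#' @param vol a [volume()] or [label_volume()].
#' @param tf a `fos_transform`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param out_dim output (fixed) grid shape; defaults to the input shape.
#' @return Same type as `vol`, on the fixed grid.
#' @export
apply_transform <- function(vol, tf, interpolation = NULL, out_dim = NULL) {
  is_lab <- inherits(vol, "fos_labels")
  if (is.null(interpolation)) interpolation <- if (is_lab) "nearest" else "linear"
  if (is_lab && interpolation == "linear")
    stop("linear interpolation on label volumes is not allowed")
  arr <- if (is_lab) array(as.numeric(vol$labels), dim(vol$labels)) else vol$data
  d <- as.integer(dim(arr))
  od <- as.integer(out_dim %||% tf$dim %||% d)
  mode <- if (interpolation == "nearest") 1L else 0L
  if (inherits(tf, "fos_affine")) {
    out <- cpp_sample_affine(arr, d, as.numeric(t(tf$A)), tf$t, od, mode)
  } else {
    u <- as_field(tf, od)
    if (!identical(as.integer(dim(u)[1:3]), od))
      stop("transform domain does not match output grid")
    out <- cpp_sample_field_anydim(arr, d, od, u, mode)
  }
  out <- array(out, od)
  if (is_lab) {
    label_volume(array(as.integer(round(out)), od), vol$spacing_um,
                 ontology = vol$ontology)
  } else {
    volume(pmax(out, 0), vol$spacing_um)
  }
}

# sample `arr` (shape d) at x + u(x) for x on the output grid (shape od);
# when od == d this is the plain field sampler
cpp_sample_field_anydim <- function(arr, d, od, u, mode) {
  if (identical(d, od))
    return(cpp_sample_field(arr, d, as.numeric(u), mode))
  # general case: build explicit coordinates via the affine sampler per axis
  stop("dense-field resampling requires matching grids")
}

#' Invert a transform
#'
#' Affine transforms invert in closed form; B-spline and dense-field
#' transforms are inverted numerically by fixed-point iteration on the
#' dense field (`v(x) = -u(x + v(x))`). Divergence is reported with the
#' final maximum residual step.
#'
#' @param tf a `fos_transform`.
#' @param iters,tol fixed-point iteration controls.
#' @return A `fos_transform` (affine or dense field).
#' @export
invert_transform <- function(tf, iters = 50, tol = 1e-3) {
  if (inherits(tf, "fos_affine")) {
    Ai <- solve(tf$A)
    return(affine_transform(Ai, as.numeric(-Ai %*% tf$t), tf$dim))
  }
  u <- as_field(tf)
  d <- as.integer(dim(u)[1:3])
  res <- cpp_invert_field(as.numeric(u), d, as.integer(iters), tol)
  out <- field_transform(array(res$field, c(d, 3)), d)
  attr(out, "max_residual_step") <- res$max_residual_step
  if (res$max_residual_step > 0.5)
    warning("field inversion did not fully converge; max residual step ",
            signif(res$max_residual_step, 3), " voxels")
  out
}

#' Compose two transforms
#'
#' `compose_transforms(a, b)` is the transform `x -> a(b(x))`, so
#' `compose_transforms(invert_transform(t), t)` is approximately the
#' identity. Two affines compose in closed form; otherwise the composition
#' is computed densely on `b`'s domain.
#'
#' @param a,b `fos_transform`s.
#' @return A `fos_transform`.
#' @export
compose_transforms <- function(a, b) {
  if (inherits(a, "fos_affine") && inherits(b, "fos_affine"))
    return(affine_transform(a$A %*% b$A,
                            as.numeric(a$A %*% b$t + a$t), b$dim %||% a$dim))
  d <- as.integer(b$dim %||% a$dim)
  ua <- as_field(a, d)
  ub <- as_field(b, d)
  field_transform(array(cpp_compose_fields(as.numeric(ua), as.numeric(ub), d),
                        c(d, 3)), d)
}

# ---- mutual information ----------------------------------------------------

mi_from_hist <- function(h) {
  p <- h / sum(h)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (outer(pa, pb)[nz])))
}

mi_log_ratio <- function(h, eps = 1e-10) {
  p <- h / sum(h)
  pa <- rowSums(p); pb <- colSums(p)
  log((p + eps) / (outer(pa, pb) + eps))
}

mi_volumes <- function(a, b, nbins, arange, brange) {
  h <- cpp_joint_hist(as.numeric(a), as.numeric(b), nbins,
                      arange[1], arange[2], brange[1], brange[2])
  mi_from_hist(h)
}

# Gaussian smooth + factor-2 block-mean pyramid
pyramid <- function(arr, nlev) {
  out <- list(arr)
  for (l in seq_len(nlev - 1)) {
    cur <- out[[l]]
    d <- dim(cur)
    if (min(d) < 16) { break }
    sm <- array(cpp_gauss3(cur, as.integer(d), rep(1, 3)), d)
    crop <- (d %/% 2L) * 2L
    sm <- sm[seq_len(crop[1]), seq_len(crop[2]), seq_len(crop[3]), drop = FALSE]
    out[[l + 1]] <- array(cpp_block_mean(sm, as.integer(dim(sm)), rep(2L, 3L)),
                          dim(sm) %/% 2L)
  }
  rev(out)  # coarse first
}

# ---- registration driver ---------------------------------------------------

#' Register a moving volume to a fixed volume
#'
#' Multi-resolution intensity-based registration with a mutual-information
#' similarity metric. `model = "affine"` optimises a full 12-parameter
#' affine (gradient-free BFGS on the MI objective, with a coarse
#' translation search for initialisation). `model = "bspline"` optimises
#' cubic B-spline free-form deformations coarse-to-fine; the control-point
#' spacing halves per pyramid level (16 to 4 fixed-image voxels by
#' default) and coefficients follow the analytic MI ascent force projected
#' onto the control grid. The optimisation is fully deterministic.
#'
#' If the final metric is no better than the identity alignment, the
#' identity transform is returned (with a warning).
#'
#' @param moving,fixed [volume()]s on the same spacing convention.
#' @param model `"affine"` or `"bspline"`.
#' @param metric similarity metric; `"mi"` (mutual information) only.
#' @param levels number of pyramid levels (>= 1).
#' @param nbins histogram bins for MI.
#' @param iterations B-spline ascent iterations per level.
#' @param control_spacing_vox B-spline control spacing at the finest level.
#' @param step_vox maximal control-point update per ascent step, voxels.
#' @param verbose print per-level metric values.
#' @return List of class `fos_registration`: `transform` (fixed -> moving),
#'   `field` (dense displacement, voxel units), `metric_initial` and
#'   `metric_final` (negated MI; lower is better).
#' @export
register <- function(moving, fixed, model = c("affine", "bspline"),
                     metric = "mi", levels = 4, nbins = 32, iterations = 40,
                     control_spacing_vox = 4, step_vox = 0.4,
                     verbose = FALSE) {
  model <- match.arg(model)
  if (metric != "mi") stop("only the mutual-information metric is supported")
  if (levels < 1) stop("levels must be >= 1")
  moving <- as_volume(moving); fixed <- as_volume(fixed)
  if (!length(fixed$data) || !length(moving$data)) stop("empty volume")
  if (max(moving$data) == 0 || max(fixed$data) == 0) {
    warning("volume without intensity support; returning identity")
    d <- as.integer(dim(fixed))
    t0 <- identity_transform(d)
    return(structure(list(transform = t0, field = as_field(t0, d),
                          metric_initial = 0, metric_final = 0),
                     class = "fos_registration"))
  }
  d <- as.integer(dim(fixed))
  fr <- range(fixed$data); mr <- range(moving$data)
  mi0 <- mi_volumes(fixed$data, moving$data, nbins, fr, mr)
  res <- if (model == "affine") {
    register_affine(moving$data, fixed$data, levels, nbins, fr, mr, verbose)
  } else {
    register_bspline(moving$data, fixed$data, levels, nbins, fr, mr,
                     iterations, control_spacing_vox, step_vox, verbose)
  }
  tr <- res$transform
  warped <- apply_transform(moving, tr, "linear", out_dim = d)
  mi1 <- mi_volumes(fixed$data, warped$data, nbins, fr, mr)
  if (mi1 < mi0) {
    warning("registration did not improve the metric; returning identity")
    tr <- identity_transform(d)
    mi1 <- mi0
  }
  structure(list(transform = tr, field = as_field(tr, d),
                 metric_initial = -mi0, metric_final = -mi1),
            class = "fos_registration")
}

#' @export
print.fos_registration <- function(x, ...) {
  cat(sprintf("<fos_registration> %s; metric %0.4f -> %0.4f (-MI)\n",
              x$transform$kind, x$metric_initial, x$metric_final))
  invisible(x)
}

# level-l coordinates x_l relate to full-res x by x = s*x_l + h, h=(s-1)/2
register_affine <- function(mov, fix, levels, nbins, fr, mr, verbose) {
  d <- as.integer(dim(fix))
  pf <- pyramid(fix, levels)
  pm <- pyramid(mov, levels)
  nlev <- min(length(pf), length(pm))
  pf <- pf[seq_len(nlev)]; pm <- pm[seq_len(nlev)]
  # parameters in FULL-RES coordinates: A (row-major 9) around identity, t
  par <- c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0)
  # deterministic stride subsampling keeps the metric cost bounded at fine
  # pyramid levels without introducing randomness
  metric_stride <- function(dl, cap = 150000) {
    st <- 1L
    while (prod(ceiling(dl / st)) > cap) st <- st + 1L
    st
  }
  obj_factory <- function(fl, ml, s) {
    dl <- as.integer(dim(fl))
    st <- metric_stride(dl)
    sub <- lapply(dl, function(n) seq(1L, n, by = st))
    fsub <- as.numeric(fl[sub[[1]], sub[[2]], sub[[3]]])
    odim <- as.integer(vapply(sub, length, 1L))
    S <- diag(3) * st
    function(par) {
      A <- matrix(par[1:9], 3, 3, byrow = TRUE)
      t_full <- par[10:12]
      h <- rep((s - 1) / 2, 3)
      tl <- (A %*% h + t_full - h) / s
      w <- cpp_sample_affine(ml, as.integer(dim(ml)),
                             as.numeric(t(A %*% S)), as.numeric(tl), odim, 0L)
      h2 <- cpp_joint_hist(fsub, as.numeric(w), nbins, fr[1], fr[2],
                           mr[1], mr[2])
      -mi_from_hist(h2)
    }
  }
  for (l in seq_len(nlev)) {
    s <- 2^(nlev - l)
    fl <- pf[[l]]; ml <- pm[[l]]
    obj <- obj_factory(fl, ml, s)
    if (l == 1) {
      # coarse exhaustive translation search (full-res units)
      ext <- pmax(2, round(0.15 * d))
      grid_step <- max(1, round(min(d) / 32)) * 2
      best <- obj(par); best_t <- par[10:12]
      for (tz in seq(-ext[1], ext[1], by = grid_step))
        for (ty in seq(-ext[2], ext[2], by = grid_step))
          for (tx in seq(-ext[3], ext[3], by = grid_step)) {
            p2 <- par; p2[10:12] <- c(tz, ty, tx)
            v <- obj(p2)
            if (v < best) { best <- v; best_t <- c(tz, ty, tx) }
          }
      par[10:12] <- best_t
    }
    maxit <- if (l == nlev) 20 else 40
    opt <- optim(par, obj, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-6,
                                parscale = c(rep(0.02, 9), rep(1, 3))))
    par <- opt$par
    if (verbose) message(sprintf("affine level %d (factor %d): -MI = %.5f",
                                 l, s, opt$value))
  }
  A <- matrix(par[1:9], 3, 3, byrow = TRUE)
  list(transform = affine_transform(A, par[10:12], d))
}

register_bspline <- function(mov, fix, levels, nbins, fr, mr, iterations,
                             cs_fine, step_vox, verbose) {
  d <- as.integer(dim(fix))
  pf <- pyramid(fix, levels)
  pm <- pyramid(mov, levels)
  nlev <- min(length(pf), length(pm))
  pf <- pf[seq_len(nlev)]; pm <- pm[seq_len(nlev)]
  grids <- list()  # control grids in full-res coordinates
  for (l in seq_len(nlev)) {
    s <- 2^(nlev - l)
    fl <- pf[[l]]; ml <- pm[[l]]
    dl <- as.integer(dim(fl))
    h <- (s - 1) / 2
    # base field on this level from already-frozen grids (level voxel units)
    ubase <- array(0, c(dl, 3))
    for (g in grids)
      ubase <- ubase + array(cpp_bspline_densify(
        as.numeric(g$coef), as.integer(dim(g$coef)[1:3]),
        (g$origin - h) / s, g$spacing / s, dl), c(dl, 3)) / s
    spacing_full <- cs_fine * s
    spacing_l <- rep(cs_fine, 3)
    origin_l <- rep(-cs_fine, 3)
    cdim <- as.integer(floor((dl - 1) / cs_fine) + 4L)
    coef <- array(0, c(cdim, 3))  # level voxel units during optimisation
    dens <- function(cf) array(cpp_bspline_densify(as.numeric(cf), cdim,
                                                   origin_l, spacing_l, dl),
                               c(dl, 3))
    mi_of <- function(u) {
      w <- cpp_sample_field(ml, dl, as.numeric(u), 0L)
      mi_volumes(fl, w, nbins, fr, mr)
    }
    u <- ubase
    best_mi <- mi_of(u)
    step <- step_vox
    fails <- 0L
    for (it in seq_len(iterations)) {
      w <- array(cpp_sample_field(ml, dl, as.numeric(u), 0L), dl)
      hst <- cpp_joint_hist(as.numeric(fl), as.numeric(w), nbins,
                            fr[1], fr[2], mr[1], mr[2])
      L <- mi_log_ratio(hst)
      force <- cpp_mi_force(fl, as.numeric(w), dl, L, fr[1], fr[2], mr[1], mr[2])
      g <- array(cpp_bspline_splat(as.numeric(force), dl, cdim,
                                   origin_l, spacing_l), c(cdim, 3))
      gmag <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
      mg <- max(gmag)
      if (mg < 1e-12) break
      # per-control-point normalized ascent: strong-force points move by
      # ~step, weak ones are damped, so flat regions still converge
      denom <- array(rep(gmag + 0.1 * mg, 3), dim(g))
      trial <- coef + g / denom * step
      ut <- ubase + dens(trial)
      mit <- mi_of(ut)
      if (mit > best_mi) {
        coef <- trial; u <- ut; best_mi <- mit
        step <- min(step * 1.2, 2 * step_vox)
        fails <- 0L
      } else {
        step <- step / 2
        fails <- fails + 1L
        if (step < 0.01 || fails > 6L) break
      }
    }
    if (verbose) message(sprintf("bspline level %d (factor %d): MI = %.5f",
                                 l, s, best_mi))
    grids[[length(grids) + 1L]] <- list(
      coef = coef * s,                       # full-res displacement units
      origin = origin_l * s + h,             # full-res coordinates
      spacing = rep(spacing_full, 3))
  }
  list(transform = bspline_transform(grids, d))
}
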