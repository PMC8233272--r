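test_that("channel alignment recovers a known in-plane shift", {
  ph <- make_phantom(c(32, 64, 64), 4, seed = 5)
  auto <- ph$auto
  sh <- apply_transform(auto, affine_transform(diag(3), c(0, -3, 2), dim(auto)),
                        "linear")
  al <- align_channels(auto, sh)
  tfs <- attr(al, "slice_transforms")
  # score only slices with substantial tissue content
  content <- apply(ph$labels$tissue_mask, 1, mean)
  good <- which(content > 0.3)
  tmat <- t(sapply(tfs[good], function(x) x$t2))
  err <- sqrt((tmat[, 1] - 3)^2 + (tmat[, 2] + 2)^2)
  expect_lt(max(err), 0.5)
})

test_that("self-alignment stays within a quarter voxel", {
  ph <- make_phantom(c(32, 48, 48), 4, seed = 6)
  al <- align_channels(ph$auto, ph$auto)
  content <- apply(ph$labels$tissue_mask, 1, mean)
  tfs <- attr(al, "slice_transforms")[content > 0.2]
  for (tf in tfs) {
    expect_lt(max(abs(tf$t2)), 0.25)
    expect_lt(max(abs(tf$A2 - diag(2))), 0.05)
  }
})

test_that("slices are processed independently", {
  ph <- make_phantom(c(32, 48, 48), 4, seed = 7)
  spec <- warp_phantom(ph$auto, 1.5, seed = 2)$warped
  al <- align_channels(ph$auto, spec)
  perm <- c(5:32, 1:4)
  auto_p <- volume(ph$auto$data[perm, , ])
  spec_p <- volume(spec$data[perm, , ])
  al_p <- align_channels(auto_p, spec_p)
  expect_equal(al_p$data, al$data[perm, , ], tolerance = 1e-12)
})

test_that("the per-slice top-hat matches its morphology oracle", {
  # constant slice opens to itself: top-hat is zero
  cv <- volume(array(500, c(3, 20, 20)))
  expect_true(all(subtract_background(cv, 3)$data == 0))
  # an isolated spike on constant background keeps (spike - background)
  v <- array(100, c(1, 21, 21)); v[1, 11, 11] <- 900
  th <- subtract_background(volume(v), 3)
  expect_equal(th$data[1, 11, 11], 800)
  expect_true(all(th$data[1, -11, ] == 0))
  # random volumes equal the brute-force erosion-then-dilation top-hat
  set.seed(61)
  for (r in c(2, 3)) {
    rv <- array(runif(4 * 18 * 18, 0, 1000), c(4, 18, 18))
    expect_equal(subtract_background(volume(rv), r)$data, brute_tophat(rv, r),
                 tolerance = 1e-12)
  }
  # contract: 0 <= out <= input
  rv <- array(runif(4 * 18 * 18, 0, 1000), c(4, 18, 18))
  out <- subtract_background(volume(rv), 2)$data
  expect_true(all(out >= 0 & out <= rv + 1e-12))
})

test_that("autofluorescence removal obeys its clamp contracts", {
  set.seed(62)
  d <- c(8, 16, 16)
  spec <- volume(array(runif(prod(d), 0, 1000), d))
  zero <- volume(array(0, d))
  expect_warning(out <- remove_autofluorescence(spec, zero), "all zero")
  expect_identical(out$data, spec$data)
  auto <- volume(array(runif(prod(d), 0, 800), d))
  out2 <- remove_autofluorescence(spec, auto,
                                  detect_config(autofluor_scale = 1))
  expect_true(all(out2$data >= 0))
  expect_true(all(out2$data <= spec$data + 1e-12))
  expect_equal(out2$data, pmax(spec$data - auto$data, 0))
})

test_that("shared artifacts are suppressed while cells survive", {
  # clean construction: flat channels, equal-height artifacts in both,
  # spec-only gaussian cells well separated from the artifacts
  d <- c(24, 48, 48)
  auto <- array(1200, d); spec <- array(200, d)
  blob <- function(arr, c0, peak, sigma) {
    g <- expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1), x = 0:(d[3] - 1))
    arr + array(peak * exp(-((g$z - c0[1])^2 + (g$y - c0[2])^2 +
                             (g$x - c0[3])^2) / (2 * sigma^2)), d)
  }
  arts <- rbind(c(6, 10, 10), c(6, 36, 36), c(17, 10, 36))
  cells <- rbind(c(12, 24, 10), c(12, 24, 40), c(17, 38, 12))
  for (i in 1:3) {
    auto <- blob(auto, arts[i, ], 2500, 2)
    spec <- blob(spec, arts[i, ], 2500, 2)
  }
  for (i in 1:3) spec <- blob(spec, cells[i, ], 3000, 1.5)
  spec_bg <- subtract_background(volume(spec), 7)
  auto_bg <- subtract_background(volume(auto), 7)
  out <- remove_autofluorescence(spec_bg, auto_bg)
  expect_equal(attr(out, "autofluor_scale"), 1, tolerance = 0.02)
  for (i in 1:3) {
    p <- arts[i, ] + 1
    expect_lt(out$data[p[1], p[2], p[3]], 800)    # below the cut-off
    p <- cells[i, ] + 1
    expect_gt(out$data[p[1], p[2], p[3]],          # cells within 1 percent
              0.99 * spec_bg$data[p[1], p[2], p[3]])
  }
  # on a noisy phantom the same correction still suppresses artifacts and
  # leaves clear cells nearly intact
  ph <- test_phantom()
  ic <- implant_cells(ph$labels, c(`2` = 8), peak_intensity = 3000,
                      min_sep = 10, seed = 71)
  ar <- add_shared_artifacts(ph$auto, ic$spec, n = 5, intensity = 2500,
                             seed = 72)
  sbg <- subtract_background(ar$spec, 7)
  abg <- subtract_background(ar$auto, 7)
  outn <- remove_autofluorescence(sbg, abg)
  for (i in seq_len(5)) {
    p <- ar$truth$artifact_centers[i, ] + 1L
    expect_lt(outn$data[p[1], p[2], p[3]], 800)
  }
  for (i in seq_len(nrow(ic$truth$cell_centers))) {
    p0 <- ic$truth$cell_centers[i, ]
    if (min(sqrt(rowSums(sweep(ar$truth$artifact_centers, 2, p0)^2))) < 10)
      next  # cells inside an artifact tail legitimately lose shared signal
    p <- p0 + 1L
    expect_gt(outn$data[p[1], p[2], p[3]], 0.97 * sbg$data[p[1], p[2], p[3]])
  }
})

test_that("maxima detection matches the exhaustive scan", {
  # degenerate cases
  expect_equal(nrow(detect_maxima(volume(array(0, c(6, 6, 6))))), 0)
  v <- array(0, c(9, 9, 9)); v[4, 5, 6] <- 7
  m <- detect_maxima(volume(v), c(3, 5, 5))
  expect_equal(unname(m), matrix(c(3L, 4L, 5L), 1))
  # random volumes against the brute-force oracle
  set.seed(7)
  for (rep in 1:5) {
    rv <- array(sample(0:30, 24 * 24 * 12, TRUE), c(12, 24, 24))
    got <- detect_maxima(volume(rv), c(3, 5, 5))
    want <- brute_maxima(rv, c(3, 5, 5))
    expect_equal(unname(got), unname(want))
  }
})

test_that("seeded watershed respects mask, seeds and the flood oracle", {
  # one seed on a uniform supra-cutoff blob claims exactly the blob
  v <- array(0, c(5, 9, 9)); v[2:4, 3:7, 3:7] <- 1000
  seg <- watershed_segment(volume(v), matrix(c(3L, 5L, 5L), 1), 800)
  expect_identical(seg == 1L, v >= 800)
  # no voxel above the cutoff: no segments, seeds dropped with warning
  low <- volume(array(100, c(4, 4, 4)))
  expect_warning(s0 <- watershed_segment(low, matrix(c(1L, 1L, 1L), 1), 800),
                 "dropped")
  expect_true(all(s0 == 0L))
  # two gaussian peaks with a valley: boundary in the valley, oracle match
  d <- c(5, 11, 21)
  g <- expand.grid(z = 0:4, y = 0:10, x = 0:20)
  pk <- function(c0) 1000 * exp(-((g$z - c0[1])^2 + (g$y - c0[2])^2 +
                                  (g$x - c0[3])^2) / 18)
  v2 <- array(round(pk(c(2, 5, 5)) + pk(c(2, 5, 15))), d)
  seeds <- detect_maxima(volume(v2), c(3, 5, 5))
  seg2 <- watershed_segment(volume(v2), seeds, 200)
  expect_equal(sort(unique(as.vector(seg2[seg2 > 0]))), c(1L, 2L))
  left <- seg2[, , 1:9]; right <- seg2[, , 13:21]
  expect_true(all(left[left > 0] == seg2[seeds[1, 1] + 1, seeds[1, 2] + 1,
                                         seeds[1, 3] + 1]))
  expect_equal(array(seg2, dim(seg2)), brute_flood(v2, seeds, 200),
               ignore_attr = TRUE)
})

test_that("size filtering keeps exactly the in-range segments", {
  # engineered sizes {5, 8, 100, 194, 195}
  sizes <- c(5, 8, 100, 194, 195)
  d <- c(4, 20, 40)
  seg <- array(0L, d)
  pos <- 1
  for (k in seq_along(sizes)) {
    seg[seq(pos, pos + sizes[k] - 1)] <- k
    pos <- pos + sizes[k] + 7
  }
  out <- filter_by_size(seg, 8, 194)
  expect_setequal(attr(out, "kept_labels"), c(2L, 3L, 4L))
  expect_true(all(out[seg == 1L] == 0L))
  expect_true(all(out[seg == 3L] == 3L))
  # empty input
  e <- filter_by_size(array(0L, c(3, 3, 3)), 8, 194)
  expect_true(all(e == 0L))
  # random segmentations against a brute-force size scan
  set.seed(72)
  for (rep in 1:5) {
    rs <- array(sample(0:9, 10 * 12 * 12, TRUE), c(10, 12, 12))
    lo <- sample(5:40, 1); hi <- lo + sample(20:120, 1)
    out <- filter_by_size(rs, lo, hi)
    want_keep <- which(table(factor(rs[rs > 0], levels = 1:9)) >= lo &
                       table(factor(rs[rs > 0], levels = 1:9)) <= hi)
    expect_setequal(attr(out, "kept_labels"), as.integer(want_keep))
    expect_true(all(out[!(rs %in% want_keep)] == 0L))
  }
})

test_that("full detection is deterministic and recovers implanted cells", {
  ph <- test_phantom()
  ic <- implant_cells(ph$labels, c(`2` = 10, `3` = 8), min_sep = 8, seed = 81)
  cfg <- detect_config(align = FALSE)  # channels are co-registered by design
  c1 <- detect_cells(ph$auto, ic$spec, cfg)
  c2 <- detect_cells(ph$auto, ic$spec, cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  m <- match_detections(c1, ic$truth$cell_centers, tol = 2)
  expect_gte(m$tp / 18, 0.95)
  expect_lte(m$fp, 1)
  expect_true(all(c1$size >= 8 & c1$size <= 194))
})

test_that("raising the cutoff or narrowing size bounds never adds cells", {
  ph <- test_phantom()
  ic <- implant_cells(ph$labels, c(`2` = 12), min_sep = 8, seed = 91)
  ar <- add_shared_artifacts(ph$auto, ic$spec, n = 3, seed = 92)
  base <- detect_config(align = FALSE)
  n_base <- nrow(detect_cells(ar$auto, ar$spec, base))
  for (cut in c(1200, 2000)) {
    cfg <- detect_config(intensity_cutoff = cut, align = FALSE)
    expect_lte(nrow(detect_cells(ar$auto, ar$spec, cfg)), n_base)
  }
  wide <- detect_config(min_size_vox = 1, max_size_vox = 5000, align = FALSE)
  expect_gte(nrow(detect_cells(ar$auto, ar$spec, wide)), n_base)
})

test_that("detector stages only ever shrink the candidate set", {
  ph <- test_phantom()
  ic <- implant_cells(ph$labels, c(`2` = 10), min_sep = 8, seed = 95)
  spec_bg <- subtract_background(ic$spec, 7)
  auto_bg <- subtract_background(ph$auto, 7)
  corr <- remove_autofluorescence(spec_bg, auto_bg)
  seeds <- detect_maxima(corr, c(3, 5, 5))
  segs <- suppressWarnings(watershed_segment(corr, seeds, 800))
  surviving_ws <- sort(unique(as.vector(segs[segs > 0])))
  expect_true(all(surviving_ws %in% seq_len(nrow(seeds))))
  filt <- filter_by_size(segs, 8, 194)
  expect_true(all(attr(filt, "kept_labels") %in% surviving_ws))
})

test_that("cells are assigned to regions with exact count conservation", {
  ph <- test_phantom()
  set.seed(101)
  n <- 40
  pts <- cbind(sample(0:(dim(ph$labels)[1] - 1), n, TRUE),
               sample(0:(dim(ph$labels)[2] - 1), n, TRUE),
               sample(0:(dim(ph$labels)[3] - 1), n, TRUE))
  cells <- cell_set(data.frame(z = pts[, 1], y = pts[, 2], x = pts[, 3],
                               size = 10L, intensity = 1000,
                               region_id = 0L))
  res <- assign_cells(cells, ph$labels)
  expect_equal(sum(res$counts$count), n)     # nothing silently dropped
  want <- ph$labels$labels[pts + 1L]          # brute-force per-cell lookup
  expect_identical(res$cells$region_id, as.integer(want))
  # all cells inside one region count into that region
  inside <- which(ph$labels$labels == 3L, arr.ind = TRUE)[1:5, ] - 1L
  cells3 <- cell_set(data.frame(z = inside[, 1], y = inside[, 2],
                                x = inside[, 3], size = 10L,
                                intensity = 1000, region_id = 0L))
  res3 <- assign_cells(cells3, ph$labels)
  expect_equal(res3$counts$count[res3$counts$region_id == 3L], 5L)
  # a cell outside the tissue lands in the unassigned row
  out_cell <- cell_set(data.frame(z = 0, y = 0, x = 0, size = 1L,
                                  intensity = 1, region_id = 0L))
  reso <- assign_cells(out_cell, ph$labels)
  expect_equal(reso$counts$count[reso$counts$region_id == 0L], 1L)
})
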