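# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's C++ code paths.

# shift an array by (dz, dy, dx), padding with `fill`
shift3 <- function(a, dz, dy, dx, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

# cube max via exhaustive offset enumeration
brute_cube_max <- function(v, cube) {
  r <- cube %/% 2
  mx <- array(-Inf, dim(v))
  for (dz in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dx in -r[3]:r[3])
    mx <- pmax(mx, shift3(v, dz, dy, dx))
  mx
}

# local maxima with the plateau rule: candidates are positive voxels equal
# to the cube max; each 26-connected equal-valued candidate component
# contributes its lexicographically-first (z, y, x) voxel
brute_maxima <- function(v, cube) {
  d <- dim(v)
  cand <- which(v > 0 & v == brute_cube_max(v, cube))
  if (!length(cand)) return(matrix(integer(0), 0, 3))
  coords <- arrayInd(cand, d)
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  cand <- cand[ord]; coords <- coords[ord, , drop = FALSE]
  in_cand <- logical(prod(d)); in_cand[cand] <- TRUE
  visited <- logical(prod(d))
  seeds <- NULL
  for (k in seq_along(cand)) {
    i <- cand[k]
    if (visited[i]) next
    seeds <- rbind(seeds, coords[k, ])
    val <- v[i]
    queue <- i; visited[i] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (!dz && !dy && !dx) next
        p <- cc + c(dz, dy, dx)
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (in_cand[j] && !visited[j] && v[j] == val) {
          visited[j] <- TRUE; queue <- c(queue, j)
        }
      }
    }
  }
  unname(seeds - 1L)  # 0-based
}

# per-slice grayscale opening (erosion then dilation) with an inclusive
# disk of radius r, truncated at borders
brute_tophat <- function(v, r) {
  d <- dim(v)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  ero <- array(Inf, d); dil <- array(-Inf, d)
  for (k in seq_len(nrow(off))) {
    sh <- shift3(v, 0, off$dy[k], off$dx[k], fill = Inf)
    ero <- pmin(ero, sh)
  }
  for (k in seq_len(nrow(off))) {
    sh <- shift3(ero, 0, off$dy[k], off$dx[k], fill = -Inf)
    dil <- pmax(dil, sh)
  }
  v - dil
}

# seeded priority flood: highest intensity first, FIFO tie-break, mask
# {v >= cutoff}, 26-connectivity; neighbour push order (x, then y, then z)
# matching a plain nested-loop implementation
brute_flood <- function(v, seeds, cutoff) {
  d <- dim(v)
  lab <- array(0L, d)
  n <- prod(d)
  qval <- numeric(0); qord <- numeric(0); qidx <- integer(0); qlab <- integer(0)
  ord <- 0
  push <- function(i, l) {
    qval <<- c(qval, v[i]); qord <<- c(qord, ord); qidx <<- c(qidx, i)
    qlab <<- c(qlab, l); ord <<- ord + 1
  }
  for (k in seq_len(nrow(seeds))) {
    p <- seeds[k, ] + 1L
    i <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
    if (v[i] < cutoff || lab[i] != 0L) next
    lab[i] <- k
    push(i, k)
  }
  while (length(qidx)) {
    best <- which(qval == max(qval))
    best <- best[which.min(qord[best])]
    i <- qidx[best]; l <- qlab[best]
    qval <- qval[-best]; qord <- qord[-best]; qidx <- qidx[-best]; qlab <- qlab[-best]
    cc <- arrayInd(i, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (!dz && !dy && !dx) next
      p <- cc + c(dz, dy, dx)
      if (any(p < 1) || any(p > d)) next
      j <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
      if (lab[j] != 0L || v[j] < cutoff) next
      lab[j] <- l
      push(j, l)
    }
  }
  lab
}

# step-up BH: adjusted p_i = min over j with p_j >= p_i of p_j * m / rank_j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# shared small phantom (cached across test files)
.fixture_env <- new.env()
test_phantom <- function() {
  if (is.null(.fixture_env$ph))
    .fixture_env$ph <- make_phantom(c(40, 56, 56), 4, seed = 3)
  .fixture_env$ph
}

# greedy matching of detections against true centres within `tol` voxels
match_detections <- function(det, truth, tol = 2) {
  if (!nrow(det)) return(list(tp = 0, fp = 0))
  dd <- outer(seq_len(nrow(det)), seq_len(nrow(truth)),
              Vectorize(function(i, j)
                sqrt(sum((as.numeric(det[i, c("z", "y", "x")]) - truth[j, ])^2))))
  list(tp = sum(apply(dd, 2, min) <= tol),
       fp = sum(apply(dd, 1, min) > tol))
}
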