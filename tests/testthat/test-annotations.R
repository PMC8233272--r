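test_that("overlap resolution keeps single claims and fills by nearest claim", {
  d <- c(8L, 8L, 8L)
  mask <- array(TRUE, d)
  b1 <- array(0L, d); b1[, , 1:4] <- 1L
  b2 <- array(0L, d); b2[, , 5:8] <- 2L
  out <- resolve_overlaps(list(b1, b2), mask)
  expect_identical(out$labels[, , 1:4], array(1L, c(8, 8, 4)))
  expect_identical(out$labels[, , 5:8], array(2L, c(8, 8, 4)))
  # a voxel claimed by two blocks at equal distance: smaller region id wins
  b1b <- array(0L, d); b1b[4, 4, 4] <- 7L
  b2b <- array(0L, d); b2b[4, 4, 4] <- 3L
  single <- array(0L, d); single[4, 4, 3] <- 7L; single[4, 4, 5] <- 3L
  out2 <- resolve_overlaps(list(b1b, b2b,
                                single), array(FALSE, d))
  expect_equal(out2$labels[4, 4, 4], 3L)
})

test_that("overlap resolution matches an exhaustive nearest-claim search", {
  set.seed(31)
  d <- c(10L, 12L, 9L)
  mask <- array(runif(prod(d)) < 0.8, d)
  b1 <- array(0L, d); b2 <- array(0L, d)
  b1[sample(prod(d), 40)] <- sample(c(2L, 5L), 40, TRUE)
  b2[sample(prod(d), 40)] <- sample(c(3L, 9L), 40, TRUE)
  out <- resolve_overlaps(list(b1, b2), mask)
  claims <- (b1 != 0L) + (b2 != 0L)
  single <- array(0L, d)
  single[claims == 1L] <- pmax(b1, b2)[claims == 1L]
  coords <- arrayInd(which(single > 0L), d)
  for (i in which(claims > 1L | (claims == 0L & mask))) {
    p <- arrayInd(i, d)
    d2 <- rowSums(sweep(coords, 2, as.numeric(p))^2)
    best <- which(d2 == min(d2))
    want <- min(single[which(single > 0L)][best])
    expect_identical(out$labels[i], want)
  }
  expect_error(resolve_overlaps(list(array(0L, d)), mask), "empty")
})

test_that("identity transfer reproduces the source labels almost everywhere", {
  ph <- test_phantom()
  # on identical templates the registrations may return the identity
  # (with the guard's warning), which is exactly the expected behaviour
  out <- suppressWarnings(
    transfer_annotations(ph$auto, ph$labels, ph$auto, partition = NULL,
                         register_args = list(levels = 2, iterations = 15)))
  mask <- ph$labels$tissue_mask
  agree <- mean(out$labels[mask] == ph$labels$labels[mask])
  expect_gte(agree, 0.99)
  # full coverage contract: no unlabeled in-mask voxels
  expect_equal(sum(out$labels[mask] == 0L), 0)
})

test_that("transfer onto a warped target keeps boundaries within tolerance", {
  ph <- test_phantom()
  wp <- warp_phantom(ph$auto, amplitude_vox = 3, smoothness = 10, seed = 41)
  part <- parental_partition(list(a = c(2L, 3L), b = c(4L, 5L)))
  out <- suppressWarnings(
    transfer_annotations(ph$auto, ph$labels, wp$warped, partition = part,
                         register_args = list(levels = 2, iterations = 40)))
  # truth: target voxel x corresponds to source position x + u_true(x)
  truth <- apply_transform(ph$labels, field_transform(wp$field), "nearest")
  tmask <- truth$labels > 0L
  expect_equal(sum(out$labels[tmask] == 0L), 0)  # everything labelled
  agree <- mean(out$labels[tmask] == truth$labels[tmask])
  expect_gte(agree, 0.9)
  # disagreements must hug the truth label boundaries (displacement <= 2):
  # dilate the truth boundary by a 2-voxel chebyshev ball and check the
  # mislabeled voxels fall inside it
  lb <- truth$labels
  d <- dim(lb)
  bnd <- array(FALSE, d)
  dz <- lb[-1, , ] != lb[-d[1], , ]
  bnd[-1, , ] <- bnd[-1, , ] | dz; bnd[-d[1], , ] <- bnd[-d[1], , ] | dz
  dy <- lb[, -1, ] != lb[, -d[2], ]
  bnd[, -1, ] <- bnd[, -1, ] | dy; bnd[, -d[2], ] <- bnd[, -d[2], ] | dy
  dx <- lb[, , -1] != lb[, , -d[3]]
  bnd[, , -1] <- bnd[, , -1] | dx; bnd[, , -d[3]] <- bnd[, , -d[3]] | dx
  dil <- bnd
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2)
    dil <- dil | (shift3(array(as.numeric(bnd), dim(bnd)), dz, dy, dx, 0) > 0)
  wrong <- which(tmask & out$labels != truth$labels)
  expect_gte(mean(dil[wrong]), 0.95)
})

test_that("hierarchical collapse conserves counts exactly", {
  # toy tree: parent P (1) with leaves a (2): 3 cells, b (3): 4 cells
  ont <- ontology(data.frame(region_id = 1:3, acronym = c("P", "a", "b"),
                             name = c("P", "a", "b"),
                             parent_id = c(NA, 1, 1)))
  ct <- data.frame(animal_id = "m1", group = "g", region_id = c(2L, 3L),
                   count = c(3L, 4L))
  lm <- c(`2` = 1L, `3` = 1L)
  cc <- collapse_to_parents(ct, ont, lm)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$count, 7L)
  # identity map returns the input unchanged (up to aggregation order)
  idm <- c(`2` = 2L, `3` = 3L)
  cid <- collapse_to_parents(ct, ont, idm)
  expect_equal(sort(cid$count), c(3L, 4L))
  # unmapped leaf and non-ancestor targets are rejected
  expect_error(collapse_to_parents(ct, ont, c(`2` = 1L)), "no mapped ancestor")
  expect_error(collapse_to_parents(ct, ont, c(`2` = 3L, `3` = 1L)),
               "not an ancestor")
})

test_that("collapse conserves totals on random trees and level maps", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    parent <- c(NA, sapply(2:n, function(i) sample(seq_len(i - 1), 1)))
    ont <- ontology(data.frame(region_id = 1:n, acronym = paste0("n", 1:n),
                               name = paste0("n", 1:n), parent_id = parent))
    leaves <- ont$region_id[ont$is_leaf]
    lm <- vapply(leaves, function(l) {
      anc <- c(l, fosmap:::ancestor_chain(ont, l))
      sample(anc, 1)
    }, 0L)
    names(lm) <- as.character(leaves)
    ct <- data.frame(animal_id = "m1", group = "g", region_id = leaves,
                     count = sample(0:50, length(leaves), TRUE))
    cc <- collapse_to_parents(ct, ont, lm)
    expect_identical(sum(cc$count), sum(ct$count))
  }
})

test_that("label volumes collapse by relabelling voxels", {
  ont <- ontology(data.frame(region_id = 1:3, acronym = c("P", "a", "b"),
                             name = c("P", "a", "b"), parent_id = c(NA, 1, 1)))
  lv <- label_volume(array(sample(c(0L, 2L, 3L), 4^3, TRUE), c(4, 4, 4)),
                     ontology = ont)
  out <- collapse_to_parents(lv, ont, c(`2` = 1L, `3` = 1L))
  expect_true(all(out$labels[lv$labels > 0L] == 1L))
  expect_true(all(out$labels[lv$labels == 0L] == 0L))
})

test_that("partitions validate disjointness and ontology block extraction", {
  expect_error(parental_partition(list(a = 1:3, b = 3:5)), "disjoint")
  expect_error(parental_partition(list(1:3)), "named")
  sa <- synthetic_atlas_ontology(20, 8)
  blocks <- sa$ontology$region_id[!is.na(sa$ontology$parent_id) &
                                  sa$ontology$parent_id == 1L]
  part <- partition_from_ontology(sa$ontology, blocks)
  expect_length(part, 6)
  leaves <- sa$ontology$region_id[sa$ontology$is_leaf]
  expect_true(all(leaves %in% unlist(part)))
})
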