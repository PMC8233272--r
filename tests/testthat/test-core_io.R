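test_that("volume TIFF round-trips are bit-exact for integer data", {
  set.seed(1)
  arr <- array(sample.int(65536, 4 * 4 * 4, replace = TRUE) - 1L, c(4, 4, 4))
  v <- volume(array(as.double(arr), dim(arr)), spacing_um = 10)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  r <- read_volume(f, spacing_um = 10)
  expect_identical(r$data, v$data)
  expect_equal(r$spacing_um, 10)
})

test_that("a directory of per-slice TIFFs stacks along z", {
  dirp <- withr::local_tempdir()
  set.seed(2)
  slices <- lapply(1:3, function(i) matrix(sample(0:1000, 50), 10, 5))
  for (i in 1:3)
    tiff::writeTIFF(slices[[i]] / 65535, file.path(dirp, sprintf("s%02d.tif", i)),
                    bits.per.sample = 16L)
  v <- read_volume(dirp)
  expect_equal(dim(v), c(3L, 10L, 5L))
  expect_equal(v$data[2, , ], slices[[2]])
})

test_that("inconsistent slice shapes are rejected", {
  dirp <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 10, 10), file.path(dirp, "a.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0, 12, 10), file.path(dirp, "b.tif"), bits.per.sample = 16L)
  expect_error(read_volume(dirp), "inconsistent slice shapes")
  expect_error(read_volume("/nonexistent/vol.tif"), "not found")
})

test_that("NIfTI round-trip preserves data and carries spacing in the file", {
  set.seed(3)
  v <- volume(array(sample(0:5000, 4 * 5 * 6, TRUE), c(4, 5, 6)), spacing_um = 25)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, spacing_um = 999)  # must be overridden by the file
  expect_equal(r$data, v$data)
  expect_equal(r$spacing_um, 25, tolerance = 1e-6)
  lv <- label_volume(array(sample(0:4, 60, TRUE), c(4, 5, 3)), spacing_um = 25)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(lv, f2)
  r2 <- read_label_volume(f2)
  expect_identical(r2$labels, lv$labels)
})

test_that("volume invariants are enforced", {
  expect_error(volume(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(volume(array(1, c(2, 2)), 20), "3-D")
  expect_error(volume(array(1, c(2, 2, 2)), -5), "positive")
  expect_error(label_volume(array(1L, c(2, 2, 2)), 20,
                            tissue_mask = array(TRUE, c(3, 2, 2))),
               "share the label grid shape")
})

test_that("ontology reading computes leaves and validates the tree", {
  # toy 5-node tree: root -> (a, b); b -> (b1, b2)  => leaves a, b1, b2
  df <- data.frame(region_id = 1:5,
                   acronym = c("r", "a", "b", "b1", "b2"),
                   name = letters[1:5],
                   parent_id = c(NA, 1, 1, 3, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  ont <- read_ontology(f)
  expect_equal(n_leaf_regions(ont), 3)
  expect_setequal(ont$region_id[ont$is_leaf], c(2, 4, 5))
  # round-trip through write_ontology
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ontology(ont, f2)
  expect_equal(n_leaf_regions(read_ontology(f2)), 3)
})

test_that("ontology validation rejects cycles, duplicates and dangling parents", {
  base <- data.frame(region_id = 1:3, acronym = c("r", "a", "b"),
                     name = c("r", "a", "b"), parent_id = c(NA, 1, 1))
  self <- base; self$parent_id[2] <- 2
  expect_error(ontology(self), "cycl")
  two_cycle <- base; two_cycle$parent_id <- c(3, 1, 1)
  expect_error(ontology(two_cycle), "cycl")
  dup <- rbind(base, base[2, ])
  expect_error(ontology(dup), "duplicate")
  dang <- base; dang$parent_id[3] <- 99
  expect_error(ontology(dang), "dangling")
})

test_that("random parent rewirings that create cycles are always caught", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    parent <- c(NA, sapply(2:n, function(i) sample(seq_len(i - 1), 1)))
    df <- data.frame(region_id = 1:n, acronym = paste0("n", 1:n),
                     name = paste0("n", 1:n), parent_id = parent)
    expect_silent(ontology(df))  # a valid random tree passes
    # rewire one non-root node to a descendant (or itself) => cycle
    i <- sample(2:n, 1)
    desc <- c(i, descendant_ids(ontology(df), i))
    df$parent_id[i] <- desc[sample.int(length(desc), 1)]
    expect_error(ontology(df), "cycl")
  }
})

test_that("landmark tables round-trip and reject malformed rows", {
  set.seed(4)
  lm <- landmark_set(data.frame(name = sprintf("lm%02d", 1:27),
                                z = runif(27, 0, 95), y = runif(27, 0, 127),
                                x = runif(27, 0, 127)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  r <- read_landmarks(f)
  expect_equal(as.data.frame(r), as.data.frame(lm), tolerance = 1e-12)
  bad <- data.frame(name = c("a", "b"), z = c("1", "oops"), y = 1:2, x = 1:2)
  expect_error(landmark_set(bad), "row 2")
  expect_error(landmark_set(data.frame(name = c("a", "a"), z = 1:2,
                                       y = 1:2, x = 1:2)),
               "duplicate")
})

test_that("empty landmark file with header only gives an empty set", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,z,y,x", f)
  r <- read_landmarks(f)
  expect_s3_class(r, "fos_landmarks")
  expect_equal(nrow(r), 0)
})

test_that("cell tables round-trip at full precision", {
  set.seed(5)
  cells <- cell_set(data.frame(z = runif(10, 0, 50), y = runif(10, 0, 50),
                               x = runif(10, 0, 50),
                               size = sample(8:194, 10),
                               intensity = runif(10, 800, 5000),
                               region_id = sample(0:6, 10, TRUE)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(cells, f)
  r <- read_cell_table(f)
  expect_equal(as.data.frame(r), as.data.frame(cells), tolerance = 1e-12)
})

test_that("count tables enforce one row per animal and region", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(animal_id = c("m1", "m1"), group = "a",
                   region_id = c(2L, 2L), count = c(3L, 4L))
  write.csv(df, f, row.names = FALSE)
  expect_error(read_count_table(f), "one row per")
})
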