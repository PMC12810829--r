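# Volume / atlas / dataset I-O and the split allocator.

test_that("NIfTI volume round trip preserves data and squeezes singleton 4D", {
  v <- array(as.numeric(sample.int(1000, 16^3, replace = TRUE)), dim = c(16, 16, 16))
  p <- tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(dim(v2), dim(v))
  expect_equal(as.numeric(v2), as.numeric(v))  # integers are exact in float32

  # float32 payloads survive a second round trip bit-exactly
  vf <- array(rnorm(8^3), dim = c(8, 8, 8))
  p1 <- tempfile(fileext = ".nii.gz")
  write_volume(vf, p1)
  once <- read_volume(p1)
  p2 <- tempfile(fileext = ".nii.gz")
  write_volume(once, p2)
  expect_identical(as.numeric(read_volume(p2)), as.numeric(once))

  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(rnorm(16^3), dim = c(16, 16, 16, 1))), p4)
  expect_identical(dim(read_volume(p4)), c(16L, 16L, 16L))

  expect_error(read_volume(tempfile(fileext = ".nii")), "exist")
  p5 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(rnorm(4^3 * 3), dim = c(4, 4, 4, 3))), p5)
  expect_error(read_volume(p5), "3D")
})

test_that("a full-size scan volume reads back with its 80^3 shape", {
  p <- tempfile(fileext = ".nii.gz")
  write_volume(array(0, dim = c(80, 80, 80)), p)
  expect_identical(dim(read_volume(p)), c(80L, 80L, 80L))
})

test_that("normalize_volume standardizes, is idempotent and affine-invariant", {
  set.seed(3)
  v <- array(runif(10^3, 1, 9), dim = c(10, 10, 10))
  n1 <- normalize_volume(v)
  expect_lt(abs(mean(n1)), 1e-6)
  expect_lt(abs(mean(n1^2) - 1), 1e-6)
  expect_equal(as.numeric(normalize_volume(n1)), as.numeric(n1), tolerance = 1e-6)
  expect_equal(as.numeric(normalize_volume(5 * v + 7)), as.numeric(n1),
               tolerance = 1e-9)
  expect_error(normalize_volume(array(2, dim = c(4, 4, 4))), "constant")
})

test_that("read_atlas counts regions, re-indexes bijectively, flags missing names", {
  dirp <- tempfile()
  dir.create(dirp)
  lab <- array(rep(1:20, length.out = 5^3), dim = c(5, 5, 5))
  lp <- file.path(dirp, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(lab), dim = dim(lab))), lp)
  np <- file.path(dirp, "names.tsv")
  writeLines(c(paste(1:20, paste0("r", 1:20), sep = "\t")), np)
  a <- read_atlas(lp, np)
  expect_equal(a$R, 20L)

  # 96 regions, non-contiguous original IDs, comma dialect with header
  ids <- sort(sample(1:500, 96))
  lab96 <- array(rep(ids, length.out = 6^3), dim = c(6, 6, 6))
  lp96 <- file.path(dirp, "atlas96.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(lab96), dim = dim(lab96))), lp96)
  np96 <- file.path(dirp, "names96.csv")
  writeLines(c("id,name", paste(ids, paste0("region", ids), sep = ",")), np96)
  a96 <- read_atlas(lp96, np96)
  expect_equal(a96$R, 96L)
  expect_identical(sort(unique(as.integer(a96$labels))), 1:96)          # re-indexed
  expect_identical(a96$names$orig_id, ids)                              # bijection
  expect_identical(a96$names$name[a96$labels[2, 3, 4]],
                   paste0("region", lab96[2, 3, 4]))

  np_bad <- file.path(dirp, "bad.tsv")
  writeLines(paste(setdiff(1:20, 7), paste0("r", setdiff(1:20, 7)), sep = "\t"), np_bad)
  expect_error(read_atlas(lp, np_bad), "7")
})

test_that("split_dataset partitions with class balance and is deterministic", {
  vols <- replicate(140, array(0, dim = c(2, 2, 2)), simplify = FALSE)
  cls <- rep(c(0L, 1L), each = 70)
  ds <- split_dataset(vols, cls, c(0.7, 0.15, 0.15), seed = 9)
  expect_equal(sum(ds$split == "train"), 98L)
  expect_equal(sum(ds$split == "val"), 21L)
  expect_equal(sum(ds$split == "test"), 21L)
  tab <- table(ds$split, ds$classes)
  expect_true(all(abs(tab[, "0"] - tab[, "1"]) <= 1))    # balance within one
  expect_equal(length(ds$split), 140L)                   # partition: all assigned

  ds2 <- split_dataset(vols, cls, c(0.7, 0.15, 0.15), seed = 9)
  expect_identical(ds$split, ds2$split)

  all_train <- split_dataset(vols, cls, c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  expect_error(split_dataset(vols[1:3], c(0L, 1L, 1L), c(0.5, 0.25, 0.25), 1),
               "fewer samples")
  expect_error(split_dataset(vols, cls, c(0.5, 0.2, 0.2), 1), "sum to 1")
})

test_that("cohort manifest round trip restores volumes, classes and split", {
  tc <- tiny_cohort(shape = c(6L, 6L, 6L), n = 3L)
  d <- tempfile()
  mp <- write_cohort(tc$cohort, d)
  back <- read_cohort(mp)
  expect_identical(back$classes, tc$cohort$classes)
  expect_identical(back$split, tc$cohort$split)
  expect_equal(as.numeric(back$volumes[[5]]), as.numeric(tc$cohort$volumes[[5]]),
               tolerance = 1e-6)
})
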