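test_that("minmax normalization: arithmetic, degenerate case, idempotence", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_identical(minmax_normalize(matrix(3, 2, 2)), array(0, c(2, 2)))
  x <- matrix(rnorm(16), 4, 4)
  n1 <- minmax_normalize(x)
  expect_equal(minmax_normalize(n1), n1)
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("annotation rasterization matches an exhaustive voxel-distance scan", {
  set.seed(30)
  for (trial in 1:5) {
    shape <- sample(10:20, 3, replace = TRUE)
    spacing <- runif(3, 0.5, 2)
    origin <- runif(3, -10, 10)
    ctr_vox <- vapply(shape, function(s) runif(1, 2, s - 3), numeric(1))
    world <- origin + ctr_vox * spacing
    ann <- nodule_annotation("t", world[1], world[2], world[3],
                             diameter = runif(1, 1, 6))
    mask <- annotation_to_mask(ann, origin, spacing, shape)
    # independent oracle: test every voxel's mm distance
    oracle <- array(0L, shape)
    for (i in 1:shape[1]) for (j in 1:shape[2]) for (k in 1:shape[3]) {
      d <- sqrt(sum((((c(i, j, k) - 1) - ctr_vox) * spacing)^2))
      if (d <= ann$diameter / 2) oracle[i, j, k] <- 1L
    }
    if (sum(oracle) == 0L) next  # sub-voxel sphere handled below
    expect_identical(mask, oracle)
  }
})

test_that("annotation edge cases: face-neighbour ball, sub-voxel, bounds", {
  shape <- c(9L, 9L, 9L); spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  ann <- nodule_annotation("t", 4, 4, 4, diameter = 2)
  mask <- annotation_to_mask(ann, origin, spacing, shape)
  expect_identical(sum(mask), 7L)  # centre voxel plus its 6 face neighbours
  expect_identical(mask[5, 5, 5], 1L)
  expect_identical(mask[6, 5, 5] + mask[4, 5, 5] + mask[5, 6, 5] +
                     mask[5, 4, 5] + mask[5, 5, 6] + mask[5, 5, 4], 6L)

  tiny <- annotation_to_mask(nodule_annotation("t", 4.2, 4.2, 4.2, 0.3),
                             origin, spacing, shape)
  expect_identical(sum(tiny), 1L)
  expect_identical(tiny[5, 5, 5], 1L)

  expect_error(annotation_to_mask(nodule_annotation("t", 50, 4, 4, 2),
                                  origin, spacing, shape), "outside")
})

test_that("lesion-centred cropping clamps at borders and keeps its size", {
  src <- matrix(seq_len(512 * 512), 512, 512)
  p <- crop_patch(src, c(256, 256))
  expect_equal(dim(p), c(128, 128))
  expect_identical(p[1, 1], src[192, 192])
  pc <- crop_patch(src, c(0, 0))
  expect_identical(pc, src[1:128, 1:128])
  set.seed(31)
  for (i in 1:1000) {
    ctr <- runif(2, -10, 522)
    expect_identical(dim(crop_patch(src, ctr)), c(128L, 128L))
  }
  expect_error(crop_patch(matrix(0, 100, 100), c(50, 50)), "resample")
})

test_that("resampling hits the target size and respects mask labels", {
  img <- matrix(runif(512 * 512), 512, 512)
  out <- resample_to(img, 128)
  expect_equal(dim(out), c(128, 128))
  msk <- matrix(sample(0:2, 64 * 64, replace = TRUE), 64, 64)
  rmk <- resample_to(msk, 32, is_mask = TRUE)
  expect_true(all(rmk %in% 0:2))
  same <- matrix(runif(128 * 128), 128, 128)
  expect_identical(resample_to(same, 128), same)
})

test_that("dataset splitting is deterministic, disjoint and exhaustive", {
  ids <- sprintf("c%02d", 1:10)
  sp <- split_dataset(ids, seed = 7)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 1)
  expect_length(sp$test_ids, 1)
  expect_identical(sp, split_dataset(ids, seed = 7))
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, ids)
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_error(split_dataset(c("a", "b")), "at least 3")
})

test_that("MetaImage volumes round-trip through the .mhd/.raw pair", {
  dir <- withr::local_tempdir()
  vol <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  path <- file.path(dir, "vol.mhd")
  write_mhd(vol, path, spacing = c(0.7, 0.7, 1.25), origin = c(-100, -100, -50))
  rd <- read_mhd(path)
  expect_equal(rd$volume, vol, tolerance = 1e-6)  # float32 storage
  expect_equal(rd$spacing, c(0.7, 0.7, 1.25))
  expect_equal(rd$origin, c(-100, -100, -50))
  ivol <- array(sample(-1000:1000, 60), c(5, 4, 3))
  write_mhd(ivol, file.path(dir, "i.mhd"), type = "MET_SHORT")
  expect_identical(read_mhd(file.path(dir, "i.mhd"))$volume, ivol + 0)
})

test_that("NIfTI volumes round-trip", {
  dir <- withr::local_tempdir()
  vol <- array(runif(8 * 8 * 3), c(8, 8, 3))
  path <- file.path(dir, "v.nii.gz")
  write_nifti_volume(vol, path, spacing = c(1, 1, 2))
  rd <- read_nifti_volume(path)
  expect_equal(rd$volume, vol, tolerance = 1e-6)
  expect_equal(rd$spacing[1:3], c(1, 1, 2))
})

test_that("PNG slices round-trip; masks exactly, images to 8-bit", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(32 * 32), 32, 32)
  f <- file.path(dir, "img.png")
  write_slice_png(img, f)
  expect_lt(max(abs(read_slice_png(f) - img)), 1 / 255)
  msk <- matrix(sample(0:2, 32 * 32, replace = TRUE), 32, 32)
  fm <- file.path(dir, "mask.png")
  write_slice_png(msk, fm, is_mask = TRUE)
  expect_identical(read_slice_png(fm, is_mask = TRUE), msk)
})

test_that("annotation CSVs parse with and without a diameter column", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ann.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,-10.5,20.25,-3,6.5", "s2,0,1,2,3"), f)
  anns <- read_annotations(f)
  expect_length(anns, 2)
  expect_equal(anns[[1]]$diameter, 6.5)
  f2 <- file.path(dir, "ann2.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ", "s1,1,2,3"), f2)
  expect_equal(read_annotations(f2)[[1]]$diameter, 3)
  f3 <- file.path(dir, "bad.csv")
  writeLines(c("a,b", "1,2"), f3)
  expect_error(read_annotations(f3), "seriesuid")
})

test_that("volume-to-slice extraction yields normalized lesion-centred patches", {
  set.seed(32)
  vol <- array(rnorm(160 * 160 * 12, 40, 15), c(160, 160, 12))
  origin <- c(0, 0, 0); spacing <- c(1, 1, 2)
  ann <- nodule_annotation("s1", 80, 75, 12, diameter = 8)
  slices <- extract_labeled_slices(vol, list(ann), origin, spacing, side = 128L)
  expect_gt(length(slices), 0)
  for (sl in slices) {
    expect_equal(dim(sl$image), c(128, 128))
    expect_true(min(sl$image) >= 0 && max(sl$image) <= 1)
    expect_gt(sum(sl$mask), 0)
  }
})
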