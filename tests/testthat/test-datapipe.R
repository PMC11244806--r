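# Image I/O, normalization, patch extraction and splitting.

test_that("TIFF stacks round-trip losslessly", {
  dir <- withr::local_tempdir()
  set.seed(1)
  # 16-bit integer data on the k/65535 grid survives exactly
  ints <- array(sample(0:65535, 32^3, replace = TRUE), c(32, 32, 32))
  vol <- as_volume(ints / 65535, voxel_size = c(0.3, 0.3, 0.3))
  p <- file.path(dir, "x.tif")
  write_stack(vol, p, bits = 16L)
  back <- read_stack(p)
  expect_identical(round(back$data * 65535), ints * 1.0)
  expect_equal(back$voxel_size, c(0.3, 0.3, 0.3))
  # float32 path
  volf <- as_volume(array(rnorm(16^3), c(16, 16, 16)))
  pf <- file.path(dir, "f.tif")
  write_stack(volf, pf, bits = 32L)
  expect_equal(read_stack(pf)$data, volf$data, tolerance = 1e-6)
  # single-page TIFF reads as 2D
  write_stack(as_volume(matrix(runif(64), 8, 8)), file.path(dir, "s.tif"))
  expect_length(dim(read_stack(file.path(dir, "s.tif"))$data), 2)
  expect_error(read_stack(file.path(dir, "missing.tif")), "not found")
})

test_that("normalization maps min/max to -1/+1 affinely and inverts exactly", {
  ramp <- as_volume(matrix(seq(0, 255, length.out = 256), 16, 16))
  nr <- normalize(ramp)
  expect_equal(min(nr$data), -1)
  expect_equal(max(nr$data), 1)
  # affine formula: value 127.5 on [0, 255] maps to 0
  v <- as_volume(matrix(c(0, 127.5, 255, 10), 2, 2))
  expect_equal(normalize(v)$data[2, 1], 0)
  # round trip
  set.seed(2)
  vol <- as_volume(array(runif(1000, 3, 9), c(10, 10, 10)))
  back <- denormalize(normalize(vol))
  expect_equal(back$data, vol$data, tolerance = 1e-12)
  # denormalize with explicit affine maps [-1, 1] to [min, max]
  unit <- as_volume(matrix(c(-1, 1), 1, 2))
  expect_equal(as.numeric(denormalize(unit, affine = c(0, 255))$data), c(0, 255))
  expect_error(denormalize(unit), "no normalization affine")
  # constant image: zeros plus a warning, never NaN
  expect_warning(cz <- normalize(as_volume(matrix(4, 5, 5))), "constant")
  expect_true(all(cz$data == 0))
})

test_that("2D patch extraction follows the protocol counts and is seeded", {
  set.seed(3)
  vols <- list(as_volume(array(runif(4 * 140 * 150), c(4, 140, 150))),
               as_volume(array(runif(4 * 140 * 150), c(4, 140, 150))))
  ps <- extract_patches_2d(vols, size = 128, n_per_image = 2500, seed = 1)
  expect_length(ps$patches, 5000)  # 2500 per image, two images per domain
  expect_true(all(vapply(ps$patches, function(p) identical(dim(p), c(128L, 128L)),
                         logical(1))))
  coords1 <- ps$coords
  rm(ps); gc(FALSE)
  ps2 <- extract_patches_2d(vols, size = 128, n_per_image = 2500, seed = 1)
  expect_identical(coords1, ps2$coords)
  # in-bounds coordinates
  expect_true(all(ps2$coords[, "y"] >= 1 & ps2$coords[, "y"] + 127 <= 140))
  expect_true(all(ps2$coords[, "x"] >= 1 & ps2$coords[, "x"] + 127 <= 150))
  rm(ps2); gc(FALSE)
  expect_error(extract_patches_2d(as_volume(matrix(0, 50, 50)), size = 128,
                                  n_per_image = 5, seed = 1),
               "smaller than")
})

test_that("3D patch extraction yields protocol counts and seeded cubes", {
  set.seed(4)
  vols <- list(as_volume(array(runif(70^3), c(70, 70, 70))),
               as_volume(array(runif(70^3), c(70, 70, 70))))
  # protocol counts at a reduced cube edge (the count depends only on
  # n_images x n_per_image); the 64-cube geometry is checked separately
  ps <- extract_patches_3d(vols, size = 16, n_per_image = 900, seed = 2)
  expect_length(ps$patches, 1800)  # 900 per image, two images per domain
  coords1 <- ps$coords
  rm(ps); gc(FALSE)
  ps2 <- extract_patches_3d(vols, size = 16, n_per_image = 900, seed = 2)
  expect_identical(coords1, ps2$coords)
  rm(ps2); gc(FALSE)
  ps64 <- extract_patches_3d(vols, size = 64, n_per_image = 10, seed = 3)
  expect_identical(dim(ps64$patches[[1]]), c(64L, 64L, 64L))
  expect_true(all(ps64$coords >= 1 & ps64$coords + 63 <= 70))
})

test_that("train/validation split is a seeded exact partition", {
  set.seed(5)
  vol <- as_volume(array(runif(20 * 40 * 40), c(20, 40, 40)))
  ps <- extract_patches_2d(vol, size = 16, n_per_image = 1800, seed = 3)
  sp <- split_train_val(ps, fraction = 0.9, seed = 4)
  expect_length(sp$train$patches, 1620)  # 90 percent of 1800
  expect_length(sp$val$patches, 180)
  # union equals the input as a multiset of provenance coordinates
  # (positions can repeat under sampling with replacement)
  key <- function(s) paste(s$coords[, 1], s$coords[, 2], s$coords[, 3])
  expect_identical(sort(c(key(sp$train), key(sp$val))), sort(key(ps)))
  sp5 <- split_train_val(extract_patches_2d(vol, 16, 10, seed = 1), 0.5, seed = 1)
  expect_length(sp5$train$patches, 5)
  expect_length(sp5$val$patches, 5)
  expect_error(split_train_val(extract_patches_2d(vol, 16, 1, seed = 1), 0.9, 1),
               "at least 2")
})
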