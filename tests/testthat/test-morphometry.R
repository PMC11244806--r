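# Skeletonization, radius and branch-length recovery, axis profiles.

test_that("segmentation recovers rasterized tubes and handles degenerate input", {
  ph <- small_phantom()
  bc <- ph$channels$bc
  mask <- segment_network(bc)
  truth_mask <- bc > 0
  jaccard <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(jaccard, 0.99)  # noiseless channel: near-exact recovery
  # affine intensity rescaling leaves the Otsu mask unchanged
  expect_identical(segment_network(bc * 7 + 2), mask)
  expect_warning(empty <- segment_network(array(0, c(8, 8, 8))), "empty")
  expect_false(any(empty))
})

test_that("a straight tube skeletonizes to one branch with the right length and radius", {
  mask <- straight_tube_mask(shape = c(24, 24, 60), radius = 3, margin = 3)
  g <- skeletonize_network(mask, c(1, 1, 1))
  expect_equal(length(g$branches), 1)
  # axial length 55 voxels at 1 um/voxel
  expect_lt(abs(g$branches[[1]]$length_um - 55) / 55, 0.05)
  rs <- radius_stats(g)
  expect_lt(abs(rs$mean_radius_um - 3) / 3, 0.10)
  # lengths scale linearly with voxel size
  g2 <- skeletonize_network(mask, c(2, 2, 2))
  expect_equal(g2$branches[[1]]$length_um, 2 * g$branches[[1]]$length_um,
               tolerance = 1e-9)
  # empty mask: empty graph
  ge <- skeletonize_network(array(FALSE, c(6, 6, 6)))
  expect_equal(length(ge$branches), 0)
})

test_that("a Y-shaped tube gives three branches and one junction", {
  m <- array(0, c(40, 40, 40))
  m <- tissuegan:::rasterize_tube(m, rbind(c(20, 20, 2), c(20, 20, 20)), 2, c(1, 1, 1))
  m <- tissuegan:::rasterize_tube(m, rbind(c(20, 20, 20), c(35, 30, 38)), 2, c(1, 1, 1))
  m <- tissuegan:::rasterize_tube(m, rbind(c(20, 20, 20), c(5, 30, 38)), 2, c(1, 1, 1))
  g <- prune_spurs(skeletonize_network(m == 1, c(1, 1, 1)), 3)
  expect_equal(length(g$branches), 3)
  expect_equal(sum(g$nodes$degree > 2), 1)
})

test_that("radius statistics separate a bimodal two-tube population and track dilation", {
  m <- array(0, c(30, 60, 80))
  m <- tissuegan:::rasterize_tube(m, rbind(c(15, 15, 5), c(15, 15, 75)), 2, c(1, 1, 1))
  m <- tissuegan:::rasterize_tube(m, rbind(c(15, 45, 5), c(15, 45, 75)), 4, c(1, 1, 1))
  g <- skeletonize_network(m == 1, c(1, 1, 1))
  rs <- radius_stats(g)
  expect_lt(abs(rs$mean_radius_um - 3) / 3, 0.15)
  # bimodality: both radius classes well represented
  expect_gt(mean(rs$radii_um < 3), 0.25)
  expect_gt(mean(rs$radii_um > 3), 0.25)
  # dilating the mask by ~1 voxel raises the mean radius by ~1 voxel
  edt_bg <- tissuegan:::cpp_edt3d(array(as.numeric(!(m == 1)), dim(m)), c(1, 1, 1))
  dil <- (m == 1) | (edt_bg <= 1)
  g2 <- skeletonize_network(dil, c(1, 1, 1))
  expect_lt(abs((radius_stats(g2)$mean_radius_um - rs$mean_radius_um) - 1), 0.5)
})

test_that("branch length statistics average correctly and spur pruning removes short spurs", {
  m <- array(0, c(20, 20, 40))
  m <- tissuegan:::rasterize_tube(m, rbind(c(10, 10, 3), c(10, 10, 37)), 2, c(1, 1, 1))
  g <- skeletonize_network(m == 1, c(1, 1, 1))
  bl <- branch_length_stats(g)
  expect_equal(bl$n_branches, 1)
  expect_equal(bl$mean_length_um, g$branches[[1]]$length_um)
  # synthetic graph arithmetic: branches of 10 and 20 um average to 15
  g_fake <- g
  g_fake$branches <- list(list(length_um = 10, ends = c(1, 2), path = g$branches[[1]]$path),
                          list(length_um = 20, ends = c(2, 3), path = g$branches[[1]]$path))
  g_fake$nodes <- data.frame(id = 1:3, z = 1, y = 1, x = 1, degree = c(1, 2, 1))
  expect_equal(branch_length_stats(g_fake)$mean_length_um, 15)
  # a short terminal spur is pruned at the 2 um cutoff
  g_sp <- g_fake
  g_sp$branches <- c(g_sp$branches, list(list(length_um = 1, ends = c(3, 4),
                                              path = g$branches[[1]]$path)))
  g_sp$nodes <- rbind(g_sp$nodes, data.frame(id = 4, z = 1, y = 1, x = 1, degree = 1))
  bl_pruned <- branch_length_stats(g_sp, prune_um = 2)
  expect_equal(bl_pruned$n_branches, 2)
  expect_error(branch_length_stats(skeletonize_network(array(FALSE, c(5, 5, 5)))),
               "empty")
})

test_that("axis profiles bin correctly: uniform field, gradient, single sample", {
  axis <- list(origin = c(0, 0, 0), direction = c(0, 0, 1), length_vox = 100)
  set.seed(19)
  pos <- cbind(runif(500, 1, 10), runif(500, 1, 10), runif(500, 0, 100))
  # uniform quantity: every bin mean q, sd 0
  pu <- profile_along_axis(rep(7, 500), pos, axis, n_bins = 10)
  expect_true(all(abs(pu$mean - 7) < 1e-12))
  expect_true(all(pu$sd == 0))
  # linear gradient 2 -> 4 along the axis recovers endpoint values
  q <- 2 + 2 * pos[, 3] / 100
  pg <- profile_along_axis(q, pos, axis, n_bins = 10)
  expect_true(all(diff(pg$mean) > 0))
  expect_lt(abs(pg$mean[1] - 2) / 2, 0.10)
  expect_lt(abs(pg$mean[10] - 4) / 4, 0.10)
  # single sample: one occupied bin, sd absent
  p1 <- profile_along_axis(5, matrix(c(1, 1, 50), 1), axis, n_bins = 10)
  expect_equal(sum(p1$n), 1)
  expect_true(is.na(p1$sd[p1$n == 1]))
  expect_error(profile_along_axis(1, matrix(1, 1, 3), axis, n_bins = 0), "n_bins")
})

test_that("skeleton statistics are invariant to intensity rescaling of the channel", {
  ph <- small_phantom()
  m1 <- morphometry(ph$channels$bc, c(1, 1, 1), prune_um = 2)
  m2 <- morphometry(ph$channels$bc * 31 + 5, c(1, 1, 1), prune_um = 2)
  expect_equal(m1$branch_length$mean_length_um, m2$branch_length$mean_length_um)
  expect_equal(m1$radius$mean_radius_um, m2$radius$mean_radius_um)
})

test_that("the Euclidean distance transform matches an independent implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(23)
  mask <- array(as.numeric(runif(10^3) > 0.4), c(10, 10, 10))
  mine <- tissuegan:::cpp_edt3d(mask, c(1, 1, 1))
  dir <- withr::local_tempdir()
  writeLines(as.character(as.vector(mask)), file.path(dir, "mask.txt"))
  script <- file.path(dir, "edt.py")
  writeLines(c(
    "import numpy as np",
    "from scipy import ndimage",
    "import sys, os",
    "d = os.path.dirname(os.path.abspath(__file__))",
    "m = np.loadtxt(os.path.join(d, 'mask.txt')).reshape((10, 10, 10), order='F')",
    "e = ndimage.distance_transform_edt(m)",
    "np.savetxt(os.path.join(d, 'edt.txt'), e.flatten(order='F'))"
  ), script)
  status <- suppressWarnings(system2("python", script, stdout = FALSE, stderr = FALSE))
  skip_if(status != 0, "python/scipy unavailable")
  ref <- array(as.numeric(readLines(file.path(dir, "edt.txt"))), c(10, 10, 10))
  expect_equal(mine, ref, tolerance = 1e-8, ignore_attr = TRUE)
})
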