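# Synthetic liver phantom: geometry, determinism, attenuation, noise,
# unpaired mixing.

test_that("phantom generation is deterministic and channels are well-formed", {
  cfg <- phantom_config(shape = c(40, 48, 48), n_cells = 8, cell_diameter = 18,
                        attenuation_depth = 30, seed = 11)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$channels, ph2$channels)
  expect_identical(ph1$truth$cell_label_map, ph2$truth$cell_label_map)
  expect_setequal(names(ph1$channels), c("membrane", "bc", "sinusoid", "kupffer"))
  for (ch in ph1$channels) {
    expect_identical(dim(ch), as.integer(c(40, 48, 48)))
    expect_true(all(is.finite(ch)) && min(ch) >= 0)
  }
  # every channel contains structure
  expect_gt(mean(ph1$channels$membrane > 0), 0.01)
  expect_gt(sum(ph1$channels$bc), 0)
  expect_gt(sum(ph1$channels$sinusoid), 0)
  # centerline points lie inside the volume
  for (b in ph1$truth$bc_centerlines) {
    expect_true(all(b$points >= 0.5) &&
                  all(sweep(b$points, 2, dim(ph1$channels$bc), "<=")))
    expect_true(all(b$radius > 0))
  }
  expect_equal(sqrt(sum(ph1$truth$lobule_axis$direction^2)), 1)
})

test_that("different seeds give different phantoms", {
  cfg1 <- phantom_config(shape = c(32, 40, 40), n_cells = 6, cell_diameter = 15,
                         attenuation_depth = 20, seed = 1)
  cfg2 <- phantom_config(shape = c(32, 40, 40), n_cells = 6, cell_diameter = 15,
                         attenuation_depth = 20, seed = 2)
  expect_false(identical(generate_phantom(cfg1)$channels$membrane,
                         generate_phantom(cfg2)$channels$membrane))
})

test_that("tube rasterization recovers the configured radius via the distance transform", {
  # straight single centerline of radius 3 voxels
  mask <- straight_tube_mask(radius = 3)
  edt <- tissuegan:::cpp_edt3d(array(as.numeric(mask), dim(mask)), c(1, 1, 1))
  expect_lt(abs(max(edt) - 3), 0.5)
})

test_that("zero kupffer count yields an exactly-zero channel and too-small shapes error", {
  cfg <- phantom_config(shape = c(32, 40, 40), n_cells = 6, cell_diameter = 15,
                        kupffer_count = 0, attenuation_depth = 20, seed = 3)
  ph <- generate_phantom(cfg)
  expect_true(all(ph$channels$kupffer == 0))
  tiny <- phantom_config(shape = c(8, 8, 8), cell_diameter = 20,
                         attenuation_depth = 5, seed = 1)
  expect_error(generate_phantom(tiny), "too small")
})

test_that("depth attenuation is multiplicative, monotone, and correctly scaled", {
  cfg <- phantom_config(shape = c(40, 24, 24), n_cells = 4, cell_diameter = 12,
                        attenuation_depth = 20, seed = 7)
  ph <- generate_phantom(cfg)
  const <- ph
  const$channels$bc <- array(1, dim(ph$channels$bc))
  att <- apply_depth_attenuation(const, "bc", depth = 20, width = 10)
  prof <- depth_profile(as_volume(att$channels$bc))
  expect_gt(prof$mean_intensity[1], 0.95)
  expect_lt(prof$mean_intensity[40], 0.05)
  expect_true(all(diff(prof$mean_intensity) <= 1e-12))
  # knee far beyond the stack: volume essentially unchanged
  att2 <- apply_depth_attenuation(const, "bc", depth = 400, width = 10)
  expect_equal(att2$channels$bc, const$channels$bc, tolerance = 1e-6)
  expect_error(apply_depth_attenuation(ph, "nonexistent", 20, 10), "unknown channel")
})

test_that("noise model preserves the expectation and is seed-reproducible", {
  img <- array(5, c(30, 30, 30))
  n1 <- add_noise(img, gaussian_sd = 0.3, poisson_scale = 0.05, seed = 4)
  n2 <- add_noise(img, gaussian_sd = 0.3, poisson_scale = 0.05, seed = 4)
  n3 <- add_noise(img, gaussian_sd = 0.3, poisson_scale = 0.05, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  # CLT check: sample mean within 3 SE of the true value
  v <- 5
  se <- sd(n1) / sqrt(length(n1))
  expect_lt(abs(mean(n1) - v), 3 * se)
  # same summary statistics across seeds, within tolerance
  expect_lt(abs(mean(n1) - mean(n3)), 4 * se)
  # identity when both noise sources are off
  expect_identical(add_noise(img, 0, 0, seed = 1), img)
  expect_error(add_noise(img, gaussian_sd = -1), "non-negative")
})

test_that("unpaired mixing destroys correspondence but preserves multisets", {
  imgs <- lapply(1:10, function(i) matrix(i, 2, 2))
  pairs <- lapply(1:10, function(i) list(imgs[[i]], imgs[[i]] * 10))
  mixed <- make_unpaired(pairs, seed = 3)
  expect_identical(mixed$permutation, make_unpaired(pairs, seed = 3)$permutation)
  expect_false(any(mixed$permutation == 1:10))  # no pair left intact
  # multiset of B preserved
  expect_setequal(vapply(mixed$B, function(m) m[1, 1], numeric(1)),
                  (1:10) * 10)
  # 2 pairs: the swap is forced
  two <- make_unpaired(pairs[1:2], seed = 1)
  expect_identical(two$permutation, c(2L, 1L))
  expect_error(make_unpaired(pairs[1], seed = 1), "at least 2")
})

test_that("phantoms round-trip to disk with config and truth sidecar", {
  dir <- withr::local_tempdir()
  ph <- small_phantom()
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "membrane.tif")))
  expect_true(file.exists(file.path(dir, "phantom.json")))
  side <- jsonlite::read_json(file.path(dir, "phantom.json"))
  expect_equal(side$config$seed, ph$config$seed)
  expect_equal(length(side$truth$bc_centerlines), length(ph$truth$bc_centerlines))
  back <- read_stack(file.path(dir, "membrane.tif"))
  expect_equal(back$data, ph$channels$membrane, tolerance = 1e-6)
})
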