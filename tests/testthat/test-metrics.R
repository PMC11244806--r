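# Quality-metric suite: closed-form cases, perfect-match identities,
# degenerate-input contracts, and the block-decomposition identity.

test_that("cube partition follows the floor rule", {
  expect_equal(partition_cubes(array(0, c(640, 640, 128)), 128)$count, 25)
  p1 <- partition_cubes(array(0, c(128, 128, 128)), 128)
  expect_equal(p1$count, 1)
  expect_equal(unname(p1$origins[1, ]), c(1, 1, 1))
  # 130^3: one cube, 2-voxel margins discarded
  expect_equal(partition_cubes(array(0, c(130, 130, 130)), 128)$count, 1)
  expect_error(partition_cubes(array(0, c(100, 130, 130)), 128), "smaller")
})

test_that("pixel metrics match hand arithmetic and perfect-match identities", {
  set.seed(9)
  img <- array(runif(8^3), c(8, 8, 8))
  pm0 <- pixel_metrics(img, img)
  expect_equal(pm0$MSE, 0); expect_equal(pm0$MAE, 0)
  expect_equal(pm0$MSLE, 0); expect_equal(pm0$RMSE, 0)
  expect_identical(pm0$PSNR, Inf)
  # PSNR closed form: max(gt) 255, MSE 25 -> 10 log10(255^2/25) = 34.1514 dB
  gt <- matrix(c(255, rep(100, 99)), 10, 10)
  pred <- gt + 5
  pm <- pixel_metrics(pred, gt)
  expect_equal(pm$MSE, 25)
  expect_equal(pm$PSNR, 10 * log10(255^2 / 25), tolerance = 1e-12)
  expect_equal(pm$PSNR, 34.1514, tolerance = 1e-4)
  # two-pixel case
  pm2 <- pixel_metrics(matrix(c(0, 1), 1, 2), matrix(c(0, 0), 1, 2))
  expect_equal(pm2$MSE, 0.5)
  expect_equal(pm2$MAE, 0.5)
  expect_equal(pm2$RMSE, sqrt(0.5), tolerance = 1e-12)
  expect_error(pixel_metrics(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("MSE equals RMSE squared and MAE <= RMSE on random inputs", {
  set.seed(10)
  for (i in 1:5) {
    a <- array(rnorm(6^3), c(6, 6, 6)); b <- array(rnorm(6^3), c(6, 6, 6))
    pm <- pixel_metrics(a, b)
    expect_equal(pm$MSE, pm$RMSE^2, tolerance = 1e-12)
    expect_lte(pm$MAE, pm$RMSE + 1e-12)
  }
})

test_that("SSIM identities: perfect match, symmetry, anti-correlation", {
  set.seed(11)
  img <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(img, img), 1, tolerance = 1e-9)
  b <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(img, b), ssim(b, img), tolerance = 1e-12)
  # structured binary image vs its negative: anti-correlated structure
  bin <- matrix(as.numeric((row(matrix(0, 40, 40)) + col(matrix(0, 40, 40))) %% 7 < 3), 40, 40)
  expect_lt(ssim(1 - bin, bin, data_range = 1), 0)
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
  # 3D SSIM perfect match
  vol <- array(runif(16^3), c(16, 16, 16))
  expect_equal(ssim(vol, vol), 1, tolerance = 1e-9)
})

test_that("MS-SSIM is 1 at perfect match and drops under degradation", {
  set.seed(12)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ms_ssim(img, img), 1, tolerance = 1e-9)
  noisy <- img + rnorm(length(img), 0, 0.3)
  v <- ms_ssim(noisy, img, data_range = 1)
  expect_lt(v, 0.999)
  expect_gte(v, 0)
})

test_that("vector metrics: identities, affine relation, orthogonality, sentinels", {
  set.seed(13)
  img <- array(runif(5^3), c(5, 5, 5))
  vm <- vector_metrics(img, img)
  expect_equal(vm$COS, 1, tolerance = 1e-12)
  expect_equal(vm$CoC, 1, tolerance = 1e-12)
  # affine transform: correlation stays 1, cosine drops below 1
  vm2 <- vector_metrics(2 * img + 3, img)
  expect_equal(vm2$CoC, 1, tolerance = 1e-12)
  expect_lt(vm2$COS, 1)
  # orthogonal indicators
  a <- matrix(c(1, 0, 0, 0), 2, 2); b <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(vector_metrics(a, b)$COS, 0)
  w <- capture_warnings(z <- vector_metrics(matrix(0, 2, 2), a))
  expect_match(w, "zero vector", all = FALSE)
  expect_equal(z$COS, 0)
  expect_warning(cc <- vector_metrics(matrix(1, 2, 2), a), "constant")
  expect_equal(cc$CoC, 0)
})

test_that("FID: identity, closed-form Gaussian shift, symmetry, degenerate extractor", {
  ex <- feature_extractor_linear(function(img) img[1])
  set.seed(14)
  sams <- lapply(rnorm(400, 0, 1), function(v) matrix(v, 1, 1))
  samb <- lapply(rnorm(400, 2, 1), function(v) matrix(v, 1, 1))
  expect_lt(fid(sams, sams, ex), 1e-10)
  # univariate gaussians N(0,1) vs N(2,1): FID -> (2)^2 = 4
  v <- fid(sams, samb, ex)
  expect_lt(abs(v - 4), 0.8)  # sampling tolerance at n = 400
  expect_equal(fid(samb, sams, ex), v, tolerance = 1e-9)
  # constant extractor: 0 for any inputs
  exc <- feature_extractor_linear(function(img) 1)
  expect_equal(fid(sams[1:10], samb[1:10], exc), 0)
  expect_error(fid(sams[1], samb, ex), "at least 2")
})

test_that("default feature extractor is deterministic and fixed-dimension", {
  ex <- feature_extractor_default(n_features = 16, pool = 8, seed = 3)
  set.seed(15)
  img <- matrix(runif(32 * 32), 32, 32)
  f1 <- ex(img)
  ex2 <- feature_extractor_default(n_features = 16, pool = 8, seed = 3)
  expect_identical(f1, ex2(img))
  expect_length(ex2(matrix(runif(32 * 32), 32, 32)), length(f1))
})

test_that("foreground/background split metrics localize errors correctly", {
  set.seed(16)
  gt <- array(0.05, c(12, 12, 12))
  gt[4:8, 4:8, 4:8] <- 0.95
  sp0 <- fg_bg_metrics(gt, gt)
  expect_true(all(sp0$value[sp0$metric == "MSE"] == 0))
  # errors only in the foreground
  pred <- gt
  fg <- gt > 0.5
  pred[fg] <- pred[fg] + 0.2
  sp <- fg_bg_metrics(pred, gt)
  expect_equal(sp$value[sp$metric == "MSE" & sp$region == "bg"], 0)
  expect_gt(sp$value[sp$metric == "MSE" & sp$region == "fg"], 0)
  # constant gt: all background, fg entries absent
  spc <- suppressWarnings(fg_bg_metrics(gt * 0, gt * 0))
  expect_true(all(is.na(spc$value[spc$region == "fg"])))
})

test_that("block error heatmap localizes errors and decomposes the global MSE", {
  set.seed(17)
  gt <- matrix(runif(100 * 110), 100, 110)
  hm0 <- error_heatmap(gt, gt)
  expect_identical(dim(hm0), c(9L, 9L))
  expect_true(all(hm0 == 0))
  # inject an error wholly inside block (3, 5)
  pred <- gt
  e1 <- 100 %/% 9; e2 <- 110 %/% 9
  pred[(2 * e1 + 2):(2 * e1 + 4), (4 * e2 + 2):(4 * e2 + 4)] <- 5
  hm <- error_heatmap(pred, gt)
  expect_equal(sum(hm > 0), 1)
  expect_gt(hm[3, 5], 0)
  # size-weighted block MSE equals the global MSE
  n <- attr(hm, "n")
  expect_equal(sum(hm * n) / sum(n), mean((pred - gt)^2), tolerance = 1e-12)
  expect_equal(sum(n), length(gt))
  expect_error(error_heatmap(matrix(0, 5, 5), matrix(0, 5, 5)), "smaller")
})

test_that("cube-wise evaluation returns every metric per cube with exact recomputation", {
  set.seed(18)
  gt <- array(runif(64 * 32 * 32), c(64, 32, 32))
  pred <- gt + rnorm(length(gt), 0, 0.1)
  part <- partition_cubes(gt, 32)
  expect_equal(part$count, 2)
  rep <- evaluate_cubewise(pred, gt, part,
                           fid_extractor = feature_extractor_linear(function(i) c(mean(i), sd(i))))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("MSE", "MSLE", "MAE", "RMSE", "PSNR", "SSIM", "MS_SSIM",
                    "COS", "CoC", "FID") %in% names(rep)))
  # oracle recomputation of per-cube MSE on extracted sub-arrays
  for (ci in 1:2) {
    o <- part$origins[ci, ]
    sub_p <- pred[o[1]:(o[1] + 31), o[2]:(o[2] + 31), o[3]:(o[3] + 31)]
    sub_g <- gt[o[1]:(o[1] + 31), o[2]:(o[2] + 31), o[3]:(o[3] + 31)]
    expect_equal(rep$MSE[ci], mean((sub_p - sub_g)^2), tolerance = 1e-12)
  }
  # identical volumes: zeros and ones where they should be
  rep0 <- evaluate_cubewise(gt, gt, part, fid_extractor = FALSE)
  expect_true(all(rep0$MSE == 0))
  expect_equal(rep0$SSIM, rep(1, 2), tolerance = 1e-9)
  expect_equal(rep0$CoC, rep(1, 2), tolerance = 1e-9)
  # summary has the box-plot statistics per metric
  s <- summary(rep)
  expect_true(all(c("median", "q1", "q3", "min", "max") %in% names(s)))
  expect_true("MSE" %in% s$metric)
})
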