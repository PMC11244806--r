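# Training loop contracts: configuration validation, smoke runs,
# determinism, and optimizer behaviour. The heavier learning checks live
# in test-acceptance.R and share cached fitted models.

test_that("training configuration enforces its invariants", {
  cfg <- train_config()
  expect_equal(cfg$lr, 0.002)
  expect_equal(cfg$beta1, 0.5)
  expect_equal(cfg$batch_size, 1L)
  expect_equal(c(cfg$w_bg, cfg$w_fg), c(0.2, 0.8))
  expect_error(train_config(w_bg = 0.3, w_fg = 0.8), "equal 1")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr = -1), "lr")
})

test_that("a short unpaired run completes with finite losses and a full history", {
  ps <- inversion_patch_sets()
  a16 <- ps$A; a16$patches <- a16$patches[1:8]
  a16$source_ids <- a16$source_ids[1:8]; a16$coords <- a16$coords[1:8, ]
  b16 <- ps$B; b16$patches <- b16$patches[1:8]
  b16$source_ids <- b16$source_ids[1:8]; b16$coords <- b16$coords[1:8, ]
  fit <- train_unpaired(train_config(epochs = 2, seed = 31), a16, b16,
                        gen_spec = TEST_GEN_SPEC, disc_spec = TEST_DISC_SPEC,
                        dims = 2L)
  expect_s3_class(fit, "tg_cyclegan")
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(unlist(fit$history[, c("adv_G", "adv_D", "cycle_A",
                                                   "cycle_B", "total_G", "total_D")]))))
  expect_error(train_unpaired(train_config(epochs = 1), a16,
                              extract_patches_2d(ps$volume, 16, 4, seed = 1)),
               "incompatible patch shapes")
})

test_that("unpaired training is reproducible under a fixed seed", {
  ps <- inversion_patch_sets()
  a8 <- ps$A; a8$patches <- a8$patches[1:6]
  b8 <- ps$B; b8$patches <- b8$patches[1:6]
  f1 <- train_unpaired(train_config(epochs = 2, seed = 77), a8, b8,
                       gen_spec = TEST_GEN_SPEC, disc_spec = TEST_DISC_SPEC, dims = 2L)
  f2 <- train_unpaired(train_config(epochs = 2, seed = 77), a8, b8,
                       gen_spec = TEST_GEN_SPEC, disc_spec = TEST_DISC_SPEC, dims = 2L)
  expect_equal(f1$history$total_G, f2$history$total_G, tolerance = 1e-12)
  expect_equal(f1$history$total_D, f2$history$total_D, tolerance = 1e-12)
  x <- ps$hold$patches[[1]]
  expect_equal(net_forward(f1$G_AB, x), net_forward(f2$G_AB, x), tolerance = 1e-12)
})

test_that("per-epoch checkpoints are written and restore the generators", {
  dir <- withr::local_tempdir()
  ps <- inversion_patch_sets()
  a8 <- ps$A; a8$patches <- a8$patches[1:6]
  b8 <- ps$B; b8$patches <- b8$patches[1:6]
  fit <- train_unpaired(train_config(epochs = 2, seed = 5), a8, b8,
                        gen_spec = TEST_GEN_SPEC, disc_spec = TEST_DISC_SPEC,
                        dims = 2L, checkpoint_dir = dir)
  expect_true(file.exists(file.path(dir, "G_AB_epoch002.rds")))
  g <- load_checkpoint(file.path(dir, "G_AB_epoch002.rds"))
  x <- ps$hold$patches[[1]]
  expect_equal(net_forward(g, x), net_forward(fit$G_AB, x), tolerance = 1e-12)
})

test_that("paired training on the identity task reduces its loss", {
  ps <- inversion_patch_sets()
  setA <- ps$A; setA$patches <- setA$patches[1:10]
  setB <- setA  # identity task: B == A
  fit <- train_paired(train_config(epochs = 6, seed = 9, use_otsu_loss = FALSE),
                      setA, setB, dims = 2L, depth = 1L, base_filters = 4L)
  expect_s3_class(fit, "tg_paired")
  h <- fit$history$train_loss
  expect_true(all(is.finite(h)))
  # on average the loss decreases over the first epochs
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
})

test_that("early stopping halts after the patience window", {
  ps <- inversion_patch_sets()
  a6 <- ps$A; a6$patches <- a6$patches[1:4]
  b6 <- ps$B; b6$patches <- b6$patches[1:4]
  # a constant evaluation metric can never improve after epoch 1
  fit <- train_unpaired(train_config(epochs = 30, seed = 3,
                                     early_stop_patience = 2),
                        a6, b6, gen_spec = TEST_GEN_SPEC,
                        disc_spec = TEST_DISC_SPEC, dims = 2L,
                        eval_fn = function(G_AB, G_BA) 0.5)
  expect_lte(nrow(fit$history), 4)
})
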