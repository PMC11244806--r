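# Shared fixtures, built in code. Small sizes keep the default run fast;
# the training-based checks use the cached fixtures below so several tests
# can share one fitted model.

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- phantom_config(shape = c(48, 64, 64), n_cells = 10,
                            attenuation_depth = 40, seed = 5)
      cache <<- generate_phantom(cfg)
    }
    cache
  }
})

# A straight tube mask of given radius along the x axis.
straight_tube_mask <- function(shape = c(24, 24, 60), radius = 3,
                               margin = 3) {
  arr <- array(0, shape)
  mid <- shape[1:2] / 2
  tissuegan:::rasterize_tube(
    arr, rbind(c(mid[1], mid[2], margin), c(mid[1], mid[2], shape[3] - margin + 1)),
    radius, c(1, 1, 1)) == 1
}

# Reduced architecture strings used throughout the training tests. The
# down/up spec exercises the full block set; the residual-only spec is
# used for the inversion learning task, whose target map is pointwise.
TEST_GEN_SPEC <- "c7s1-8, d16, R16 (x2), u8, c7s1-1"
INV_GEN_SPEC <- "c7s1-12, R12 (x2), c7s1-1"
TEST_DISC_SPEC <- "C8, C16, F1"

# Membrane patches (domain A) and their analytic inversion (domain B):
# the translation target is known exactly, so recovery is measurable.
inversion_patch_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- small_phantom()
      mem <- normalize(as_volume(
        add_noise(ph$channels$membrane, 0.02, 0.01, seed = 9)))
      sA <- extract_patches_2d(mem, size = 32, n_per_image = 48, seed = 11,
                               domain = "A")
      sB <- extract_patches_2d(mem, size = 32, n_per_image = 48, seed = 12,
                               domain = "B")
      sB$patches <- lapply(sB$patches, function(p) -p)
      hold <- extract_patches_2d(mem, size = 32, n_per_image = 8, seed = 13,
                                 domain = "A")
      cache <<- list(A = sA, B = sB, hold = hold, volume = mem)
    }
    cache
  }
})

heldout_inversion_ssim <- function(G_AB, hold = inversion_patch_sets()$hold) {
  mean(vapply(hold$patches, function(a) {
    ssim(net_forward(G_AB, a), -a, data_range = 2)
  }, numeric(1)))
}

# One shared inversion-task fit per variant, trained lazily and cached so
# the learning tests and the acceptance checks reuse the same models.
trained_inversion_models <- local({
  cache <- list()
  function(variant = c("otsu", "plain", "paired")) {
    variant <- match.arg(variant)
    if (!is.null(cache[[variant]])) return(cache[[variant]])
    ps <- inversion_patch_sets()
    eval_unpaired <- function(G_AB, G_BA) heldout_inversion_ssim(G_AB, ps$hold)
    fit <- switch(variant,
      otsu = train_unpaired(
        train_config(epochs = 50, seed = 42, use_otsu_loss = TRUE,
                     lr_decay_from = 40),
        ps$A, ps$B, gen_spec = INV_GEN_SPEC, disc_spec = TEST_DISC_SPEC,
        dims = 2L, eval_fn = eval_unpaired),
      plain = train_unpaired(
        train_config(epochs = 50, seed = 43, use_otsu_loss = FALSE,
                     lr_decay_from = 40),
        ps$A, ps$B, gen_spec = INV_GEN_SPEC, disc_spec = TEST_DISC_SPEC,
        dims = 2L, eval_fn = eval_unpaired),
      paired = {
        pairedB <- ps$A
        pairedB$patches <- lapply(ps$A$patches, function(p) -p)
        pairedB$domain <- "B"
        train_paired(
          train_config(epochs = 10, seed = 44, use_otsu_loss = FALSE),
          ps$A, pairedB, dims = 2L, depth = 2L, base_filters = 8L,
          eval_fn = function(model) {
            mean(vapply(ps$hold$patches, function(a) {
              ssim(net_forward(model, a), -a, data_range = 2)
            }, numeric(1)))
          })
      })
    cache[[variant]] <<- fit
    fit
  }
})

# Deep-tissue emulation: BC channel attenuated at half depth, translation
# model trained on membrane patches vs shallow-region BC patches, then
# applied to the whole depth. Cached: trained once per session.
deep_tissue_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- phantom_config(shape = c(48, 64, 64), n_cells = 10,
                          attenuation_depth = 24, attenuation_width = 8,
                          seed = 5)
    ph <- generate_phantom(cfg)
    att <- apply_depth_attenuation(ph, "bc", depth = 24, width = 8)
    mem <- normalize(as_volume(ph$channels$membrane, name = "membrane"))
    bc_att <- normalize(as_volume(att$channels$bc, name = "bc"))
    shallowB <- as_volume(bc_att$data[1:16, , ], name = "bc_shallow")
    dA <- extract_patches_2d(mem, size = 32, n_per_image = 24, seed = 41,
                             domain = "A")
    dB <- extract_patches_2d(shallowB, size = 32, n_per_image = 24, seed = 42,
                             domain = "B")
    fit <- train_unpaired(train_config(epochs = 15, seed = 43,
                                       use_otsu_loss = TRUE),
                          dA, dB, gen_spec = TEST_GEN_SPEC,
                          disc_spec = TEST_DISC_SPEC, dims = 2L)
    pred <- predict_volume(fit$G_AB, mem, tiling_plan(32L, 0.5))
    pred$norm <- bc_att$norm
    pred_dn <- denormalize(pred)
    prof_exp <- depth_profile(as_volume(att$channels$bc), channel = "experimental")
    prof_pred <- depth_profile(pred_dn, channel = "predicted")
    shallow <- function(p) mean(p$mean_intensity[p$z_um <= 16])
    deep <- function(p) mean(p$mean_intensity[p$z_um >= 36])
    cache <<- list(
      fit = fit, prof_exp = prof_exp, prof_pred = prof_pred,
      experimental_retention = deep(prof_exp) / shallow(prof_exp),
      predicted_retention = deep(prof_pred) / shallow(prof_pred)
    )
    cache
  }
})
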