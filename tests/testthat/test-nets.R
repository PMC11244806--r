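# Architecture parsing, network construction, shape contracts, parameter
# counts against analytic oracles, and backprop correctness.

test_that("the reference generator and discriminator specs parse to the printed layouts", {
  g128 <- parse_arch_spec("c7s1-64, d128, d256, R256 (x6), u128, u64, c7s1-1")
  expect_equal(nrow(g128$tokens), 12)  # 1 + 2 + 6 + 2 + 1
  expect_equal(g128$tokens$kind,
               c("c7s1", "d", "d", rep("R", 6), "u", "u", "c7s1"))
  expect_equal(g128$tokens$k[1:3], c(64L, 128L, 256L))
  g256 <- parse_arch_spec("c7s1-64, d128, d256, R256 (x9), u128, u64, c7s1-1")
  expect_equal(sum(g256$tokens$kind == "R"), 9)
  # the discriminator string as printed, including unicode hyphens
  d <- parse_arch_spec("C64 ‐ C128 ‐ C256 ‐ C512 ‐ F1")
  expect_equal(nrow(d$tokens), 5)
  expect_equal(d$tokens$kind, c("C", "C", "C", "C", "F"))
  expect_equal(d$tokens$k, c(64L, 128L, 256L, 512L, 1L))
  # round trip through the formatter
  expect_equal(format_arch_spec(g128),
               "c7s1-64, d128, d256, R256 (x6), u128, u64, c7s1-1")
  expect_error(parse_arch_spec("c7s1-64, x9q"), "unknown architecture token")
})

test_that("generator parameter counts match the analytic per-layer formula", {
  # conv: k^dims * in * out + out biases; IN affine: 2 * out (skipped on the
  # tanh output layer); residual: two convs + two INs.
  count_spec <- function(spec, dims) {
    toks <- parse_arch_spec(spec, dims)$tokens
    kpow <- function(k) k^dims
    total <- 0; ch <- 1
    for (i in seq_len(nrow(toks))) {
      k <- toks$k[i]; kind <- toks$kind[i]; last <- i == nrow(toks)
      total <- total + switch(kind,
        c7s1 = kpow(7) * ch * k + k + if (last) 0 else 2 * k,
        d = kpow(3) * ch * k + k + 2 * k,
        R = 2 * (kpow(3) * ch * ch + ch) + 2 * (2 * ch),
        u = kpow(3) * ch * k + k + 2 * k)
      if (kind != "R") ch <- k
    }
    total
  }
  for (dims in c(2L, 3L)) {
    for (spec in c("c7s1-2, d4, R4 (x1), u2, c7s1-1",
                   "c7s1-4, d8, d16, R16 (x2), u8, u4, c7s1-1",
                   "c7s1-3, R3 (x2), c7s1-1")) {
      net <- build_generator(parse_arch_spec(spec, dims, 1L, 1L), seed = 1)
      expect_equal(count_params(net), count_spec(spec, dims),
                   info = paste(spec, dims))
    }
  }
})

test_that("generators preserve spatial shape in 2D and 3D and bound outputs", {
  g2 <- build_generator(parse_arch_spec(TEST_GEN_SPEC, 2L, 1L, 1L), seed = 2)
  x2 <- matrix(runif(128 * 128, -1, 1), 128, 128)
  y2 <- net_forward(g2, x2)
  expect_identical(dim(y2), dim(x2))
  expect_true(all(abs(y2) <= 1))
  g3 <- build_generator(parse_arch_spec("c7s1-4, d8, d8, R8 (x1), u8, u4, c7s1-1",
                                        3L, 1L, 1L), seed = 3)
  x3 <- array(runif(24^3, -1, 1), c(24, 24, 24))
  expect_identical(dim(net_forward(g3, x3)), dim(x3))
  # inputs not divisible by the downsampling factor are rejected
  expect_error(net_forward(g2, matrix(0, 31, 31)), "divisible")
})

test_that("2D and 3D builders produce the same layer sequence, differing only in kernel rank", {
  spec2 <- parse_arch_spec(TEST_GEN_SPEC, 2L, 1L, 1L)
  spec3 <- parse_arch_spec(TEST_GEN_SPEC, 3L, 1L, 1L)
  g2 <- build_generator(spec2, seed = 1)
  g3 <- build_generator(spec3, seed = 1)
  expect_equal(length(g2$layers), length(g3$layers))
  for (i in seq_along(g2$layers)) {
    expect_identical(g2$layers[[i]]$kind, g3$layers[[i]]$kind)
    w2 <- if (g2$layers[[i]]$kind == "residual") g2$layers[[i]]$conv1$pars$W else g2$layers[[i]]$pars$W
    w3 <- if (g3$layers[[i]]$kind == "residual") g3$layers[[i]]$conv1$pars$W else g3$layers[[i]]$pars$W
    expect_identical(dim(w2)[2:5], dim(w3)[2:5])  # same k, channels
    expect_identical(dim(w2)[1], 1L)              # 2D kernels are depth-1
    expect_identical(dim(w3)[1], dim(w3)[2])      # 3D kernels are cubic
  }
})

test_that("discriminator output is a spatially reduced one-channel score map", {
  d <- build_discriminator(parse_arch_spec("C64, C128, C256, C512, F1",
                                           2L, 1L, 1L), seed = 4)
  x <- matrix(runif(128 * 128, -1, 1), 128, 128)
  s <- net_forward(d, x)
  # shape recurrence: four 4x4 stride-2 pad-1 convs then one stride-1
  sz <- 128
  for (i in 1:4) sz <- floor((sz + 2 - 4) / 2) + 1
  sz <- floor((sz + 2 - 4) / 1) + 1
  expect_identical(dim(s), as.integer(c(sz, sz)))
  expect_lt(prod(dim(s)), prod(dim(x)))
  d3 <- build_discriminator(parse_arch_spec(TEST_DISC_SPEC, 3L, 1L, 1L), seed = 5)
  s3 <- net_forward(d3, array(runif(32^3), c(32, 32, 32)))
  expect_length(dim(s3), 3)
  expect_error(build_discriminator(parse_arch_spec("C8, C16", 2L)), "end with F1")
  expect_error(net_forward(d, matrix(0, 4, 4)), "too small")
})

test_that("UNet is shape-preserving with doubling skip concatenations and oracle parameter count", {
  u <- build_unet(2L, 1L, 1L, depth = 2L, base_filters = 4L, seed = 6)
  x <- matrix(runif(32 * 32, -1, 1), 32, 32)
  y <- net_forward(u, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))
  # decoder convs see 2 * level_filters input channels (skip concatenation)
  for (i in seq_len(u$unet$depth)) {
    enc_out <- dim(u$unet$enc[[i]]$pars$W)[5]
    dec_in <- dim(u$unet$dec[[i]]$pars$W)[4]
    expect_identical(dec_in, 2L * enc_out)
  }
  expect_error(net_forward(u, matrix(0, 30, 30)), "divisible")
  # depth-1, base-2 parameter count by hand:
  # enc 3x3 1->2 (+IN), down 3x3 2->4 (+IN), bottom 3x3 4->4 (+IN),
  # up tconv 3x3 4->2 (+IN), dec 3x3 4->2 (+IN), final 3x3 2->1 (no IN)
  u1 <- build_unet(2L, 1L, 1L, depth = 1L, base_filters = 2L, seed = 7)
  hand <- (9 * 1 * 2 + 2 + 4) + (9 * 2 * 4 + 4 + 8) + (9 * 4 * 4 + 4 + 8) +
    (9 * 4 * 2 + 2 + 4) + (9 * 4 * 2 + 2 + 4) + (9 * 2 * 1 + 1)
  expect_equal(count_params(u1), hand)
})

test_that("backpropagation matches central finite differences on tiny nets", {
  run_check <- function(net, x) {
    M <- array(rnorm(length(net_forward(net, x))), dim(net_forward(net, x)))
    tissuegan:::zero_grads(net)
    net_forward(net, x, train = TRUE)
    tissuegan:::net_backward(net, M)
    eps <- 1e-6
    worst <- 0
    for (l in tissuegan:::net_layer_envs(net)) {
      for (nm in names(l$pars)) {
        idx <- 1L
        p0 <- l$pars[[nm]][idx]
        l$pars[[nm]][idx] <- p0 + eps
        yp <- net_forward(net, x)
        l$pars[[nm]][idx] <- p0 - eps
        ym <- net_forward(net, x)
        l$pars[[nm]][idx] <- p0
        num <- sum((yp - ym) * M) / (2 * eps)
        ana <- l$grads[[nm]][idx]
        worst <- max(worst, abs(num - ana) / max(1, abs(num)))
      }
    }
    worst
  }
  set.seed(8)
  g <- build_generator(parse_arch_spec("c7s1-2, d4, R4 (x1), u2, c7s1-1", 2L, 1L, 1L))
  expect_lt(run_check(g, matrix(runif(256, -1, 1), 16, 16)), 1e-4)
  d <- build_discriminator(parse_arch_spec("C4, F1", 2L, 1L, 1L))
  expect_lt(run_check(d, matrix(runif(256, -1, 1), 16, 16)), 1e-4)
  u <- build_unet(2L, 1L, 1L, depth = 1L, base_filters = 2L)
  expect_lt(run_check(u, matrix(runif(256, -1, 1), 16, 16)), 1e-4)
})

test_that("checkpoints are self-describing and restore forward behaviour exactly", {
  dir <- withr::local_tempdir()
  g <- build_generator(parse_arch_spec(TEST_GEN_SPEC, 2L, 1L, 1L), seed = 9)
  x <- matrix(runif(32 * 32, -1, 1), 32, 32)
  y <- net_forward(g, x)
  p <- file.path(dir, "g.rds")
  save_checkpoint(g, p)
  g2 <- load_checkpoint(p)
  expect_identical(g2$spec$source, TEST_GEN_SPEC)
  expect_equal(net_forward(g2, x), y, tolerance = 1e-12)
  u <- build_unet(2L, 1L, 1L, depth = 1L, base_filters = 2L, seed = 10)
  save_checkpoint(u, file.path(dir, "u.rds"))
  expect_equal(net_forward(load_checkpoint(file.path(dir, "u.rds")), x),
               net_forward(u, x), tolerance = 1e-12)
})
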