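#' Parse a network architecture token string
#'
#' Parses the compact layer notation used to describe the translation
#' networks: `c7s1-k` (7x7 stride-1 convolution with k filters, instance
#' norm, ReLU), `dk` (3x3 stride-2 down-convolution), `Rk` or `Rk (xm)`
#' (residual blocks with two 3x3 convolutions, expanded to m blocks), `uk`
#' (3x3 stride-2 transposed convolution), `Ck` (4x4 discriminator block,
#' instance norm, LeakyReLU), and `F1` (final 4x4 convolution to a 1-channel
#' score map). Tokens are separated by commas or hyphens between blocks.
#'
#' @param spec_string The token string, e.g.
#'   `"c7s1-64, d128, d256, R256 (x6), u128, u64, c7s1-1"`.
#' @param dims 2 or 3 (2D or 3D convolutions).
#' @param in_ch,out_ch Input/output channel counts.
#' @return A `tg_arch_spec` with the expanded token table.
#' @export
parse_arch_spec <- function(spec_string, dims = 2L, in_ch = 1L, out_ch = 1L) {
  stopifnot(is.character(spec_string), nzchar(spec_string), dims %in% c(2L, 3L))
  norm <- gsub("‐|‑|‒|–", ",", spec_string)
  norm <- gsub("\\s+-\\s+", ",", norm)  # " - " separators, not "c7s1-64"
  raw <- trimws(strsplit(norm, ",")[[1]])
  raw <- raw[nzchar(raw)]
  tokens <- list()
  for (i in seq_along(raw)) {
    t <- raw[i]
    m <- regmatches(t, regexec("^c7s1[-]?([0-9]+)$", t))[[1]]
    if (length(m)) { tokens[[length(tokens) + 1]] <- list(kind = "c7s1", k = as.integer(m[2])); next }
    m <- regmatches(t, regexec("^d([0-9]+)$", t))[[1]]
    if (length(m)) { tokens[[length(tokens) + 1]] <- list(kind = "d", k = as.integer(m[2])); next }
    m <- regmatches(t, regexec("^R([0-9]+)\\s*(\\(x([0-9]+)\\))?$", t))[[1]]
    if (length(m)) {
      reps <- if (nzchar(m[4])) as.integer(m[4]) else 1L
      for (r in seq_len(reps)) tokens[[length(tokens) + 1]] <- list(kind = "R", k = as.integer(m[2]))
      next
    }
    m <- regmatches(t, regexec("^u([0-9]+)$", t))[[1]]
    if (length(m)) { tokens[[length(tokens) + 1]] <- list(kind = "u", k = as.integer(m[2])); next }
    m <- regmatches(t, regexec("^C([0-9]+)$", t))[[1]]
    if (length(m)) { tokens[[length(tokens) + 1]] <- list(kind = "C", k = as.integer(m[2])); next }
    m <- regmatches(t, regexec("^F([0-9]+)$", t))[[1]]
    if (length(m)) { tokens[[length(tokens) + 1]] <- list(kind = "F", k = as.integer(m[2])); next }
    stop("unknown architecture token '", t, "' at position ", i)
  }
  toks <- data.frame(kind = vapply(tokens, `[[`, "", "kind"),
                     k = vapply(tokens, `[[`, 0L, "k"))
  structure(list(tokens = toks, dims = as.integer(dims),
                 in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 source = spec_string),
            class = "tg_arch_spec")
}

#' @export
print.tg_arch_spec <- function(x, ...) {
  cat("<tg_arch_spec> ", nrow(x$tokens), " layers (", x$dims, "D, ",
      x$in_ch, " -> ", x$out_ch, " ch): ", format_arch_spec(x), "\n", sep = "")
  invisible(x)
}

#' Format an architecture spec back to its compact string
#' @param spec A `tg_arch_spec`.
#' @return A single string; consecutive identical residual blocks collapse
#'   to `Rk (xm)`.
#' @export
format_arch_spec <- function(spec) {
  toks <- spec$tokens
  out <- character(0)
  i <- 1
  while (i <= nrow(toks)) {
    kind <- toks$kind[i]; k <- toks$k[i]
    if (kind == "R") {
      j <- i
      while (j < nrow(toks) && toks$kind[j + 1] == "R" && toks$k[j + 1] == k) j <- j + 1
      reps <- j - i + 1
      out <- c(out, if (reps > 1) sprintf("R%d (x%d)", k, reps) else sprintf("R%d", k))
      i <- j + 1
    } else {
      out <- c(out, switch(kind,
        c7s1 = sprintf("c7s1-%d", k), d = sprintf("d%d", k),
        u = sprintf("u%d", k), C = sprintf("C%d", k), F = sprintf("F%d", k)))
      i <- i + 1
    }
  }
  paste(out, collapse = ", ")
}

new_network <- function(kind, dims, layers, spec = NULL, down_factor = 1L,
                        extra = list()) {
  net <- new.env(parent = emptyenv())
  net$kind <- kind
  net$dims <- as.integer(dims)
  net$layers <- layers
  net$spec <- spec
  net$down_factor <- as.integer(down_factor)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = net)
  class(net) <- "tg_network"
  net
}

#' @export
print.tg_network <- function(x, ...) {
  cat("<tg_network> ", x$kind, ", ", x$dims, "D, ",
      length(x$layers), " blocks, ", count_params(x), " parameters\n", sep = "")
  if (!is.null(x$spec)) cat("  spec: ", format_arch_spec(x$spec), "\n", sep = "")
  invisible(x)
}

#' Build a residual translation generator from its architecture spec
#'
#' Instantiates the generator described by a token spec: a 7x7 stem,
#' stride-2 down-convolutions, a stack of residual blocks, stride-2
#' transposed convolutions back to full resolution, and a final 7x7
#' convolution with a tanh activation bounding outputs to `[-1, 1]` (the
#' normalization range of the training data). Convolutions use reflection
#' padding, so the generator preserves spatial shape for any input whose
#' edges are multiples of the total downsampling factor.
#'
#' @param spec A `tg_arch_spec` (or a string, parsed with defaults).
#' @param seed Seed for weight initialization.
#' @return A `tg_network`.
#' @export
build_generator <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- parse_arch_spec(spec)
  stopifnot(inherits(spec, "tg_arch_spec"))
  if (!is.null(seed)) set.seed(seed)
  dims <- spec$dims
  layers <- list()
  ch <- spec$in_ch
  n <- nrow(spec$tokens)
  n_down <- 0L
  for (i in seq_len(n)) {
    kind <- spec$tokens$kind[i]; k <- spec$tokens$k[i]
    last <- i == n
    if (kind == "c7s1") {
      out_ch <- if (last) spec$out_ch else k
      layers[[i]] <- layer_conv(dims, 7L, ch, out_ch, 1L, "reflect",
                                norm = !last, act = if (last) "tanh" else "relu")
      ch <- out_ch
    } else if (kind == "d") {
      layers[[i]] <- layer_conv(dims, 3L, ch, k, 2L, "reflect", TRUE, "relu")
      ch <- k
      n_down <- n_down + 1L
    } else if (kind == "R") {
      if (k != ch) stop("residual block R", k, " does not match current width ", ch)
      layers[[i]] <- layer_residual(dims, ch)
    } else if (kind == "u") {
      layers[[i]] <- layer_tconv(dims, 3L, ch, k, 2L, TRUE, "relu")
      ch <- k
    } else {
      stop("token '", kind, k, "' is not valid in a generator spec")
    }
  }
  new_network("generator", dims, layers, spec, down_factor = 2L^n_down)
}

#' Build a patch discriminator from its architecture spec
#'
#' Instantiates the patch-wise discriminator: a chain of 4x4 stride-2
#' convolution blocks with instance normalization and LeakyReLU (0.2),
#' closed by a stride-1 4x4 convolution to a one-channel real/fake score
#' map that is spatially smaller than the input.
#'
#' @param spec A `tg_arch_spec` ending in `F1` (or a string).
#' @param norm_first Apply instance normalization to the first C block too
#'   (the literal reading of the architecture description; set `FALSE` for
#'   the family's conventional variant that skips it).
#' @param seed Seed for weight initialization.
#' @return A `tg_network` producing score maps.
#' @export
build_discriminator <- function(spec, norm_first = TRUE, seed = NULL) {
  if (is.character(spec)) spec <- parse_arch_spec(spec)
  stopifnot(inherits(spec, "tg_arch_spec"))
  if (!is.null(seed)) set.seed(seed)
  toks <- spec$tokens
  if (toks$kind[nrow(toks)] != "F") stop("discriminator spec must end with F1")
  dims <- spec$dims
  layers <- list()
  ch <- spec$in_ch
  for (i in seq_len(nrow(toks))) {
    kind <- toks$kind[i]; k <- toks$k[i]
    if (kind == "C") {
      layers[[i]] <- layer_conv(dims, 4L, ch, k, 2L, "zero",
                                norm = if (i == 1) norm_first else TRUE,
                                act = "lrelu", pad = 1L)
      ch <- k
    } else if (kind == "F") {
      layers[[i]] <- layer_conv(dims, 4L, ch, k, 1L, "zero",
                                norm = FALSE, act = "none", pad = 1L)
      ch <- k
    } else {
      stop("token '", kind, k, "' is not valid in a discriminator spec")
    }
  }
  new_network("discriminator", dims, layers, spec)
}

#' Build a UNet for paired (supervised) translation
#'
#' A shape-preserving encoder-decoder with skip connections: each level has
#' a 3x3 convolution block followed by a stride-2 down-convolution, the
#' decoder mirrors it with transposed convolutions, and each decoder level
#' concatenates the matching encoder features (doubling its input
#' channels). Instance normalization throughout; final tanh. Input edges
#' must be divisible by `2^depth`.
#'
#' @param dims 2 or 3.
#' @param in_ch,out_ch Channel counts.
#' @param depth Number of down/up levels (default 4).
#' @param base_filters Filters at the top level (default 64), doubling per
#'   level.
#' @param seed Seed for weight initialization.
#' @return A `tg_network` of kind `"unet"`.
#' @export
build_unet <- function(dims = 2L, in_ch = 1L, out_ch = 1L, depth = 4L,
                       base_filters = 64L, seed = NULL) {
  stopifnot(depth >= 1, base_filters >= 1, dims %in% c(2L, 3L))
  if (!is.null(seed)) set.seed(seed)
  f <- base_filters * 2L^(seq_len(depth + 1L) - 1L)
  enc <- vector("list", depth)
  down <- vector("list", depth)
  up <- vector("list", depth)
  dec <- vector("list", depth)
  ch <- in_ch
  for (i in seq_len(depth)) {
    enc[[i]] <- layer_conv(dims, 3L, ch, f[i], 1L, "reflect", TRUE, "relu")
    down[[i]] <- layer_conv(dims, 3L, f[i], f[i + 1L], 2L, "reflect", TRUE, "relu")
    ch <- f[i + 1L]
  }
  bottom <- layer_conv(dims, 3L, f[depth + 1L], f[depth + 1L], 1L, "reflect",
                       TRUE, "relu")
  for (i in rev(seq_len(depth))) {
    up[[i]] <- layer_tconv(dims, 3L, f[i + 1L], f[i], 2L, TRUE, "relu")
    dec[[i]] <- layer_conv(dims, 3L, 2L * f[i], f[i], 1L, "reflect", TRUE, "relu")
  }
  final <- layer_conv(dims, 3L, f[1L], out_ch, 1L, "reflect", FALSE, "tanh")
  layers <- c(enc, down, list(bottom), up, dec, list(final))
  new_network("unet", dims, layers, NULL, down_factor = 2L^depth,
              extra = list(unet = list(enc = enc, down = down, bottom = bottom,
                                       up = up, dec = dec, final = final,
                                       depth = depth)))
}

check_divisible <- function(x, net) {
  d <- dim(x)
  sp <- if (net$dims == 2) d[2:3] else d[1:3]
  if (any(sp %% net$down_factor != 0)) {
    stop("input spatial shape (", paste(sp, collapse = "x"),
         ") must be divisible by ", net$down_factor)
  }
}

#' Run a network forward
#'
#' @param net A `tg_network`.
#' @param x Input image: a 2D matrix, 3D array, or (spatial..., channel)
#'   array matching the network's dimensionality.
#' @param train Keep caches for a subsequent backward pass.
#' @return The output image (generators/UNet: same spatial shape;
#'   discriminators: a smaller score map).
#' @export
net_forward <- function(net, x, train = FALSE) {
  x <- as_net_tensor(x, net$dims)
  if (net$down_factor > 1L) check_divisible(x, net)
  y <- if (net$kind == "unet") unet_forward(net, x, train) else {
    h <- x
    for (l in net$layers) h <- layer_forward(l, h, train)
    h
  }
  if (!all(is.finite(y))) stop("non-finite activation in ", net$kind, " forward pass")
  from_net_tensor(y, net$dims)
}

net_backward <- function(net, gy) {
  gy <- as_net_tensor(gy, net$dims)
  g <- if (net$kind == "unet") unet_backward(net, gy) else {
    h <- gy
    for (l in rev(net$layers)) h <- layer_backward(l, h)
    h
  }
  from_net_tensor(g, net$dims)
}

unet_forward <- function(net, x, train) {
  u <- net$unet
  skips <- vector("list", u$depth)
  h <- x
  for (i in seq_len(u$depth)) {
    h <- layer_forward(u$enc[[i]], h, train)
    skips[[i]] <- h
    h <- layer_forward(u$down[[i]], h, train)
  }
  h <- layer_forward(u$bottom, h, train)
  for (i in rev(seq_len(u$depth))) {
    h <- layer_forward(u$up[[i]], h, train)
    d <- dim(h)
    cat_in <- array(0, c(d[1:3], d[4] + dim(skips[[i]])[4]))
    cat_in[, , , seq_len(dim(skips[[i]])[4])] <- skips[[i]]
    cat_in[, , , dim(skips[[i]])[4] + seq_len(d[4])] <- h
    h <- layer_forward(u$dec[[i]], cat_in, train)
  }
  layer_forward(u$final, h, train)
}

unet_backward <- function(net, gy) {
  u <- net$unet
  g <- layer_backward(u$final, gy)
  gskips <- vector("list", u$depth)
  for (i in seq_len(u$depth)) {
    gcat <- layer_backward(u$dec[[i]], g)
    d4 <- dim(gcat)[4]
    nskip <- d4 %/% 2L
    gskips[[i]] <- gcat[, , , seq_len(nskip), drop = FALSE]
    gup <- gcat[, , , nskip + seq_len(d4 - nskip), drop = FALSE]
    g <- layer_backward(u$up[[i]], gup)
  }
  g <- layer_backward(u$bottom, g)
  for (i in rev(seq_len(u$depth))) {
    g <- layer_backward(u$down[[i]], g)
    g <- g + gskips[[i]]
    g <- layer_backward(u$enc[[i]], g)
  }
  g
}

net_layer_envs <- function(net) {
  unlist(lapply(net$layers, layer_param_envs), recursive = FALSE)
}

#' Count trainable parameters
#' @param net A `tg_network`.
#' @return Integer parameter count (weights, biases, norm affines).
#' @export
count_params <- function(net) {
  sum(vapply(net$layers, layer_n_params, numeric(1)))
}

zero_grads <- function(net) {
  for (l in net$layers) zero_grads_layer(l)
  invisible(net)
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint embeds the architecture spec string (or UNet
#' hyperparameters) with the parameter arrays, so it can be restored
#' without outside knowledge.
#'
#' @param net A `tg_network`.
#' @param path Destination file.
#' @return `path` invisibly; `load_checkpoint()` returns the rebuilt network.
#' @export
save_checkpoint <- function(net, path) {
  envs <- net_layer_envs(net)
  pars <- lapply(envs, function(e) e$pars)
  meta <- list(kind = net$kind, dims = net$dims,
               spec = if (!is.null(net$spec)) net$spec$source else NULL,
               spec_in = if (!is.null(net$spec)) net$spec$in_ch else NULL,
               spec_out = if (!is.null(net$spec)) net$spec$out_ch else NULL,
               unet = if (net$kind == "unet")
                 list(depth = net$unet$depth,
                      in_ch = dim(net$unet$enc[[1]]$pars$W)[4],
                      out_ch = dim(net$unet$final$pars$W)[5],
                      base = dim(net$unet$enc[[1]]$pars$W)[5]) else NULL)
  saveRDS(list(meta = meta, pars = pars), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- ck$meta
  net <- if (m$kind == "generator") {
    build_generator(parse_arch_spec(m$spec, m$dims, m$spec_in, m$spec_out))
  } else if (m$kind == "discriminator") {
    build_discriminator(parse_arch_spec(m$spec, m$dims, m$spec_in, m$spec_out))
  } else {
    build_unet(m$dims, m$unet$in_ch, m$unet$out_ch, m$unet$depth, m$unet$base)
  }
  envs <- net_layer_envs(net)
  stopifnot(length(envs) == length(ck$pars))
  for (i in seq_along(envs)) envs[[i]]$pars <- ck$pars[[i]]
  net
}
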