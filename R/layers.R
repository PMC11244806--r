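# Minimal define-by-layer neural network framework on dense R arrays.
#
# Tensors are rank-4 arrays with dims (D, H, W, C); 2D data has D == 1.
# Batch size is fixed at 1 (the training protocol's setting), so there is
# no batch axis. Layers are environments carrying parameters, gradient
# accumulators and Adam state; the convolution kernels live in C++.

TG_INIT_SD <- 0.02  # weight init SD, the convention of this GAN family

as_net_tensor <- function(x, dims) {
  # promote a 2D/3D image (or (spatial..., C) array) to (D, H, W, C)
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (dims == 2) {
    if (length(d) == 2) dim(x) <- c(1L, d, 1L)
    else if (length(d) == 3) dim(x) <- c(1L, d)  # (H, W, C)
    else if (length(d) != 4) stop("bad 2D input rank")
  } else {
    if (length(d) == 3) dim(x) <- c(d, 1L)
    else if (length(d) != 4) stop("bad 3D input rank")
  }
  x
}

from_net_tensor <- function(y, dims) {
  d <- dim(y)
  if (d[4] == 1L) {
    if (dims == 2) matrix(y, d[2], d[3]) else array(y, d[1:3])
  } else {
    if (dims == 2) array(y, d[2:4]) else y
  }
}

pad_map <- function(n, p, mode) {
  if (p == 0) return(seq_len(n))
  left <- switch(mode,
    reflect = rev(seq_len(p)) + 1L,
    replicate = rep.int(1L, p),
    zero = rep.int(NA_integer_, p))
  right <- switch(mode,
    reflect = n - seq_len(p),
    replicate = rep.int(n, p),
    zero = rep.int(NA_integer_, p))
  if (mode == "reflect" && n <= p) stop("image too small for reflection padding")
  c(left, seq_len(n), right)
}

pad_spatial <- function(x, p3, mode) {
  if (all(p3 == 0)) return(x)
  d <- dim(x)
  m1 <- pad_map(d[1], p3[1], mode)
  m2 <- pad_map(d[2], p3[2], mode)
  m3 <- pad_map(d[3], p3[3], mode)
  if (mode == "zero") {
    out <- array(0, c(length(m1), length(m2), length(m3), d[4]))
    out[p3[1] + seq_len(d[1]), p3[2] + seq_len(d[2]), p3[3] + seq_len(d[3]), ] <- x
    out
  } else {
    x[m1, m2, m3, , drop = FALSE]
  }
}

unpad_fold <- function(g, p3, mode) {
  # adjoint of pad_spatial: fold pad-region gradients back onto their sources
  for (axis in 1:3) {
    p <- p3[axis]
    if (p == 0) next
    d <- dim(g)
    n <- d[axis] - 2L * p
    core_idx <- p + seq_len(n)
    sel <- function(i) switch(axis,
      g[i, , , , drop = FALSE], g[, i, , , drop = FALSE], g[, , i, , drop = FALSE])
    core <- sel(core_idx)
    if (mode != "zero") {
      map <- pad_map(n, p, mode)
      add_at <- function(core, src, slab) {
        switch(axis,
          { core[src, , , ] <- core[src, , , , drop = FALSE] + slab; core },
          { core[, src, , ] <- core[, src, , , drop = FALSE] + slab; core },
          { core[, , src, ] <- core[, , src, , drop = FALSE] + slab; core })
      }
      for (j in seq_len(p)) core <- add_at(core, map[j], sel(j))
      for (j in seq_len(p)) {
        jj <- n + p + j
        core <- add_at(core, map[jj], sel(jj))
      }
    }
    g <- core
  }
  g
}

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$pars <- list()
  e$grads <- list()
  e$opt <- list()
  e$cache <- NULL
  meta <- list(...)
  for (nm in names(meta)) assign(nm, meta[[nm]], envir = e)
  e
}

init_weight <- function(dims) array(rnorm(prod(dims), 0, TG_INIT_SD), dims)

# A convolution block: pad -> conv -> [instance norm] -> [activation].
layer_conv <- function(dims, k, in_ch, out_ch, stride = 1L,
                       pad_mode = "reflect", norm = TRUE, act = "relu",
                       pad = NULL) {
  kd <- if (dims == 3) k else 1L
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  pd <- if (dims == 3) pad else 0L
  l <- new_layer("conv", dims = dims, k = k, in_ch = in_ch, out_ch = out_ch,
                 stride3 = c(if (dims == 3) stride else 1L, stride, stride),
                 pad3 = c(pd, pad, pad), pad_mode = pad_mode,
                 norm = norm, act = act)
  l$pars$W <- init_weight(c(kd, k, k, in_ch, out_ch))
  l$pars$b <- numeric(out_ch)
  if (norm) {
    l$pars$gamma <- rep(1, out_ch)
    l$pars$beta <- numeric(out_ch)
  }
  l
}

# A transposed-convolution block (stride-2 learned upsampling, k = 3,
# pad = 1, output padding = 1, so spatial size exactly doubles).
layer_tconv <- function(dims, k, in_ch, out_ch, stride = 2L,
                        norm = TRUE, act = "relu") {
  kd <- if (dims == 3) k else 1L
  p <- (k - 1L) %/% 2L
  l <- new_layer("tconv", dims = dims, k = k, in_ch = in_ch, out_ch = out_ch,
                 stride3 = c(if (dims == 3) stride else 1L, stride, stride),
                 pad3 = c(if (dims == 3) p else 0L, p, p),
                 opad3 = c(if (dims == 3) stride - 1L else 0L,
                           stride - 1L, stride - 1L),
                 norm = norm, act = act)
  l$pars$W <- init_weight(c(kd, k, k, in_ch, out_ch))
  l$pars$b <- numeric(out_ch)
  if (norm) {
    l$pars$gamma <- rep(1, out_ch)
    l$pars$beta <- numeric(out_ch)
  }
  l
}

# Residual block: x + (conv-IN-ReLU -> conv-IN)(x), the classic layout.
layer_residual <- function(dims, ch, pad_mode = "reflect") {
  l <- new_layer("residual", dims = dims, ch = ch)
  l$conv1 <- layer_conv(dims, 3L, ch, ch, 1L, pad_mode, norm = TRUE, act = "relu")
  l$conv2 <- layer_conv(dims, 3L, ch, ch, 1L, pad_mode, norm = TRUE, act = "none")
  l
}

instance_norm_fw <- function(l, z) {
  d <- dim(z)
  npix <- prod(d[1:3])
  zm <- z; dim(zm) <- c(npix, d[4])
  mu <- colMeans(zm)
  zc <- sweep(zm, 2, mu)
  sdv <- sqrt(colMeans(zc^2) + 1e-5)
  xhat <- sweep(zc, 2, sdv, "/")
  y <- sweep(sweep(xhat, 2, l$pars$gamma, "*"), 2, l$pars$beta, "+")
  l$cache$in_xhat <- xhat
  l$cache$in_sd <- sdv
  dim(y) <- d
  y
}

instance_norm_bw <- function(l, gy) {
  d <- dim(gy)
  npix <- prod(d[1:3])
  gm <- gy; dim(gm) <- c(npix, d[4])
  xhat <- l$cache$in_xhat
  l$grads$gamma <- l$grads$gamma + colSums(gm * xhat)
  l$grads$beta <- l$grads$beta + colSums(gm)
  dxh <- sweep(gm, 2, l$pars$gamma, "*")
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(xhat, 2, colMeans(dxh * xhat), "*")
  gx <- sweep(t1 - t2, 2, l$cache$in_sd, "/")
  dim(gx) <- d
  gx
}

act_fw <- function(l, z) {
  switch(l$act,
    none = z,
    relu = { l$cache$act_in <- z; z * (z > 0) },
    lrelu = { l$cache$act_in <- z; ifelse(z > 0, z, 0.2 * z) },
    tanh = { y <- tanh(z); l$cache$act_out <- y; y })
}

act_bw <- function(l, gy) {
  switch(l$act,
    none = gy,
    relu = gy * (l$cache$act_in > 0),
    lrelu = gy * ifelse(l$cache$act_in > 0, 1, 0.2),
    tanh = gy * (1 - l$cache$act_out^2))
}

zero_grads_layer <- function(l) {
  for (nm in names(l$pars)) {
    g <- l$pars[[nm]]
    l$grads[[nm]] <- if (is.null(dim(g))) numeric(length(g)) else array(0, dim(g))
  }
  if (l$kind == "residual") {
    zero_grads_layer(l$conv1)
    zero_grads_layer(l$conv2)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_forward <- function(l, x, train = TRUE) {
  l$cache <- list()
  if (l$kind == "conv") {
    xp <- pad_spatial(x, l$pad3, l$pad_mode)
    if (any(dim(xp)[1:3] < dim(l$pars$W)[1:3])) {
      stop("input spatial shape (", paste(dim(x)[1:3], collapse = "x"),
           ") too small for a ", l$k, "-wide convolution")
    }
    z <- cpp_conv_fw(xp, l$pars$W, l$pars$b, as.integer(l$stride3))
    if (train) l$cache$xp <- xp
    if (l$norm) z <- instance_norm_fw(l, z)
    act_fw(l, z)
  } else if (l$kind == "tconv") {
    z <- cpp_tconv_fw(x, l$pars$W, l$pars$b, as.integer(l$stride3),
                      as.integer(l$pad3), as.integer(l$opad3))
    if (train) l$cache$x <- x
    if (l$norm) z <- instance_norm_fw(l, z)
    act_fw(l, z)
  } else if (l$kind == "residual") {
    h <- layer_forward(l$conv1, x, train)
    h <- layer_forward(l$conv2, h, train)
    x + h
  } else stop("unknown layer kind ", l$kind)
}

layer_backward <- function(l, gy) {
  if (l$kind == "conv") {
    g <- act_bw(l, gy)
    if (l$norm) g <- instance_norm_bw(l, g)
    xp <- l$cache$xp
    l$grads$W <- l$grads$W +
      cpp_conv_bw_weight(xp, g, dim(l$pars$W)[1:3], as.integer(l$stride3))
    gb <- g; dim(gb) <- c(prod(dim(g)[1:3]), dim(g)[4])
    l$grads$b <- l$grads$b + colSums(gb)
    gxp <- cpp_conv_bw_input(g, l$pars$W, as.integer(l$stride3),
                             as.integer(dim(xp)))
    unpad_fold(gxp, l$pad3, l$pad_mode)
  } else if (l$kind == "tconv") {
    g <- act_bw(l, gy)
    if (l$norm) g <- instance_norm_bw(l, g)
    x <- l$cache$x
    l$grads$W <- l$grads$W +
      cpp_tconv_bw_weight(x, g, dim(l$pars$W)[1:3], as.integer(l$stride3),
                          as.integer(l$pad3))
    gb <- g; dim(gb) <- c(prod(dim(g)[1:3]), dim(g)[4])
    l$grads$b <- l$grads$b + colSums(gb)
    cpp_tconv_bw_input(g, l$pars$W, as.integer(l$stride3),
                       as.integer(l$pad3), as.integer(dim(x)))
  } else if (l$kind == "residual") {
    g2 <- layer_backward(l$conv2, gy)
    g1 <- layer_backward(l$conv1, g2)
    gy + g1
  } else stop("unknown layer kind ", l$kind)
}

layer_param_envs <- function(l) {
  if (l$kind == "residual") list(l$conv1, l$conv2) else list(l)
}

layer_n_params <- function(l) {
  sum(vapply(layer_param_envs(l), function(e)
    sum(vapply(e$pars, length, integer(1))), numeric(1)))
}
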