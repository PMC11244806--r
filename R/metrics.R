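# Cube-wise image-quality metric suite: pixel-error metrics, structural
# similarity, vector similarity, foreground/background splits and
# block-wise error maps. Conventions: "pred" is the generated image,
# "gt" the experimentally acquired ground truth.

#' Partition a volume into non-overlapping evaluation cubes
#'
#' Axis-aligned grid of `floor(dim / edge)` cubes per axis, fully inside
#' the volume; trailing remainders are discarded. The reference evaluation
#' divides a test stack into 25 cubes of 128^3.
#'
#' @param volume 3D `tg_volume` or array.
#' @param edge Cube edge in voxels (default 128).
#' @return A `tg_cube_partition` with integer `origins` (one row per cube).
#' @export
partition_cubes <- function(volume, edge = 128L) {
  d <- if (inherits(volume, "tg_volume")) dim(volume$data) else dim(volume)
  if (length(d) != 3L) stop("cube partition needs a 3D volume")
  edge <- as.integer(edge)
  if (any(d < edge)) {
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than one ", edge, "^3 cube")
  }
  counts <- d %/% edge
  grid <- expand.grid(z = seq_len(counts[1]), y = seq_len(counts[2]),
                      x = seq_len(counts[3]))
  origins <- as.matrix((grid - 1L) * edge + 1L)
  structure(list(edge = edge, origins = origins, count = nrow(origins),
                 volume_dim = d),
            class = "tg_cube_partition")
}

#' @export
print.tg_cube_partition <- function(x, ...) {
  cat("<tg_cube_partition> ", x$count, " cubes of ", x$edge, "^3 in a ",
      paste(x$volume_dim, collapse = "x"), " volume\n", sep = "")
  invisible(x)
}

extract_cube <- function(data, origin, edge) {
  data[origin[1]:(origin[1] + edge - 1L),
       origin[2]:(origin[2] + edge - 1L),
       origin[3]:(origin[3] + edge - 1L), drop = FALSE]
}

#' Pixel-error metrics
#'
#' MSE (mean squared difference), MSLE (squared difference of logarithms;
#' inputs are shifted to be non-negative first, then `log1p` is applied),
#' MAE (mean absolute difference), RMSE (`sqrt(MSE)`), and PSNR
#' (`10 log10(max(gt)^2 / MSE)` in dB, with the peak taken from the ground
#' truth itself). Identical images give PSNR `Inf`.
#'
#' @param pred,gt Equal-shaped numeric arrays.
#' @return Named list: `MSE`, `MSLE`, `MAE`, `RMSE`, `PSNR`.
#' @export
pixel_metrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  diff <- pred - gt
  mse <- mean(diff^2)
  shift <- max(0, -min(min(pred), min(gt)))
  msle <- mean((log1p(pred + shift) - log1p(gt + shift))^2)
  mae <- mean(abs(diff))
  psnr <- if (mse == 0) Inf else 10 * log10(max(gt)^2 / mse)
  list(MSE = mse, MSLE = msle, MAE = mae, RMSE = sqrt(mse), PSNR = psnr)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian filtering (valid region) of a 2D/3D array via the
# convolution kernels; returns the filtered array (smaller than input).
gauss_filter_valid <- function(x, size, sigma) {
  d <- dim(x); nd <- length(d)
  t4 <- x
  dim(t4) <- if (nd == 2) c(1L, d, 1L) else c(d, 1L)
  k <- gaussian_kernel_1d(size, sigma)
  s3 <- c(1L, 1L, 1L)
  axes <- if (nd == 2) 2:3 else 1:3
  for (ax in axes) {
    kd <- c(1L, 1L, 1L); kd[ax] <- size
    kern <- array(k, dim = c(kd, 1L, 1L))
    t4 <- cpp_conv_fw(t4, kern, 0, s3)
  }
  out <- t4
  dim(out) <- if (nd == 2) dim(t4)[2:3] else dim(t4)[1:3]
  out
}

ssim_components <- function(pred, gt, data_range, size = 11L, sigma = 1.5) {
  if (any(dim(pred) < size)) {
    stop("image edges (", paste(dim(pred), collapse = "x"),
         ") smaller than the ", size, "-wide SSIM window")
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- gauss_filter_valid(pred, size, sigma)
  mu2 <- gauss_filter_valid(gt, size, sigma)
  s11 <- gauss_filter_valid(pred^2, size, sigma) - mu1^2
  s22 <- gauss_filter_valid(gt^2, size, sigma) - mu2^2
  s12 <- gauss_filter_valid(pred * gt, size, sigma) - mu1 * mu2
  lum <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  cs <- (2 * s12 + C2) / (s11 + s22 + C2)
  list(ssim_map = lum * cs, cs_map = cs)
}

#' Structural similarity metrics
#'
#' SSIM with an 11-wide Gaussian window (sigma 1.5) and stability constants
#' K1 = 0.01, K2 = 0.03 over the declared data range, averaged over the
#' valid map; and MS-SSIM, which combines contrast-structure terms over
#' successive dyadic downsamplings with the standard five scale weights
#' (fewer scales with renormalized weights when the image is too small).
#'
#' @param pred,gt Equal-shaped 2D or 3D arrays.
#' @param data_range Intensity range the constants refer to; default: the
#'   joint observed range of both images (symmetric in the arguments;
#'   2 for `[-1, 1]`-normalized data).
#' @return Named list: `SSIM`, `MS_SSIM`.
#' @export
structural_metrics <- function(pred, gt, data_range = NULL) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  data_range <- default_data_range(pred, gt, data_range)
  list(SSIM = ssim(pred, gt, data_range),
       MS_SSIM = ms_ssim(pred, gt, data_range))
}

default_data_range <- function(pred, gt, data_range) {
  if (!is.null(data_range)) return(data_range)
  r <- max(max(pred), max(gt)) - min(min(pred), min(gt))
  if (r == 0) 1 else r  # constant images: constants on unit range
}

#' @rdname structural_metrics
#' @export
ssim <- function(pred, gt, data_range = NULL) {
  data_range <- default_data_range(pred, gt, data_range)
  mean(ssim_components(pred, gt, data_range)$ssim_map)
}

downsample2 <- function(x) {
  d <- dim(x); nd <- length(d)
  keep <- d - d %% 2L
  if (nd == 2) {
    x <- x[seq_len(keep[1]), seq_len(keep[2]), drop = FALSE]
    0.25 * (x[seq(1, keep[1], 2), seq(2, keep[2], 2), drop = FALSE] +
            x[seq(2, keep[1], 2), seq(2, keep[2], 2), drop = FALSE] +
            x[seq(1, keep[1], 2), seq(1, keep[2], 2), drop = FALSE] +
            x[seq(2, keep[1], 2), seq(1, keep[2], 2), drop = FALSE])
  } else {
    x <- x[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
    out <- 0
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
      out <- out + x[seq(a, keep[1], 2), seq(b, keep[2], 2),
                     seq(cc, keep[3], 2), drop = FALSE]
    }
    out / 8
  }
}

#' @rdname structural_metrics
#' @param max_levels Maximum number of dyadic scales (default 5).
#' @export
ms_ssim <- function(pred, gt, data_range = NULL, max_levels = 5L) {
  data_range <- default_data_range(pred, gt, data_range)
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  # number of scales the image can support (window 11 at every scale)
  levels <- 1L
  sz <- min(dim(pred))
  while (levels < max_levels && (sz %/% 2L) >= 11L) {
    levels <- levels + 1L
    sz <- sz %/% 2L
  }
  w <- weights[seq_len(levels)]
  w <- w / sum(w)
  vals <- numeric(levels)
  p <- pred; g <- gt
  for (lv in seq_len(levels)) {
    comp <- ssim_components(p, g, data_range)
    vals[lv] <- if (lv == levels) mean(comp$ssim_map) else mean(comp$cs_map)
    if (lv < levels) { p <- downsample2(p); g <- downsample2(g) }
  }
  vals <- pmax(vals, 0)  # clamp negative contrast terms, the usual convention
  prod(vals^w)
}

#' Vector similarity metrics
#'
#' COS: cosine of the angle between the two flattened intensity vectors.
#' CoC: Pearson correlation coefficient over voxels. Degenerate inputs
#' (zero vector for COS, constant image for CoC) return 0 with a warning
#' rather than NaN so cube-wise reports keep every cube.
#'
#' @param pred,gt Equal-shaped numeric arrays.
#' @return Named list: `COS`, `CoC`.
#' @export
vector_metrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  a <- as.numeric(pred); b <- as.numeric(gt)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cos_v <- if (na == 0 || nb == 0) {
    warning("zero vector: COS undefined, reporting 0")
    0
  } else sum(a * b) / (na * nb)
  coc <- if (sd(a) == 0 || sd(b) == 0) {
    warning("constant image: correlation undefined, reporting 0")
    0
  } else stats::cor(a, b)
  list(COS = cos_v, CoC = coc)
}

#' Foreground/background-split metrics
#'
#' Computes each pixel metric separately over the foreground and background
#' voxel sets defined by the Otsu mask of the ground truth, mirroring the
#' split evaluation of prediction quality inside and outside structures.
#' Empty regions are reported absent (`NA`), never as zeros.
#'
#' @param pred,gt Equal-shaped numeric arrays.
#' @return Data frame with columns `region`, `metric`, `value`.
#' @export
fg_bg_metrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  mask <- suppressWarnings(otsu_mask(gt))
  rows <- list()
  for (region in c("fg", "bg")) {
    sel <- if (region == "fg") mask else !mask
    if (!any(sel)) {
      rows[[region]] <- data.frame(region = region,
                                   metric = c("MSE", "MSLE", "MAE", "RMSE", "PSNR"),
                                   value = NA_real_)
      next
    }
    pm <- pixel_metrics(as.numeric(pred[sel]), as.numeric(gt[sel]))
    rows[[region]] <- data.frame(region = region, metric = names(pm),
                                 value = unlist(pm, use.names = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Block-wise error heatmap
#'
#' Divides a 2D image (or a chosen z-slice of a 3D stack) into a grid of
#' blocks (default 9 x 9) and reports the MSE within each block — the
#' spatial error map used to locate where predictions fail (errors
#' concentrate near large veins in real tissue). Remainder pixels join the
#' last block of each axis, so the blocks tile the image exactly and the
#' size-weighted mean of block MSEs equals the global MSE.
#'
#' @param pred,gt 2D matrices of equal shape (or 3D with `z` given).
#' @param blocks Grid dimensions, default `c(9, 9)`.
#' @param z Slice index when inputs are 3D.
#' @return `blocks`-shaped matrix of MSE values, with the per-block pixel
#'   counts attached as attribute `"n"`.
#' @export
error_heatmap <- function(pred, gt, blocks = c(9L, 9L), z = NULL) {
  if (!is.null(z)) {
    pred <- pred[z, , ]; gt <- gt[z, , ]
  }
  if (length(dim(pred)) != 2L) stop("error_heatmap needs 2D images (or a z slice)")
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  d <- dim(pred)
  if (any(d < blocks)) stop("image smaller than the block grid")
  e1 <- d[1] %/% blocks[1]; e2 <- d[2] %/% blocks[2]
  mse <- matrix(0, blocks[1], blocks[2])
  n <- matrix(0, blocks[1], blocks[2])
  for (i in seq_len(blocks[1])) {
    ri <- ((i - 1) * e1 + 1):(if (i == blocks[1]) d[1] else i * e1)
    for (j in seq_len(blocks[2])) {
      rj <- ((j - 1) * e2 + 1):(if (j == blocks[2]) d[2] else j * e2)
      diff <- pred[ri, rj] - gt[ri, rj]
      mse[i, j] <- mean(diff^2)
      n[i, j] <- length(diff)
    }
  }
  attr(mse, "n") <- n
  mse
}

#' Cube-wise evaluation report
#'
#' Computes every quality metric independently for each cube of a
#' partition: the pixel-error metrics, SSIM and MS-SSIM, COS and CoC, FID
#' (between the sets of z-slices of the two cubes, with a pluggable
#' feature extractor), and optionally the foreground/background splits.
#'
#' @param pred_volume,gt_volume Equal-shaped 3D volumes or arrays.
#' @param partition A [partition_cubes()] plan; default partitions
#'   `gt_volume` with 128-voxel cubes.
#' @param fid_extractor Feature extractor for FID; `NULL` uses
#'   [feature_extractor_default()]. Set `FALSE` to skip FID.
#' @param fg_bg Also compute Otsu-split foreground/background metrics.
#' @param data_range Intensity range for the structural metrics.
#' @return A `tg_metric_report`: data frame with one row per cube and one
#'   column per metric; `summary()` gives median, quartiles and range per
#'   metric (the box-plot convention: median line, quartile box, whiskers
#'   at the data range).
#' @export
evaluate_cubewise <- function(pred_volume, gt_volume, partition = NULL,
                              fid_extractor = NULL, fg_bg = FALSE,
                              data_range = NULL) {
  pred <- if (inherits(pred_volume, "tg_volume")) pred_volume$data else pred_volume
  gt <- if (inherits(gt_volume, "tg_volume")) gt_volume$data else gt_volume
  if (!identical(dim(pred), dim(gt))) stop("volume shapes differ")
  if (is.null(partition)) partition <- partition_cubes(gt)
  if (is.null(fid_extractor)) fid_extractor <- feature_extractor_default()
  do_fid <- !identical(fid_extractor, FALSE)

  rows <- vector("list", partition$count)
  for (ci in seq_len(partition$count)) {
    o <- partition$origins[ci, ]
    pc <- extract_cube(pred, o, partition$edge)
    gc <- extract_cube(gt, o, partition$edge)
    pm <- pixel_metrics(pc, gc)
    sm <- suppressWarnings(structural_metrics(pc, gc, data_range))
    vm <- suppressWarnings(vector_metrics(pc, gc))
    row <- data.frame(cube = ci, z0 = o[1], y0 = o[2], x0 = o[3],
                      MSE = pm$MSE, MSLE = pm$MSLE, MAE = pm$MAE,
                      RMSE = pm$RMSE, PSNR = pm$PSNR,
                      SSIM = sm$SSIM, MS_SSIM = sm$MS_SSIM,
                      COS = vm$COS, CoC = vm$CoC)
    if (do_fid) {
      slices_p <- lapply(seq_len(dim(pc)[1]), function(z) pc[z, , ])
      slices_g <- lapply(seq_len(dim(gc)[1]), function(z) gc[z, , ])
      row$FID <- suppressWarnings(fid(slices_p, slices_g, fid_extractor))
    }
    if (fg_bg) {
      sp <- suppressWarnings(fg_bg_metrics(pc, gc))
      for (k in seq_len(nrow(sp))) {
        row[[paste0(sp$metric[k], "_", sp$region[k])]] <- sp$value[k]
      }
    }
    rows[[ci]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tg_metric_report", "data.frame")
  out
}

#' @export
summary.tg_metric_report <- function(object, ...) {
  metric_cols <- setdiff(names(object), c("cube", "z0", "y0", "x0"))
  rows <- lapply(metric_cols, function(m) {
    v <- object[[m]]
    v <- v[is.finite(v)]
    if (!length(v)) {
      return(data.frame(metric = m, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, min = NA_real_, max = NA_real_))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(metric = m, median = q[2], q1 = q[1], q3 = q[3],
               min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}
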