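#' Otsu threshold of an image
#'
#' Histogram threshold maximizing the between-class variance, used to split
#' background from foreground both in the weighted reconstruction loss and
#' in the foreground/background metric variants. Works on any value range
#' (the histogram is built over the observed range); the returned mask
#' convention is `image > threshold` = foreground. The criterion is
#' equivariant under affine intensity rescaling.
#'
#' @param image Numeric array or vector with at least 2 distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return The threshold (numeric scalar). For a constant image, returns
#'   `Inf` with a warning so the mask is all-background.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant image: Otsu threshold undefined, mask is all background")
    return(Inf)
  }
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                      # class-0 probability up to bin t
  centers <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  mu <- cumsum(p * centers)               # class-0 unnormalized mean
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  t_idx <- which.max(sigma_b2)
  # threshold at the upper edge of the argmax bin: everything in bins
  # <= t_idx is background under the `> threshold` convention
  lo + t_idx / n_bins * (hi - lo)
}

#' Otsu foreground mask
#' @inheritParams otsu_threshold
#' @return Logical array: `image > otsu_threshold(image)`.
#' @export
otsu_mask <- function(image, n_bins = 256L) {
  image > otsu_threshold(image, n_bins)
}

#' Foreground/background-weighted mean squared error
#'
#' The reconstruction loss of the Otsu-weighted model variant: the MSE is
#' computed independently over the background (`mask == 0`) and foreground
#' (`mask == 1`) voxel sets and combined as `w_bg * MSE_bg + w_fg * MSE_fg`
#' (reference weights 0.2 and 0.8). An empty region contributes 0.
#'
#' @param pred,target Equal-shaped numeric arrays.
#' @param mask Logical/0-1 array: foreground indicator (from the target's
#'   Otsu split during training).
#' @param w_bg,w_fg Region weights; must sum to 1.
#' @return Scalar loss.
#' @export
weighted_mse <- function(pred, target, mask, w_bg = 0.2, w_fg = 0.8) {
  if (!identical(dim(pred), dim(target)) ||
      !identical(dim(pred), dim(mask))) {
    stop("pred, target and mask must have identical shapes")
  }
  if (abs(w_bg + w_fg - 1) > 1e-12) stop("w_bg + w_fg must equal 1")
  m <- as.logical(mask)
  d2 <- (pred - target)^2
  n_fg <- sum(m)
  n_bg <- length(m) - n_fg
  loss_fg <- if (n_fg > 0) sum(d2[m]) / n_fg else 0
  loss_bg <- if (n_bg > 0) sum(d2[!m]) / n_bg else 0
  w_bg * loss_bg + w_fg * loss_fg
}

# Gradient of weighted_mse w.r.t. pred (same shape as pred).
weighted_mse_grad <- function(pred, target, mask, w_bg = 0.2, w_fg = 0.8) {
  m <- as.logical(mask)
  n_fg <- sum(m)
  n_bg <- length(m) - n_fg
  g <- 2 * (pred - target)
  gm <- array(0, dim(pred))
  if (n_fg > 0) gm[m] <- g[m] * (w_fg / n_fg)
  if (n_bg > 0) gm[!m] <- g[!m] * (w_bg / n_bg)
  gm
}

#' Least-squares adversarial losses
#'
#' The least-squares GAN objective used for both discriminators: the
#' discriminator minimizes `mean((D(real) - 1)^2) + mean(D(fake)^2)`, the
#' generator minimizes `mean((D(fake) - 1)^2)` on its generated images.
#'
#' @param real_scores,fake_scores Discriminator score maps (any shape).
#' @return List with `loss_D` and `loss_G`.
#' @export
adversarial_losses <- function(real_scores, fake_scores) {
  stopifnot(all(is.finite(real_scores)), all(is.finite(fake_scores)))
  list(
    loss_D = mean((real_scores - 1)^2) + mean(fake_scores^2),
    loss_G = mean((fake_scores - 1)^2)
  )
}

# d/dscores of the least-squares objectives
adv_grad_d_real <- function(scores) 2 * (scores - 1) / length(scores)
adv_grad_d_fake <- function(scores) 2 * scores / length(scores)
adv_grad_g_fake <- function(scores) 2 * (scores - 1) / length(scores)

#' Cycle-consistency reconstruction loss
#'
#' Penalty on `G_BA(G_AB(x))` against the original `x` (and symmetrically
#' for the other direction). In plain mode it is the mean squared
#' difference; in Otsu-weighted mode (the "+" model variant) it is
#' [weighted_mse()] with the foreground mask computed from `x` itself by
#' Otsu thresholding.
#'
#' @param x Original image.
#' @param x_rec Reconstruction after a full cycle.
#' @param mode `"mse"` or `"otsu"`.
#' @param w_bg,w_fg Region weights for `"otsu"` mode.
#' @param mask Optional precomputed foreground mask of `x` (cached per patch
#'   during training).
#' @return Scalar loss.
#' @export
cycle_loss <- function(x, x_rec, mode = c("mse", "otsu"),
                       w_bg = 0.2, w_fg = 0.8, mask = NULL) {
  mode <- match.arg(mode)
  if (!identical(dim(x), dim(x_rec))) stop("shape mismatch in cycle loss")
  if (mode == "mse") {
    mean((x_rec - x)^2)
  } else {
    if (is.null(mask)) mask <- suppressWarnings(otsu_mask(x))
    weighted_mse(x_rec, x, mask, w_bg, w_fg)
  }
}

cycle_loss_grad <- function(x, x_rec, mode, w_bg = 0.2, w_fg = 0.8,
                            mask = NULL) {
  if (mode == "mse") {
    2 * (x_rec - x) / length(x)
  } else {
    if (is.null(mask)) mask <- suppressWarnings(otsu_mask(x))
    weighted_mse_grad(x_rec, x, mask, w_bg, w_fg)
  }
}
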