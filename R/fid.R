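#' Fréchet distance between feature distributions (FID)
#'
#' Fits a Gaussian to the feature representations of each image set and
#' returns the Fréchet distance
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`.
#' The feature extractor is pluggable: any `function(image) -> numeric
#' vector`. The classical choice is an ImageNet-pretrained inception
#' network; absolute FID values are only comparable within one extractor,
#' so the package default is a fixed, seeded projection extractor
#' ([feature_extractor_default()]) that needs no pretrained weights, and
#' tests use a transparent linear extractor.
#'
#' Degenerate covariances (e.g. a constant extractor) are handled by
#' clamping negative eigenvalues of the symmetrized product to zero, with
#' a warning, so the result is 0 rather than NaN for identical
#' degenerate sets.
#'
#' @param samples_a,samples_b Lists (length >= 2) of images.
#' @param feature_extractor `function(image) -> numeric vector`, constant
#'   dimension.
#' @return Scalar FID (>= 0 up to numerical tolerance).
#' @export
fid <- function(samples_a, samples_b, feature_extractor = feature_extractor_default()) {
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("FID needs at least 2 samples per side")
  }
  fa <- do.call(rbind, lapply(samples_a, function(s) as.numeric(feature_extractor(s))))
  fb <- do.call(rbind, lapply(samples_b, function(s) as.numeric(feature_extractor(s))))
  if (length(unique(c(ncol(fa), ncol(fb)))) != 1) {
    stop("feature dimension mismatch between sides")
  }
  mua <- colMeans(fa); mub <- colMeans(fb)
  Sa <- cov(fa); Sb <- cov(fb)
  covmean <- sqrtm_product(Sa, Sb)
  d <- sum((mua - mub)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(diag(covmean))
  max(d, 0)
}

# Symmetric square root of Sa %*% Sb via Sa^(1/2) Sb Sa^(1/2); PSD-safe.
sqrtm_product <- function(Sa, Sb) {
  sqa <- sqrtm_psd(Sa)
  M <- sqa %*% Sb %*% sqa
  sqrtm_psd((M + t(M)) / 2)
}

sqrtm_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8 * max(abs(vals), 1))) {
    warning("covariance not PSD within tolerance; clamping negative eigenvalues")
  }
  vals <- pmax(vals, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Default FID feature extractor
#'
#' A fixed, seeded feature extractor requiring no pretrained weights:
#' images are average-pooled to a `pool x pool` grid and mapped through a
#' frozen random linear projection with a ReLU, concatenated with simple
#' global statistics (mean, SD, quantiles). Deterministic across sessions
#' for a given seed; suitable for comparing models under one extractor.
#'
#' @param n_features Projection dimension (default 64).
#' @param pool Pooling grid edge (default 16).
#' @param seed Seed freezing the projection.
#' @return `function(image) -> numeric vector`.
#' @export
feature_extractor_default <- function(n_features = 64L, pool = 16L, seed = 7L) {
  proj <- NULL
  init <- function(d_in) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    p <- matrix(rnorm(d_in * n_features) / sqrt(d_in), d_in, n_features)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else set.seed(NULL)
    p
  }
  function(image) {
    img <- as.array(image)
    if (length(dim(img)) == 3L) {
      # 3D input: max-project along z so one extractor serves both cases
      img <- apply(img, c(2, 3), max)
    }
    pooled <- pool_to_grid(img, pool)
    v <- as.numeric(pooled)
    if (is.null(proj)) proj <<- init(length(v))
    h <- pmax(as.numeric(v %*% proj), 0)
    c(h, mean(img), sd(img), quantile(img, c(0.1, 0.5, 0.9), names = FALSE))
  }
}

pool_to_grid <- function(img, pool) {
  d <- dim(img)
  bz <- ceiling(seq_len(d[1]) / d[1] * pool)
  by <- ceiling(seq_len(d[2]) / d[2] * pool)
  # block means via two rowsum passes
  s1 <- rowsum(img, bz)                      # pool x d2, sums over rows
  n1 <- as.numeric(table(bz))
  s1 <- s1 / n1
  s2 <- t(rowsum(t(s1), by))
  n2 <- as.numeric(table(by))
  out <- sweep(s2, 2, n2, "/")
  out
}

#' Linear test feature extractor
#'
#' The transparent extractor used in closed-form FID tests: the feature of
#' an image is a fixed linear functional (default: its mean).
#'
#' @param fun Function mapping an image to a (short) numeric vector.
#' @return The extractor function.
#' @export
feature_extractor_linear <- function(fun = function(img) mean(img)) {
  function(image) as.numeric(fun(image))
}
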