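#' Image volume container
#'
#' A light container for 2D images and 3D stacks: an intensity array indexed
#' `(z, y, x)` (or `(y, x)` for 2D), the physical voxel size in micrometres
#' per axis, and a name used in error messages and provenance records.
#' `z` is depth from the imaged surface.
#'
#' @param data Numeric array, 2 or 3 dimensions, finite values.
#' @param voxel_size Numeric vector of micrometres per axis, recycled to the
#'   number of dimensions. Default 1 um isotropic.
#' @param name Character label.
#' @return An object of class `tg_volume`.
#' @export
as_volume <- function(data, voxel_size = 1, name = "volume") {
  if (!is.array(data) && !is.matrix(data)) {
    data <- as.array(data)
  }
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) {
    stop("volume must have 2 or 3 dimensions, got ", nd)
  }
  if (!all(is.finite(data))) {
    stop("volume '", name, "' contains non-finite values")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), nd)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  structure(
    list(data = data, voxel_size = voxel_size, name = name, norm = NULL),
    class = "tg_volume"
  )
}

#' @export
print.tg_volume <- function(x, ...) {
  cat("<tg_volume> '", x$name, "' ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " um/voxel\n", sep = "")
  cat("  intensity range: [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]",
      if (!is.null(x$norm)) "  (normalized, affine recorded)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.tg_volume <- function(x) dim(x$data)

#' Read an image stack from a TIFF file
#'
#' Reads single- or multi-page TIFFs into a [as_volume()] container.
#' Multi-page files become 3D stacks with pages along `z`; single-page files
#' become 2D volumes. Integer pixel types are rescaled by `tiff` to `[0, 1]`;
#' the original bit depth is recorded so [write_stack()] can round-trip
#' losslessly. The voxel size is taken from the JSON metadata sidecar
#' (`<path>.meta.json`) when a previous [write_stack()] call produced one,
#' else from `voxel_size`.
#'
#' @param path File path to an existing TIFF.
#' @param voxel_size Fallback voxel size in micrometres per axis.
#' @param name Volume name; defaults to the file name.
#' @return A `tg_volume`.
#' @export
read_stack <- function(path, voxel_size = 1, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("unreadable TIFF '", path, "': ", conditionMessage(e))
  )
  first <- if (is.list(pages)) pages[[1]] else pages
  if (length(dim(first)) > 2) {
    stop("unsupported pixel type in '", path, "': multi-sample (colour) TIFFs are not supported")
  }
  bits <- attr(first, "bits.per.sample")
  fmt <- attr(first, "sample.format")
  if (is.list(pages) && length(pages) > 1L) {
    ny <- nrow(first); nx <- ncol(first)
    data <- array(0, dim = c(length(pages), ny, nx))
    for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
  } else {
    data <- first
    attributes(data) <- list(dim = dim(first))
  }
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) voxel_size <- as.numeric(meta$voxel_size_um)
    if (!is.null(meta$intensity_range)) {
      r <- as.numeric(meta$intensity_range)
      data <- data * (r[2] - r[1]) + r[1]
    }
  }
  vol <- as_volume(data, voxel_size = voxel_size, name = name)
  vol$bits <- if (!is.null(bits)) as.integer(bits) else NA_integer_
  vol$sample_format <- if (!is.null(fmt)) fmt else NA_character_
  vol
}

#' Write an image stack to a TIFF file
#'
#' Writes a `tg_volume` (or plain array) as a single- or multi-page TIFF.
#' `bits = 32` stores IEEE float samples losslessly; 8 or 16 bit integer
#' samples expect data in `[0, 1]` (the `tiff` package convention) and
#' round-trip integer data exactly at `k / (2^bits - 1)` grid values. The
#' voxel size is stored in a JSON metadata sidecar next to the file.
#'
#' @param volume A `tg_volume` or numeric array.
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 or 32 (float). Default 32.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, bits = 32L) {
  if (!inherits(volume, "tg_volume")) volume <- as_volume(volume)
  if (!bits %in% c(8L, 16L, 32L)) stop("unsupported bits per sample: ", bits)
  data <- volume$data
  # the tiff backend stores samples on a [0, 1] scale at every bit depth;
  # out-of-range data is rescaled, with the range recorded in the sidecar
  # so read_stack() restores the original scale
  lo <- min(data); hi <- max(data)
  stored_range <- NULL
  if (lo < 0 || hi > 1) {
    stored_range <- c(lo, hi)
    data <- if (hi > lo) (data - lo) / (hi - lo) else array(0, dim(data))
  }
  what <- if (length(dim(data)) == 2L) {
    list(data)
  } else {
    lapply(seq_len(dim(data)[1]), function(k) data[k, , , drop = TRUE])
  }
  tryCatch(
    tiff::writeTIFF(what, path, bits.per.sample = bits, compression = "none",
                    reduce = FALSE),
    error = function(e) stop("cannot write TIFF '", path, "': ", conditionMessage(e))
  )
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size, name = volume$name,
         intensity_range = stored_range),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Normalize intensities to [-1, 1]
#'
#' Affine min-max normalization: the minimum maps to -1 and the maximum to
#' +1, matching the input scaling the translation networks are trained on.
#' The affine parameters are recorded on the volume so predictions can be
#' mapped back with [denormalize()]. A constant image cannot be scaled and
#' is mapped to all zeros with a warning.
#'
#' @param volume A `tg_volume` or numeric array.
#' @param clip_quantiles Optional length-2 vector of lower/upper quantiles
#'   (e.g. `c(0.001, 0.999)`); intensities are clipped there before scaling.
#'   Off (`NULL`) by default.
#' @return The normalized `tg_volume`, with `$norm = c(min, max)` recorded.
#' @export
normalize <- function(volume, clip_quantiles = NULL) {
  plain <- !inherits(volume, "tg_volume")
  if (plain) volume <- as_volume(volume)
  data <- volume$data
  if (!is.null(clip_quantiles)) {
    stopifnot(length(clip_quantiles) == 2, clip_quantiles[1] < clip_quantiles[2])
    q <- quantile(data, clip_quantiles, names = FALSE)
    data[data < q[1]] <- q[1]
    data[data > q[2]] <- q[2]
  }
  lo <- min(data); hi <- max(data)
  if (hi <= lo) {
    warning("constant image '", volume$name, "': normalized to all zeros")
    volume$data <- array(0, dim(data))
    volume$norm <- c(min = lo, max = lo + 1)
    return(volume)
  }
  volume$data <- 2 * (data - lo) / (hi - lo) - 1
  volume$norm <- c(min = lo, max = hi)
  volume
}

#' Invert a recorded normalization
#'
#' Maps a `[-1, 1]` volume back to its original intensity scale using the
#' affine recorded by [normalize()], or an explicitly supplied one.
#'
#' @param volume A normalized `tg_volume`.
#' @param affine Optional `c(min, max)` overriding the recorded affine.
#' @return The denormalized `tg_volume`.
#' @export
denormalize <- function(volume, affine = NULL) {
  if (!inherits(volume, "tg_volume")) volume <- as_volume(volume)
  if (is.null(affine)) affine <- volume$norm
  if (is.null(affine)) {
    stop("no normalization affine recorded for '", volume$name,
         "' and none supplied")
  }
  lo <- affine[[1]]; hi <- affine[[2]]
  volume$data <- (volume$data + 1) / 2 * (hi - lo) + lo
  volume$norm <- NULL
  volume
}
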