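#' Patch sets for training
#'
#' A `tg_patchset` holds equally shaped patches sampled from one or more
#' volumes, with per-patch provenance (source image and corner coordinates)
#' so any extraction is reproducible from its seed.
#'
#' @name patchset
NULL

new_patchset <- function(patches, source_ids, coords, domain, size) {
  structure(list(patches = patches, source_ids = source_ids, coords = coords,
                 domain = domain, size = size),
            class = "tg_patchset")
}

#' @export
print.tg_patchset <- function(x, ...) {
  cat("<tg_patchset> ", length(x$patches), " patches of ",
      paste(x$size, collapse = " x "), ", domain '", x$domain, "'\n", sep = "")
  invisible(x)
}

#' @export
length.tg_patchset <- function(x) length(x$patches)

as_volume_list <- function(volumes) {
  if (inherits(volumes, "tg_volume")) return(list(volumes))
  if (is.array(volumes)) return(list(as_volume(volumes)))
  lapply(volumes, function(v) if (inherits(v, "tg_volume")) v else as_volume(v))
}

#' Extract random 2D patches from image stacks
#'
#' Samples `n_per_image` square patches from each input image at seeded
#' uniform-random positions. For 3D stacks a z-slice is drawn uniformly
#' first, then an in-slice position, matching the protocol where 2D models
#' are trained on slices of 3D acquisitions; 2500 patches per image from
#' two images per domain yields the 5000-patch training domains of the
#' reference protocol. Patches may overlap (2500 patches from one image
#' necessarily do). Positions are fully inside bounds.
#'
#' @param volumes A volume, array, or list of them (one entry per image).
#' @param size Patch edge in pixels (128 for membrane/BC and
#'   membrane/sinusoid models, 256 for membrane/Kupffer).
#' @param n_per_image Patches drawn from each image.
#' @param seed Integer seed.
#' @param domain Domain label ("A" or "B").
#' @return A `tg_patchset` with `n_images * n_per_image` patches.
#' @export
extract_patches_2d <- function(volumes, size = 128L, n_per_image = 2500L,
                               seed = 1L, domain = "A") {
  volumes <- as_volume_list(volumes)
  size <- as.integer(size)
  set.seed(seed)
  patches <- list(); src <- integer(0); coords <- NULL
  for (v in seq_along(volumes)) {
    d <- volumes[[v]]$data
    dm <- dim(d)
    if (length(dm) == 2L) dm <- c(1L, dm)
    if (dm[2] < size || dm[3] < size) {
      stop("image '", volumes[[v]]$name, "' (", paste(dim(d), collapse = "x"),
           ") is smaller than the ", size, "x", size, " patch")
    }
    z <- sample.int(dm[1], n_per_image, replace = TRUE)
    y <- sample.int(dm[2] - size + 1L, n_per_image, replace = TRUE)
    x <- sample.int(dm[3] - size + 1L, n_per_image, replace = TRUE)
    for (i in seq_len(n_per_image)) {
      p <- if (length(dim(d)) == 2L) {
        d[y[i]:(y[i] + size - 1L), x[i]:(x[i] + size - 1L)]
      } else {
        d[z[i], y[i]:(y[i] + size - 1L), x[i]:(x[i] + size - 1L)]
      }
      patches[[length(patches) + 1L]] <- matrix(p, size, size)
    }
    src <- c(src, rep.int(v, n_per_image))
    coords <- rbind(coords, cbind(z = z, y = y, x = x))
  }
  new_patchset(patches, src, coords, domain, c(size, size))
}

#' Extract random 3D patches from image stacks
#'
#' Cubic analogue of [extract_patches_2d()]: 900 patches of 64^3 voxels per
#' image, two images per domain, reproduce the 1800-patch 3D training
#' domains of the reference protocol.
#'
#' @inheritParams extract_patches_2d
#' @param size Cubic patch edge in voxels (default 64).
#' @param n_per_image Patches drawn from each image (default 900).
#' @return A `tg_patchset` of cubic patches.
#' @export
extract_patches_3d <- function(volumes, size = 64L, n_per_image = 900L,
                               seed = 1L, domain = "A") {
  volumes <- as_volume_list(volumes)
  size <- as.integer(size)
  set.seed(seed)
  patches <- list(); src <- integer(0); coords <- NULL
  for (v in seq_along(volumes)) {
    d <- volumes[[v]]$data
    if (length(dim(d)) != 3L) {
      stop("image '", volumes[[v]]$name, "' is not a 3D stack")
    }
    dm <- dim(d)
    if (any(dm < size)) {
      stop("image '", volumes[[v]]$name, "' (", paste(dm, collapse = "x"),
           ") is smaller than the ", size, "^3 patch")
    }
    z <- sample.int(dm[1] - size + 1L, n_per_image, replace = TRUE)
    y <- sample.int(dm[2] - size + 1L, n_per_image, replace = TRUE)
    x <- sample.int(dm[3] - size + 1L, n_per_image, replace = TRUE)
    for (i in seq_len(n_per_image)) {
      patches[[length(patches) + 1L]] <-
        d[z[i]:(z[i] + size - 1L), y[i]:(y[i] + size - 1L),
          x[i]:(x[i] + size - 1L)]
    }
    src <- c(src, rep.int(v, n_per_image))
    coords <- rbind(coords, cbind(z = z, y = y, x = x))
  }
  new_patchset(patches, src, coords, domain, c(size, size, size))
}

#' Split a patch set into training and validation parts
#'
#' Seeded random partition with `round(fraction * N)` training patches and
#' the rest for validation (90/10 in the reference protocol); no overlap,
#' union equal to the input.
#'
#' @param patchset A `tg_patchset`.
#' @param fraction Training fraction in (0, 1). Default 0.9.
#' @param seed Integer seed.
#' @return List with `train` and `val` patch sets.
#' @export
split_train_val <- function(patchset, fraction = 0.9, seed = 1L) {
  stopifnot(inherits(patchset, "tg_patchset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(patchset$patches)
  if (n < 2) stop("need at least 2 patches to split")
  set.seed(seed)
  n_train <- round(fraction * n)
  idx <- sample.int(n)
  take <- function(ix) new_patchset(
    patchset$patches[ix], patchset$source_ids[ix],
    patchset$coords[ix, , drop = FALSE], patchset$domain, patchset$size
  )
  list(train = take(sort(idx[seq_len(n_train)])),
       val = take(sort(idx[setdiff(seq_len(n), seq_len(n_train))])))
}

#' Write a patch set to a directory of TIFFs with a manifest
#'
#' @param patchset A `tg_patchset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_patchset <- function(patchset, dir) {
  stopifnot(inherits(patchset, "tg_patchset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("patch_%05d.tif", seq_along(patchset$patches))
  for (i in seq_along(patchset$patches)) {
    write_stack(as_volume(patchset$patches[[i]]), file.path(dir, files[i]),
                bits = 32L)
  }
  jsonlite::write_json(
    list(domain = patchset$domain, size = patchset$size,
         source_ids = patchset$source_ids,
         coords = as.data.frame(patchset$coords), files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
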