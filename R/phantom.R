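#' Configuration of the synthetic liver phantom
#'
#' Defines the geometry and acquisition conditions the phantom generator
#' emulates: a space-filling hepatocyte tessellation whose boundaries form
#' the actin/membrane mesh, a connected bile-canaliculi (BC) tube network
#' running along cell-cell interfaces, thicker sinusoid tubes, sparse
#' star-shaped Kupffer-cell blobs, mixed Poisson-Gaussian noise, and a
#' sigmoid depth-attenuation emulating the ~80 um antibody-penetration
#' limit of immunostained channels.
#'
#' Default lengths are in micrometres at a 1 um desk-scale voxel; real
#' acquisitions at 0.3 um isotropic voxels use the same configuration with
#' `voxel_size = c(0.3, 0.3, 0.3)`.
#'
#' @param shape Integer voxels per axis `(z, y, x)`.
#' @param voxel_size Micrometres per axis `(z, y, x)`.
#' @param n_cells Number of tessellation cells; `NULL` derives a
#'   space-filling count from `cell_diameter`.
#' @param cell_diameter Nominal hepatocyte diameter, um.
#' @param bc_radius Bile-canaliculi tube radius, um.
#' @param bc_radius_gradient Optional `c(r0, r1)`: BC radius varies linearly
#'   from `r0` to `r1` along the lobule (CV to PV) axis instead of being
#'   constant, for spatial-profile studies.
#' @param sinusoid_radius Sinusoid tube radius, um.
#' @param kupffer_count Number of Kupffer-cell blobs.
#' @param attenuation_depth Depth (um) of the antibody-penetration knee.
#' @param attenuation_width Width (um) of the sigmoid roll-off.
#' @param noise_gaussian_sd Additive Gaussian (read) noise SD, intensity units.
#' @param noise_poisson_scale Poisson (shot) noise scale; 0 disables.
#' @param seed Integer seed; fully determines the phantom.
#' @return A `tg_phantom_config` list.
#' @export
phantom_config <- function(shape = c(192L, 192L, 192L),
                           voxel_size = c(1, 1, 1),
                           n_cells = NULL,
                           cell_diameter = 22,
                           bc_radius = 2,
                           bc_radius_gradient = NULL,
                           sinusoid_radius = 5,
                           kupffer_count = 15L,
                           attenuation_depth = 80,
                           attenuation_width = 20,
                           noise_gaussian_sd = 0.02,
                           noise_poisson_scale = 0.01,
                           seed = 1L) {
  shape <- as.integer(rep_len(shape, 3))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  extent <- shape * voxel_size
  if (any(shape < 1) || any(voxel_size <= 0)) stop("shape and voxel_size must be positive")
  if (is.null(n_cells)) n_cells <- max(1L, round(prod(extent) / cell_diameter^3))
  stopifnot(cell_diameter > 0, bc_radius > 0, sinusoid_radius > 0,
            kupffer_count >= 0, attenuation_depth > 0, attenuation_width > 0,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  if (!is.null(bc_radius_gradient)) {
    stopifnot(length(bc_radius_gradient) == 2, all(bc_radius_gradient > 0))
  }
  if (attenuation_depth > extent[1]) {
    stop("attenuation_depth (", attenuation_depth,
         " um) exceeds the z extent (", extent[1], " um)")
  }
  structure(list(
    shape = shape, voxel_size = voxel_size, n_cells = as.integer(n_cells),
    cell_diameter = cell_diameter, bc_radius = bc_radius,
    bc_radius_gradient = bc_radius_gradient,
    sinusoid_radius = sinusoid_radius, kupffer_count = as.integer(kupffer_count),
    attenuation_depth = attenuation_depth, attenuation_width = attenuation_width,
    noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_scale = noise_poisson_scale, seed = as.integer(seed)
  ), class = "tg_phantom_config")
}

# Blue-noise (dart-throwing) seed points in um coordinates, rows (z, y, x).
poisson_disc_seeds <- function(n, extent, min_dist, max_tries = 60L) {
  pts <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries * n) {
    cand <- runif(3) * extent
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_dist) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
  }
  while (nrow(pts) < n) pts <- rbind(pts, runif(3) * extent)  # relax if saturated
  pts
}

# Nearest-seed (Voronoi) label map computed with per-seed local boxes.
voronoi_labels <- function(shape, voxel_size, seeds, reach) {
  zc <- (seq_len(shape[1]) - 0.5) * voxel_size[1]
  yc <- (seq_len(shape[2]) - 0.5) * voxel_size[2]
  xc <- (seq_len(shape[3]) - 0.5) * voxel_size[3]
  lab <- array(0L, shape)
  best <- array(Inf, shape)
  for (s in seq_len(nrow(seeds))) {
    p <- seeds[s, ]
    iz <- which(abs(zc - p[1]) <= reach)
    iy <- which(abs(yc - p[2]) <= reach)
    ix <- which(abs(xc - p[3]) <= reach)
    if (!length(iz) || !length(iy) || !length(ix)) next
    d2 <- outer(outer((zc[iz] - p[1])^2, (yc[iy] - p[2])^2, "+"),
                (xc[ix] - p[3])^2, "+")
    sub <- best[iz, iy, ix, drop = FALSE]
    upd <- d2 < sub
    sub[upd] <- d2[upd]
    best[iz, iy, ix] <- sub
    labsub <- lab[iz, iy, ix, drop = FALSE]
    labsub[upd] <- s
    lab[iz, iy, ix] <- labsub
  }
  miss <- which(lab == 0L)
  if (length(miss)) {  # rare voxels outside every local box: exact assignment
    coords <- arrayInd(miss, shape)
    pos <- cbind(zc[coords[, 1]], yc[coords[, 2]], xc[coords[, 3]])
    for (i in seq_along(miss)) {
      d2 <- colSums((t(seeds) - pos[i, ])^2)
      lab[miss[i]] <- which.min(d2)
    }
  }
  lab
}

# Interface voxels between differing labels along each axis; returns the
# boundary mask plus a per-interface table of centroids (voxel coords).
interface_geometry <- function(lab) {
  shp <- dim(lab)
  boundary <- array(FALSE, shp)
  pair_key <- integer(0)
  pz <- py <- px <- numeric(0)
  collect <- function(a_idx, b_idx) {
    la <- lab[a_idx]; lb <- lab[b_idx]
    diff <- la != lb
    boundary[a_idx][diff] <<- TRUE
    boundary[b_idx][diff] <<- TRUE
    ia <- which(a_idx)[diff]
    co <- arrayInd(ia, shp)
    lo <- pmin(la[diff], lb[diff]); hi <- pmax(la[diff], lb[diff])
    pair_key <<- c(pair_key, lo * 100000L + hi)
    pz <<- c(pz, co[, 1]); py <<- c(py, co[, 2]); px <<- c(px, co[, 3])
  }
  mk <- function(axis, side) {
    idx <- array(FALSE, shp)
    n <- shp[axis]
    sel <- if (side == 1) seq_len(n - 1) else 1 + seq_len(n - 1)
    if (axis == 1) idx[sel, , ] <- TRUE
    if (axis == 2) idx[, sel, ] <- TRUE
    if (axis == 3) idx[, , sel] <- TRUE
    idx
  }
  for (ax in 1:3) collect(mk(ax, 1), mk(ax, 2))
  cent <- NULL
  if (length(pair_key)) {
    agg <- rowsum(cbind(pz, py, px, 1), group = pair_key)
    key <- as.integer(rownames(agg))
    cent <- data.frame(
      cell_a = key %/% 100000L, cell_b = key %% 100000L,
      z = agg[, 1] / agg[, 4], y = agg[, 2] / agg[, 4], x = agg[, 3] / agg[, 4],
      n_voxels = agg[, 4]
    )
  }
  list(boundary = boundary, interfaces = cent)
}

# Stamp a tube of given per-point radius (um) along a polyline (voxel coords)
# into `arr` (modified copy returned). Sphere-sweep rasterization.
rasterize_tube <- function(arr, polyline, radius_um, voxel_size) {
  shp <- dim(arr)
  radius_um <- rep_len(radius_um, nrow(polyline))
  # densify so consecutive samples are < half the smallest voxel apart
  dens <- densify_polyline(polyline, step = 0.45 * min(voxel_size) / max(voxel_size))
  rad <- approx_radii(polyline, radius_um, dens)
  for (i in seq_len(nrow(dens))) {
    p <- dens[i, ]; r <- rad[i]
    rv <- r / voxel_size  # radius in voxels per axis
    lo <- pmax(1, floor(p - rv)); hi <- pmin(shp, ceiling(p + rv))
    if (any(lo > hi)) next  # sphere entirely outside the volume
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    d2 <- outer(outer(((iz - p[1]) * voxel_size[1])^2,
                      ((iy - p[2]) * voxel_size[2])^2, "+"),
                ((ix - p[3]) * voxel_size[3])^2, "+")
    sub <- arr[iz, iy, ix, drop = FALSE]
    sub[d2 <= r^2] <- 1
    arr[iz, iy, ix] <- sub
  }
  arr
}

densify_polyline <- function(poly, step = 0.45) {
  if (nrow(poly) == 1) return(poly)
  out <- list()
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = nseg + 1)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    out[[i]] <- if (i < nrow(poly) - 1) seg[-nrow(seg), , drop = FALSE] else seg
  }
  do.call(rbind, out)
}

approx_radii <- function(poly, radii, dens) {
  if (nrow(poly) == 1 || length(unique(radii)) == 1) {
    return(rep(radii[1], nrow(dens)))
  }
  # arc-length interpolation of the per-point radii onto the densified path
  s_of <- function(p) c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  sp <- s_of(poly); sdn <- s_of(dens)
  stats::approx(sp, radii, xout = pmin(sdn, max(sp)), rule = 2)$y
}

#' Generate a synthetic liver phantom
#'
#' Builds a seeded multi-channel 3D volume with fully known geometry:
#' `membrane` (bright shells on the boundaries of a Voronoi tessellation of
#' blue-noise cell seeds), `bc` (a connected tube network of radius
#' `bc_radius` threaded along cell-cell interfaces), `sinusoid` (smooth
#' thicker tubes spanning the volume), and `kupffer` (star-shaped blobs).
#' The returned object carries the full ground truth (label map,
#' centerlines with per-point radii, blob centroids, and the lobule CV-PV
#' axis) for oracle-based evaluation of every downstream step. Identical
#' configurations produce bit-identical phantoms.
#'
#' Channels are clean (binary-intensity) geometry; use [add_noise()] and
#' [apply_depth_attenuation()] to emulate acquisition effects.
#'
#' @param config A [phantom_config()].
#' @return A `tg_phantom`: list with `channels` (named arrays), `truth`,
#'   and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "tg_phantom_config"))
  shape <- config$shape; vs <- config$voxel_size
  extent <- shape * vs
  if (any(extent < config$cell_diameter)) {
    stop("phantom shape too small to host one cell of diameter ",
         config$cell_diameter, " um")
  }
  set.seed(config$seed)

  seeds <- poisson_disc_seeds(config$n_cells, extent,
                              min_dist = 0.7 * config$cell_diameter)
  lab <- voronoi_labels(shape, vs, seeds, reach = 1.8 * config$cell_diameter)
  geom <- interface_geometry(lab)

  membrane <- array(0, shape)
  membrane[geom$boundary] <- 1

  # --- BC network: spanning subgraph of the interface-adjacency graph ---
  bc <- array(0, shape)
  bc_centerlines <- list()
  ifc <- geom$interfaces
  if (!is.null(ifc) && nrow(ifc) >= 2) {
    edges <- interface_edges(ifc, max_dist_vox = 1.6 * config$cell_diameter / min(vs))
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = edges$i, to = edges$j, weight = edges$d),
        directed = FALSE,
        vertices = data.frame(name = seq_len(nrow(ifc)))
      )
      mst <- igraph::mst(g)
      keep <- igraph::as_data_frame(mst, what = "edges")
      extra <- igraph::as_data_frame(g, what = "edges")
      in_mst <- paste(keep$from, keep$to)
      pool <- extra[!paste(extra$from, extra$to) %in% in_mst, , drop = FALSE]
      if (nrow(pool)) {  # ~15% extra short edges -> loops, as in real BC meshes
        n_extra <- ceiling(0.15 * nrow(pool))
        pool <- pool[order(pool$weight), , drop = FALSE]
        keep <- rbind(keep, pool[seq_len(min(n_extra, nrow(pool))), ])
      }
      axis_pos <- ifc$x * vs[3]  # lobule axis runs along x
      r_of <- function(xum) {
        if (is.null(config$bc_radius_gradient)) return(rep(config$bc_radius, length(xum)))
        g0 <- config$bc_radius_gradient
        g0[1] + (g0[2] - g0[1]) * xum / extent[3]
      }
      for (k in seq_len(nrow(keep))) {
        i <- as.integer(keep$from[k]); j <- as.integer(keep$to[k])
        poly <- rbind(c(ifc$z[i], ifc$y[i], ifc$x[i]),
                      c(ifc$z[j], ifc$y[j], ifc$x[j]))
        radii <- r_of(c(axis_pos[i], axis_pos[j]))
        bc <- rasterize_tube(bc, poly, radii, vs)
        bc_centerlines[[length(bc_centerlines) + 1L]] <-
          list(points = poly, radius = radii)
      }
    }
  }

  # --- sinusoids: smooth undulating tubes spanning the x axis ---
  sinusoid <- array(0, shape)
  sinusoid_centerlines <- list()
  n_sin <- max(1L, round(config$n_cells^(1 / 3)))
  for (k in seq_len(n_sin)) {
    xs <- seq(1, shape[3], length.out = max(8, shape[3] %/% 8))
    z0 <- runif(1, 0.15, 0.85) * shape[1]
    y0 <- runif(1, 0.15, 0.85) * shape[2]
    amp <- 0.5 * config$cell_diameter / min(vs)
    ph <- runif(2, 0, 2 * pi)
    per <- runif(2, 0.8, 1.5) * shape[3] / 2
    poly <- cbind(z0 + amp * sin(2 * pi * xs / per[1] + ph[1]),
                  y0 + amp * sin(2 * pi * xs / per[2] + ph[2]),
                  xs)
    poly[, 1] <- pmin(pmax(poly[, 1], 1), shape[1])
    poly[, 2] <- pmin(pmax(poly[, 2], 1), shape[2])
    sinusoid <- rasterize_tube(sinusoid, poly, config$sinusoid_radius, vs)
    sinusoid_centerlines[[k]] <- list(points = poly,
                                      radius = rep(config$sinusoid_radius, nrow(poly)))
  }

  # --- Kupffer cells: star-shaped blobs (soma + radiating arms) ---
  kupffer <- array(0, shape)
  kupffer_centroids <- NULL
  if (config$kupffer_count > 0) {
    kupffer_centroids <- matrix(0, config$kupffer_count, 3)
    soma_r <- 2.5; arm_len <- 5; arm_r <- 1
    for (k in seq_len(config$kupffer_count)) {
      ctr <- runif(3, 0.1, 0.9) * shape
      kupffer_centroids[k, ] <- ctr
      kupffer <- rasterize_tube(kupffer, matrix(ctr, 1), soma_r, vs)
      n_arms <- sample(4:7, 1)
      for (a in seq_len(n_arms)) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        tip <- ctr + dir * arm_len / vs
        kupffer <- rasterize_tube(kupffer, rbind(ctr, tip), c(arm_r, arm_r * 0.6), vs)
      }
    }
  }

  truth <- list(
    cell_label_map = lab,
    bc_centerlines = bc_centerlines,
    sinusoid_centerlines = sinusoid_centerlines,
    kupffer_centroids = kupffer_centroids,
    lobule_axis = list(origin = c(shape[1] / 2, shape[2] / 2, 1),
                       direction = c(0, 0, 1),  # CV -> PV along x
                       length_vox = shape[3] - 1)
  )
  structure(list(
    channels = list(membrane = membrane, bc = bc, sinusoid = sinusoid,
                    kupffer = kupffer),
    truth = truth, config = config
  ), class = "tg_phantom")
}

# Candidate BC edges: interfaces sharing a cell, within a distance cap.
interface_edges <- function(ifc, max_dist_vox) {
  n <- nrow(ifc)
  by_cell <- split(c(seq_len(n), seq_len(n)), c(ifc$cell_a, ifc$cell_b))
  ii <- integer(0); jj <- integer(0)
  for (members in by_cell) {
    members <- unique(members)
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
  }
  if (!length(ii)) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  dup <- duplicated(key)
  ii <- ii[!dup]; jj <- jj[!dup]
  d <- sqrt((ifc$z[ii] - ifc$z[jj])^2 + (ifc$y[ii] - ifc$y[jj])^2 +
              (ifc$x[ii] - ifc$x[jj])^2)
  keep <- d <= max_dist_vox & d > 0
  data.frame(i = ii[keep], j = jj[keep], d = d[keep])
}

#' @export
print.tg_phantom <- function(x, ...) {
  cat("<tg_phantom> ", paste(x$config$shape, collapse = " x "), " voxels, ",
      x$config$n_cells, " cells, ", length(x$truth$bc_centerlines),
      " BC branches, ", length(x$truth$sinusoid_centerlines), " sinusoids\n",
      sep = "")
  invisible(x)
}

#' Apply depth-dependent signal attenuation
#'
#' Multiplies a channel by a monotone non-increasing logistic of depth,
#' approximately 1 above `depth - width` and approximately 0 below
#' `depth + width`, emulating the sharp loss of antibody-derived signal
#' beyond the penetration limit (around 80 um in immunostained liver). The
#' membrane/actin channel, stained by the small molecule phalloidin that
#' penetrates hundreds of micrometres, is deliberately left unattenuated in
#' the deep-tissue emulation.
#'
#' @param phantom A `tg_phantom` (or a `tg_volume`/3D array).
#' @param channel Channel name (for phantoms).
#' @param depth Attenuation knee, um.
#' @param width Roll-off width, um; the factor is 0.95 at `depth - width`
#'   and 0.05 at `depth + width`.
#' @return Object of the same type with the channel attenuated.
#' @export
apply_depth_attenuation <- function(phantom, channel = "bc",
                                    depth = 80, width = 20) {
  fac <- function(z_um) stats::plogis(-(z_um - depth) * log(19) / width)
  if (inherits(phantom, "tg_phantom")) {
    if (!channel %in% names(phantom$channels)) {
      stop("unknown channel '", channel, "'; have: ",
           paste(names(phantom$channels), collapse = ", "))
    }
    vz <- phantom$config$voxel_size[1]
    z_um <- (seq_len(phantom$config$shape[1]) - 0.5) * vz
    phantom$channels[[channel]] <-
      phantom$channels[[channel]] * fac(z_um)  # recycles along z (first axis)
    return(phantom)
  }
  vol <- if (inherits(phantom, "tg_volume")) phantom else as_volume(phantom)
  if (length(dim(vol$data)) != 3) stop("depth attenuation needs a 3D volume")
  z_um <- (seq_len(dim(vol$data)[1]) - 0.5) * vol$voxel_size[1]
  vol$data <- vol$data * fac(z_um)
  if (inherits(phantom, "tg_volume")) vol else vol$data
}

#' Add mixed Poisson-Gaussian noise
#'
#' Emulates fluorescence shot noise (Poisson, scaled) plus detector read
#' noise (additive Gaussian). The expectation of the output equals the
#' input. Seeded and reproducible.
#'
#' @param channel Non-negative numeric array.
#' @param gaussian_sd Gaussian SD in intensity units; must be >= 0.
#' @param poisson_scale Intensity per photon; 0 disables shot noise.
#' @param seed Integer seed.
#' @return Noisy array of the same shape.
#' @export
add_noise <- function(channel, gaussian_sd = 0.02, poisson_scale = 0.01,
                      seed = 1L) {
  if (gaussian_sd < 0) stop("gaussian_sd must be non-negative")
  if (poisson_scale < 0) stop("poisson_scale must be non-negative")
  if (min(channel) < 0) stop("add_noise expects non-negative intensities")
  set.seed(seed)
  out <- channel
  if (poisson_scale > 0) {
    out <- array(rpois(length(channel), channel / poisson_scale) * poisson_scale,
                 dim(channel))
  }
  if (gaussian_sd > 0) {
    out <- out + rnorm(length(out), 0, gaussian_sd)
  }
  out
}

#' Destroy pairing between two image domains
#'
#' Takes spatially registered image pairs and returns the two domains with
#' the correspondence destroyed by a seeded random permutation of domain B
#' that leaves no pair intact (a derangement), emulating the computational
#' mixing used to build unpaired training sets from paired acquisitions.
#' The multiset of images in each domain is preserved.
#'
#' @param pairs List of length-2 lists (or a list with elements `A` and `B`
#'   of equal length).
#' @param seed Integer seed.
#' @return List with `A`, `B` (permuted), and the `permutation` used.
#' @export
make_unpaired <- function(pairs, seed = 1L) {
  if (!is.null(pairs$A) && !is.null(pairs$B)) {
    A <- pairs$A; B <- pairs$B
  } else {
    A <- lapply(pairs, `[[`, 1)
    B <- lapply(pairs, `[[`, 2)
  }
  n <- length(A)
  if (n < 2 || length(B) != n) {
    stop("need at least 2 pairs to destroy correspondence (mixing is a no-op)")
  }
  set.seed(seed)
  repeat {
    perm <- sample.int(n)
    if (!any(perm == seq_len(n))) break
  }
  list(A = A, B = B[perm], permutation = perm)
}

#' Write a phantom to disk
#'
#' One multi-page TIFF per channel plus a JSON sidecar holding the
#' configuration and the full ground-truth geometry (centerlines as
#' coordinate lists).
#'
#' @param phantom A `tg_phantom`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "tg_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$config$voxel_size
  for (ch in names(phantom$channels)) {
    vol <- as_volume(phantom$channels[[ch]], voxel_size = vs, name = ch)
    write_stack(vol, file.path(dir, paste0(ch, ".tif")), bits = 32L)
  }
  truth <- phantom$truth
  truth$cell_label_map <- NULL  # geometry is in the centerlines; labels are bulky
  ser <- list(
    config = unclass(phantom$config),
    truth = list(
      bc_centerlines = lapply(truth$bc_centerlines, function(b)
        list(points = unname(apply(b$points, 1, as.numeric, simplify = FALSE)),
             radius = as.numeric(b$radius))),
      sinusoid_centerlines = lapply(truth$sinusoid_centerlines, function(b)
        list(points = unname(apply(b$points, 1, as.numeric, simplify = FALSE)),
             radius = as.numeric(b$radius))),
      kupffer_centroids = if (is.null(truth$kupffer_centroids)) NULL else
        unname(apply(truth$kupffer_centroids, 1, as.numeric, simplify = FALSE)),
      lobule_axis = truth$lobule_axis
    )
  )
  jsonlite::write_json(ser, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
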