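# Morphometry of tubular networks (bile canaliculi, sinusoids): Otsu
# segmentation, 3D curve skeletonization, skeleton graphs with branch arc
# lengths, distance-transform radii, and profiles along the lobule
# (central-vein to portal-vein) axis.

#' Segment a tubular network channel
#'
#' Binary mask via Otsu thresholding (default) or a fixed threshold, with
#' an optional largest-connected-component filter.
#'
#' @param channel Intensity volume (3D array or `tg_volume`).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param largest_component Keep only the largest 26-connected component.
#' @return Logical 3D array. An all-background result warns but is allowed.
#' @export
segment_network <- function(channel, method = c("otsu", "fixed"),
                            threshold = NULL, largest_component = FALSE) {
  method <- match.arg(method)
  data <- if (inherits(channel, "tg_volume")) channel$data else channel
  mask <- if (method == "otsu") {
    suppressWarnings(otsu_mask(data))
  } else {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
    data > threshold
  }
  if (!any(mask)) warning("segmentation produced an empty mask")
  if (largest_component && any(mask)) {
    lab <- label_components_26(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- array(lab == which.max(sizes), dim(mask))
  }
  mask
}

# 26-connected component labelling via igraph on the voxel adjacency.
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  co <- arrayInd(idx, d)
  key <- function(z, y, x) (x - 1) * d[1] * d[2] + (y - 1) * d[1] + z
  pos <- key(co[, 1], co[, 2], co[, 3])
  lookup <- integer(prod(d))
  lookup[pos] <- seq_along(idx)
  edges <- NULL
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 | (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, 1] + offs[k, 1]; y2 <- co[, 2] + offs[k, 2]; x2 <- co[, 3] + offs[k, 3]
    ok <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    if (!any(ok)) next
    nb <- lookup[key(z2[ok], y2[ok], x2[ok])]
    hit <- nb > 0
    if (any(hit)) edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  g <- igraph::graph_from_edgelist(edges %||% matrix(integer(0), 0, 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- comp
  out
}

#' Skeletonize a tubular mask into a network graph
#'
#' Thins the mask to a one-voxel-wide curve skeleton with a
#' topology-preserving simple-point algorithm, then builds a graph whose
#' nodes are junction and endpoint voxels and whose branches are the
#' maximal skeleton paths between them. Branch arc lengths are summed
#' voxel-step distances under the (possibly anisotropic) voxel size; the
#' local tube radius at every skeleton voxel is the Euclidean distance
#' transform of the mask, in micrometres.
#'
#' @param mask Logical/0-1 3D array.
#' @param voxel_size Micrometres per axis `(z, y, x)`.
#' @return A `tg_network_graph`: list with `nodes` (voxel coords + degree),
#'   `branches` (paths, arc `length_um`), `skeleton` (mask),
#'   `radius_um` (per skeleton voxel).
#' @export
skeletonize_network <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  m <- array(as.integer(mask != 0), dim(mask))
  if (!any(m > 0)) {
    return(structure(list(nodes = data.frame(), branches = list(),
                          skeleton = array(FALSE, dim(mask)),
                          radius_um = numeric(0), voxel_size = voxel_size),
                     class = "tg_network_graph"))
  }
  skel <- cpp_thin3d(m) > 0
  edt <- cpp_edt3d(array(as.numeric(mask != 0), dim(mask)), voxel_size)
  graph_from_skeleton(skel, edt, voxel_size)
}

graph_from_skeleton <- function(skel, edt, voxel_size) {
  d <- dim(skel)
  idx <- which(skel)
  co <- arrayInd(idx, d)
  n <- length(idx)
  lookup <- array(0L, d)
  lookup[idx] <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # neighbour lists (26-connectivity)
  nb <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, 1] + offs[k, 1]; y2 <- co[, 2] + offs[k, 2]; x2 <- co[, 3] + offs[k, 3]
    ok <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    hit <- integer(n)
    hit[ok] <- lookup[cbind(z2[ok], y2[ok], x2[ok])]
    for (i in which(hit > 0)) nb[[i]] <- c(nb[[i]], hit[i])
  }
  deg <- lengths(nb)
  is_node <- deg != 2L
  if (!any(is_node)) is_node[1] <- TRUE  # pure loop: anchor one node
  node_ids <- which(is_node)

  step_len <- function(i, j) {
    sqrt(sum(((co[i, ] - co[j, ]) * voxel_size)^2))
  }
  branches <- list()
  visited_edge <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (v in node_ids) {
    for (w in nb[[v]]) {
      if (!is.null(visited_edge[[ekey(v, w)]])) next
      path <- c(v, w)
      visited_edge[[ekey(v, w)]] <- TRUE
      prev <- v; cur <- w
      while (!is_node[cur]) {
        nxt <- setdiff(nb[[cur]], prev)
        if (!length(nxt)) break  # dead end mid-path (should be a node)
        nxt <- nxt[1]
        visited_edge[[ekey(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      len <- sum(vapply(seq_len(length(path) - 1),
                        function(s) step_len(path[s], path[s + 1]), numeric(1)))
      branches[[length(branches) + 1]] <- list(
        path = co[path, , drop = FALSE], voxel_ids = path,
        ends = c(path[1], path[length(path)]), length_um = len
      )
    }
  }
  nodes <- data.frame(id = node_ids, z = co[node_ids, 1], y = co[node_ids, 2],
                      x = co[node_ids, 3], degree = deg[node_ids])
  structure(list(nodes = nodes, branches = branches, skeleton = skel,
                 radius_um = edt[idx], skel_coords = co,
                 voxel_size = voxel_size),
            class = "tg_network_graph")
}

#' @export
print.tg_network_graph <- function(x, ...) {
  cat("<tg_network_graph> ", length(x$branches), " branches, ",
      nrow(x$nodes), " nodes (",
      sum(x$nodes$degree == 1), " endpoints, ",
      sum(x$nodes$degree > 2), " junctions)\n", sep = "")
  invisible(x)
}

#' Prune short spur branches
#'
#' Removes terminal branches (one endpoint of degree 1) shorter than a
#' cutoff, stabilizing branch statistics against skeletonization spurs on
#' noisy masks.
#'
#' @param graph A `tg_network_graph`.
#' @param cutoff_um Minimum terminal branch length to keep (default 2).
#' @return The pruned graph.
#' @export
prune_spurs <- function(graph, cutoff_um = 2) {
  if (!length(graph$branches)) return(graph)
  deg_of <- function(id) {
    r <- graph$nodes$degree[match(id, graph$nodes$id)]
    ifelse(is.na(r), 2L, r)
  }
  keep <- vapply(graph$branches, function(b) {
    terminal <- any(deg_of(b$ends) == 1L)
    !(terminal && b$length_um < cutoff_um)
  }, logical(1))
  graph$branches <- graph$branches[keep]
  graph
}

#' Radius statistics of a skeletonized network
#'
#' The local radius at each skeleton voxel is the Euclidean distance
#' transform of the segmentation mask sampled on the skeleton (micrometre
#' units); reported as the full distribution plus its mean.
#'
#' @param graph A `tg_network_graph` (non-empty).
#' @return List: `radii_um` (per skeleton voxel), `mean_radius_um`,
#'   `median_radius_um`.
#' @export
radius_stats <- function(graph) {
  if (!length(graph$radius_um)) stop("empty network graph")
  list(radii_um = graph$radius_um,
       mean_radius_um = mean(graph$radius_um),
       median_radius_um = median(graph$radius_um))
}

#' Branch-length statistics
#'
#' @param graph A `tg_network_graph` with at least one branch.
#' @param prune_um Spur-pruning cutoff applied first; `0` disables.
#' @return List: `lengths_um`, `mean_length_um`, `n_branches`.
#' @export
branch_length_stats <- function(graph, prune_um = 0) {
  if (prune_um > 0) graph <- prune_spurs(graph, prune_um)
  if (!length(graph$branches)) stop("empty network graph")
  len <- vapply(graph$branches, `[[`, numeric(1), "length_um")
  list(lengths_um = len, mean_length_um = mean(len), n_branches = length(len))
}

#' Profile a quantity along the lobule (CV-PV) axis
#'
#' Projects spatially localized samples onto a tissue axis (for liver, the
#' central-vein to portal-vein direction), normalizes the projected
#' coordinate to `[0, 1]` between the axis endpoints, and reports per-bin
#' means and standard deviations — the spatial-variability readout for
#' radius and branch length.
#'
#' @param quantity_samples Numeric vector of per-sample values.
#' @param positions Matrix of matching voxel coordinates, columns
#'   `(z, y, x)`.
#' @param lobule_axis List with `origin` (voxel coords), unit `direction`,
#'   and `length_vox` (axis extent), as stored in a phantom's truth.
#' @param n_bins Number of bins (default 10).
#' @return Data frame of class `tg_axis_profile`: `bin_center`, `mean`,
#'   `sd` (`NA` where a bin has < 2 samples), `n`.
#' @export
profile_along_axis <- function(quantity_samples, positions, lobule_axis,
                               n_bins = 10L) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (length(quantity_samples) == 0) stop("no samples to profile")
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(quantity_samples), ncol(positions) == 3)
  dir <- lobule_axis$direction / sqrt(sum(lobule_axis$direction^2))
  t_raw <- as.numeric((sweep(positions, 2, lobule_axis$origin)) %*% dir)
  t_norm <- pmin(pmax(t_raw / lobule_axis$length_vox, 0), 1)
  bin <- pmin(floor(t_norm * n_bins) + 1L, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    v <- quantity_samples[bin == b]
    data.frame(bin_center = (b - 0.5) / n_bins,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tg_axis_profile", "data.frame")
  out
}

#' Full bile-canaliculi morphometry of an intensity channel
#'
#' Convenience wrapper: segmentation, skeletonization, radius and
#' branch-length statistics, and (if an axis is given) radius and
#' branch-length profiles along the lobule axis.
#'
#' @param channel Intensity volume.
#' @param voxel_size Micrometres per axis.
#' @param lobule_axis Optional axis description (see
#'   [profile_along_axis()]).
#' @param n_bins Bins for the axis profiles.
#' @param prune_um Spur-pruning cutoff for branch statistics.
#' @return List with `mask`, `graph`, `radius`, `branch_length`, and
#'   optionally `radius_profile`, `branch_profile`.
#' @export
morphometry <- function(channel, voxel_size = c(1, 1, 1), lobule_axis = NULL,
                        n_bins = 10L, prune_um = 2) {
  mask <- segment_network(channel)
  graph <- skeletonize_network(mask, voxel_size)
  if (!length(graph$branches)) {
    return(list(mask = mask, graph = graph, radius = NULL, branch_length = NULL))
  }
  rad <- radius_stats(graph)
  bl <- branch_length_stats(graph, prune_um = prune_um)
  out <- list(mask = mask, graph = graph, radius = rad, branch_length = bl)
  if (!is.null(lobule_axis)) {
    out$radius_profile <- profile_along_axis(
      graph$radius_um, graph$skel_coords, lobule_axis, n_bins)
    mids <- t(vapply(graph$branches, function(b)
      colMeans(b$path), numeric(3)))
    lens <- vapply(graph$branches, `[[`, numeric(1), "length_um")
    out$branch_profile <- profile_along_axis(lens, mids, lobule_axis, n_bins)
  }
  out
}
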