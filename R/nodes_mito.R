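#' Detect nodes of Ranvier along a traced axon
#'
#' Scans every traced slice (not only the sampled ones) and classifies it as
#' myelin-free when the myelin around the axon covers less than `min_cover`
#' of the angular bins about the centroid — the binned form of the 50%-ray
#' rule. A maximal run of at least `min_run` consecutive myelin-free slices
#' is one node; shorter runs are treated as segmentation dropouts and runs
#' touching either end of the trace are discarded (their gaps cannot be
#' measured). The paranodal gap is the arc distance between the flanking
#' myelinated slices (the two internode termini); the node centre is the arc
#' midpoint of the gap.
#'
#' @param vol a [label_volume()].
#' @param cl a [trace_axon()] centerline.
#' @param min_run minimum run length in slices (default 3).
#' @param n_bins angular bins for the coverage rule (default 360).
#' @param min_cover coverage fraction below which a slice counts as
#'   myelin-free (default 0.5).
#' @param index internal volume index (optional).
#' @return data.frame with one row per node: `axon_id`, `node_id`,
#'   `z_first`, `z_last`, `s_center_um`, `gap_um`.
#' @export
detect_nodes <- function(vol, cl, min_run = 3, n_bins = 360, min_cover = 0.5,
                         index = NULL) {
  pts <- cl$points
  n <- nrow(pts)
  ch <- vol$channels
  free <- logical(n)
  for (i in seq_len(n)) {
    z <- pts$z_index[i]
    my <- rbind(label_coords(vol, z, ch$myelin_offset + cl$axon_id, index),
                label_coords(vol, z, ch$decompact_offset + cl$axon_id, index))
    cov <- myelin_angular_coverage(my, c(pts$cx_um[i], pts$cy_um[i]),
                                   vol$spacing, n_bins)
    free[i] <- cov < min_cover
  }
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_run) next
    if (starts[k] == 1 || ends[k] == n) next   # boundary-touching gap
    s0 <- pts$s_um[starts[k] - 1]              # last myelinated before
    s1 <- pts$s_um[ends[k] + 1]                # first myelinated after
    out[[length(out) + 1]] <- data.frame(
      axon_id = cl$axon_id, node_id = length(out) + 1L,
      z_first = pts$z_index[starts[k]], z_last = pts$z_index[ends[k]],
      s_center_um = (s0 + s1) / 2, gap_um = s1 - s0)
  }
  if (!length(out))
    return(data.frame(axon_id = integer(), node_id = integer(),
                      z_first = integer(), z_last = integer(),
                      s_center_um = numeric(), gap_um = numeric()))
  do.call(rbind, out)
}

#' Length of a mitochondrion from its z-span
#'
#' Total length from the first slice in which the mitochondrion is in view
#' until it is no longer visible: `(last - first + 1) * dz`, in um.
#'
#' @param vol a [label_volume()].
#' @param mito_id mitochondrion instance id (channel-map offset removed).
#' @param index internal volume index (optional).
#' @return Length in um (a single-slice mitochondrion returns `dz`).
#' @export
mito_length <- function(vol, mito_id, index = NULL) {
  zs <- label_z_range(vol, vol$channels$mito_offset + mito_id, index)
  if (!length(zs)) stop("mitochondrion ", mito_id, " absent from volume")
  (zs[length(zs)] - zs[1] + 1) * spacing_um(vol$spacing)[["dz"]]
}

#' Tabulate all mitochondria with their nodal assignment
#'
#' Each mitochondrion's arc position is its z-span midpoint projected onto
#' the owning axon's centerline (the axon whose traced centroid at that
#' slice is nearest the mitochondrion's centroid). `is_nodal` flags
#' mitochondria whose arc distance to the nearest node of the same axon is
#' within `window_um` (default 10 um).
#'
#' @param vol a [label_volume()].
#' @param centerlines list of [trace_axon()] centerlines.
#' @param nodes node table from [detect_nodes()] (rows for any subset of axons).
#' @param window_um nodal window in um (default 10).
#' @param index internal volume index (optional).
#' @return data.frame: `mito_id`, `axon_id`, `z_first`, `z_last`,
#'   `length_um`, `s_um`, `node_id`, `node_dist_um`, `is_nodal`.
#' @export
mito_records <- function(vol, centerlines, nodes, window_um = 10, index = NULL) {
  ids <- mito_ids(vol)
  dz <- spacing_um(vol$spacing)[["dz"]]
  out <- list()
  for (id in ids) {
    zs <- label_z_range(vol, vol$channels$mito_offset + id, index)
    zmid <- zs[ceiling(length(zs) / 2)]
    co <- label_coords(vol, zmid, vol$channels$mito_offset + id, index)
    cc <- coords_centers_um(co, vol$spacing)
    mx <- mean(cc[, 1]); my <- mean(cc[, 2])
    best <- NULL; best_d <- Inf; best_i <- NA
    for (cl in centerlines) {
      j <- match(zmid, cl$points$z_index)
      if (is.na(j)) next
      dd <- sqrt((cl$points$cx_um[j] - mx)^2 + (cl$points$cy_um[j] - my)^2)
      if (dd < best_d) { best_d <- dd; best <- cl; best_i <- j }
    }
    if (is.null(best)) next
    s_mid <- best$points$s_um[best_i]
    nd <- nodes[nodes$axon_id == best$axon_id, , drop = FALSE]
    if (nrow(nd)) {
      k <- which.min(abs(nd$s_center_um - s_mid))
      node_id <- nd$node_id[k]
      ndist <- abs(nd$s_center_um[k] - s_mid)
    } else { node_id <- NA_integer_; ndist <- NA_real_ }
    out[[length(out) + 1]] <- data.frame(
      mito_id = id, axon_id = best$axon_id,
      z_first = zs[1], z_last = zs[length(zs)],
      length_um = (zs[length(zs)] - zs[1] + 1) * dz,
      s_um = s_mid, node_id = node_id, node_dist_um = ndist,
      is_nodal = !is.na(ndist) && ndist <= window_um)
  }
  if (!length(out))
    return(data.frame(mito_id = integer(), axon_id = integer(),
                      z_first = integer(), z_last = integer(),
                      length_um = numeric(), s_um = numeric(),
                      node_id = integer(), node_dist_um = numeric(),
                      is_nodal = logical()))
  do.call(rbind, out)
}

#' Per-node mitochondria counts and lengths
#'
#' Assigns each mitochondrion to at most one node — the nearest node of its
#' own axon, and only when the arc distance is within `window_um` — then
#' reports, per node, the count and the lengths of its mitochondria (some
#' nodes have none, others several).
#'
#' @param mitos table from [mito_records()].
#' @param nodes table from [detect_nodes()].
#' @param window_um nodal window in um (default 10).
#' @return data.frame with one row per node: `axon_id`, `node_id`, `n_mito`,
#'   `mean_length_um` (NA when empty) and a `lengths_um` list column.
#' @export
nodal_mito_stats <- function(mitos, nodes, window_um = 10) {
  out <- nodes[, c("axon_id", "node_id"), drop = FALSE]
  out$n_mito <- 0L
  out$mean_length_um <- NA_real_
  out$lengths_um <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- !is.na(mitos$node_dist_um) &
      mitos$axon_id == out$axon_id[i] &
      mitos$node_id == out$node_id[i] &
      mitos$node_dist_um <= window_um
    lens <- mitos$length_um[sel]
    out$n_mito[i] <- length(lens)
    out$lengths_um[[i]] <- lens
    if (length(lens)) out$mean_length_um[i] <- mean(lens)
  }
  out
}
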