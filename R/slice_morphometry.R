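#' Extract one axon's cross-section from a slice
#'
#' Collects the axon's in-plane voxels together with its paired compact and
#' decompacted myelin (via the channel map's id pairing). If the axon id
#' fragments into several components in the slice, the component nearest
#' `near` (in um; typically the traced centroid) is measured and the others
#' are ignored with a message; without `near`, the largest component is used.
#'
#' @param vol a [label_volume()].
#' @param axon_id axon instance id.
#' @param z slice index.
#' @param near optional c(x, y) um point used to pick among components.
#' @param index internal volume index (optional).
#' @return An object of class `cross_section` with voxel index sets `axon`,
#'   `myelin_c`, `myelin_d` (Nx2, columns y, x), `centroid_um`, `spacing`.
#' @export
cross_section <- function(vol, axon_id, z, near = NULL, index = NULL) {
  co <- label_coords(vol, z, axon_id, index)
  if (is.null(co)) stop("axon ", axon_id, " absent from slice ", z)
  comp <- mask_components(co)
  ncomp <- max(comp)
  if (ncomp > 1L) {
    if (!is.null(near)) {
      cent <- vapply(seq_len(ncomp), function(k) {
        cc <- coords_centers_um(co[comp == k, , drop = FALSE], vol$spacing)
        sqrt((mean(cc[, 1]) - near[1])^2 + (mean(cc[, 2]) - near[2])^2)
      }, 1)
      keep <- which.min(cent)
    } else keep <- which.max(tabulate(comp))
    message(sprintf("axon %d slice %d: %d fragment(s) ignored", axon_id, z, ncomp - 1L))
    co <- co[comp == keep, , drop = FALSE]
  }
  cc <- coords_centers_um(co, vol$spacing)
  structure(list(
    axon_id = axon_id, z_index = z,
    axon = co,
    myelin_c = label_coords(vol, z, vol$channels$myelin_offset + axon_id, index),
    myelin_d = label_coords(vol, z, vol$channels$decompact_offset + axon_id, index),
    centroid_um = c(mean(cc[, 1]), mean(cc[, 2])),
    spacing = vol$spacing), class = "cross_section")
}

#' Cross-sectional area of an axon section
#'
#' Voxel count times in-plane pixel area, in um^2.
#'
#' @param cs a [cross_section()].
#' @return Area in um^2.
#' @export
cross_sectional_area <- function(cs) {
  if (is.null(cs$axon) || nrow(cs$axon) == 0) stop("empty axon mask")
  sp <- spacing_um(cs$spacing)
  nrow(cs$axon) * sp[["dx"]] * sp[["dy"]]
}

#' Minimum caliper (Feret) diameter of a planar mask
#'
#' The smallest width of the mask over all orientations, computed by
#' rotating calipers on the convex hull of the voxel-corner points (so a
#' single voxel returns `min(dx, dy)`). This is the obliquity-robust
#' "minimum diameter" convention: the minimum caliper width of an ellipse
#' equals its minor axis, so a cylinder sectioned obliquely still reports
#' its true diameter.
#'
#' @param mask logical matrix, or Nx2 integer matrix of (y, x) voxel indices.
#' @param spacing a [voxel_spacing()].
#' @return Width in um.
#' @export
min_caliper_diameter <- function(mask, spacing = voxel_spacing()) {
  coords <- as_coords(mask)
  if (is.null(coords) || nrow(coords) == 0) stop("empty mask")
  pts <- mask_corners_um(coords, spacing)
  hull_min_width(pts)
}

as_coords <- function(mask) {
  if (is.logical(mask) || (is.matrix(mask) && !is.null(dim(mask)) &&
                           all(mask %in% c(0, 1)) && ncol(mask) != 2)) {
    w <- which(mask != 0)
    if (!length(w)) return(NULL)
    co <- arrayInd(w, dim(mask))
    colnames(co) <- c("y", "x")
    return(co)
  }
  mask
}

# corner points (um) of every voxel in a coordinate set
mask_corners_um <- function(coords, spacing) {
  sp <- spacing_um(spacing)
  x0 <- (coords[, 2] - 1) * sp[["dx"]]; x1 <- coords[, 2] * sp[["dx"]]
  y0 <- (coords[, 1] - 1) * sp[["dy"]]; y1 <- coords[, 1] * sp[["dy"]]
  cbind(x = c(x0, x1, x0, x1), y = c(y0, y0, y1, y1))
}

# minimum width of a point set: the minimum over convex-hull edges of the
# projection span onto the edge normal (the minimum width of a convex
# polygon is attained flush with one of its edges)
hull_min_width <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) stop("degenerate mask (collinear hull)")
  e <- hp[c(2:n, 1), ] - hp
  len <- sqrt(rowSums(e^2))
  ok <- len > 0
  nx <- -e[ok, 2] / len[ok]; ny <- e[ok, 1] / len[ok]
  proj <- hp %*% rbind(nx, ny)       # n_vertices x n_edges
  min(apply(proj, 2, max) - apply(proj, 2, min))
}

# code matrix over the section bounding box: 1 axon, 2 compact, 3 decompacted
section_code_matrix <- function(cs) {
  all <- rbind(cs$axon, cs$myelin_c, cs$myelin_d)
  ry <- range(all[, 1]); rx <- range(all[, 2])
  m <- matrix(0L, ry[2] - ry[1] + 1, rx[2] - rx[1] + 1)
  put <- function(co, code) {
    if (!is.null(co) && nrow(co))
      m[cbind(co[, 1] - ry[1] + 1, co[, 2] - rx[1] + 1)] <<- code
  }
  put(cs$axon, 1L); put(cs$myelin_c, 2L); put(cs$myelin_d, 3L)
  list(m = m, y0 = ry[1] - 1L, x0 = rx[1] - 1L)
}

# march n_rays rays from the centroid; per ray: myelin intersection length
# (um), whether any decompacted voxel is crossed, whether any myelin at all
ray_profile <- function(cs, n_rays = 360) {
  if (n_rays < 90) stop("n_rays must be >= 90")
  if (is.null(cs$axon) || nrow(cs$axon) == 0) stop("empty axon mask")
  sp <- spacing_um(cs$spacing)
  dx <- sp[["dx"]]; dy <- sp[["dy"]]
  step <- 0.25 * min(dx, dy)
  cm <- section_code_matrix(cs)
  nr <- nrow(cm$m); nc <- ncol(cm$m)
  cx <- cs$centroid_um[1]; cy <- cs$centroid_um[2]
  corners_x <- c(cm$x0, cm$x0 + nc) * dx
  corners_y <- c(cm$y0, cm$y0 + nr) * dy
  r_max <- sqrt(max(abs(corners_x - cx))^2 + max(abs(corners_y - cy))^2) + 2 * step
  ang <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  rad <- seq(step / 2, r_max, by = step)
  X <- cx + outer(cos(ang), rad)
  Y <- cy + outer(sin(ang), rad)
  ix <- ceiling(X / dx) - cm$x0
  iy <- ceiling(Y / dy) - cm$y0
  ok <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
  code <- matrix(0L, n_rays, length(rad))
  code[ok] <- cm$m[cbind(iy[ok], ix[ok])]
  myel <- code == 2L | code == 3L
  list(len = rowSums(myel) * step,
       has_myelin = rowSums(myel) > 0,
       has_decompact = rowSums(code == 3L) > 0)
}

#' Minimum myelin thickness by centroid ray-casting
#'
#' Casts `n_rays` rays at uniform angles from the axon centroid and measures,
#' per ray, the length of its intersection with myelin (compact plus
#' decompacted). Returns the minimum over rays that intersect myelin —
#' implementing the minimum-thickness convention — or 0 when fewer than
#' `min_cover` of the rays meet myelin (a nodal slice rather than a
#' segmentation dropout).
#'
#' @param cs a [cross_section()].
#' @param n_rays number of rays (>= 90, default 360).
#' @param min_cover minimum fraction of rays intersecting myelin for the
#'   sheath to count as present (default 0.5).
#' @return Thickness in um (0 on nodal slices).
#' @export
myelin_thickness <- function(cs, n_rays = 360, min_cover = 0.5) {
  rp <- ray_profile(cs, n_rays)
  if (mean(rp$has_myelin) < min_cover) return(0)
  min(rp$len[rp$has_myelin])
}

#' Percent of the myelinated circumference that is decompacted
#'
#' Fraction of rays whose myelin intersection contains at least one
#' decompacted voxel, among rays intersecting any myelin, times 100. Scoring
#' over the myelin-bearing rays (rather than all angles) means a partial
#' wrap next to a node is scored over its actual circumference.
#'
#' @inheritParams myelin_thickness
#' @return Percent in \[0, 100\]; 0 when no ray meets myelin.
#' @export
decompaction_percent <- function(cs, n_rays = 360) {
  rp <- ray_profile(cs, n_rays)
  denom <- sum(rp$has_myelin)
  if (denom == 0) return(0)
  100 * sum(rp$has_decompact) / denom
}

#' Fiber (axon + myelin) diameter
#'
#' Minimum caliper diameter of the union of the axon and both myelin masks;
#' equals the axon diameter exactly when myelin is absent. Set
#' `additive = TRUE` for the alternative reading axon diameter +
#' 2 x myelin thickness.
#'
#' @param cs a [cross_section()].
#' @param additive use axon_diameter + 2*thickness instead of a caliper of
#'   the whole fiber.
#' @param n_rays rays for the additive thickness (ignored otherwise).
#' @return Diameter in um.
#' @export
fiber_diameter <- function(cs, additive = FALSE, n_rays = 360) {
  if (is.null(cs$axon) || nrow(cs$axon) == 0) stop("empty axon mask")
  if (additive)
    return(min_caliper_diameter(cs$axon, cs$spacing) +
             2 * myelin_thickness(cs, n_rays))
  min_caliper_diameter(rbind(cs$axon, cs$myelin_c, cs$myelin_d), cs$spacing)
}

#' G-ratio
#'
#' Axon diameter divided by fiber diameter; in (0, 1].
#'
#' @param axon_diameter,fiber_diameter diameters in um.
#' @return Unitless ratio.
#' @export
g_ratio <- function(axon_diameter, fiber_diameter) {
  if (any(fiber_diameter <= 0)) stop("fiber diameter must be positive")
  if (any(axon_diameter > fiber_diameter + 1e-9))
    stop("axon diameter exceeds fiber diameter")
  pmin(axon_diameter / fiber_diameter, 1)
}

#' All per-slice measurements for one cross-section
#'
#' @param cs a [cross_section()].
#' @param n_rays rays for thickness/decompaction (default 360).
#' @return One-row data.frame: `axon_id`, `z_index`, `area_um2`,
#'   `axon_diameter_um`, `myelin_thickness_um`, `fiber_diameter_um`,
#'   `g_ratio`, `decompaction_pct`.
#' @export
measure_cross_section <- function(cs, n_rays = 360) {
  ad <- min_caliper_diameter(cs$axon, cs$spacing)
  fd <- fiber_diameter(cs)
  rp <- ray_profile(cs, n_rays)
  th <- if (mean(rp$has_myelin) < 0.5) 0 else min(rp$len[rp$has_myelin])
  dp <- if (sum(rp$has_myelin) == 0) 0 else 100 * sum(rp$has_decompact) / sum(rp$has_myelin)
  data.frame(axon_id = cs$axon_id, z_index = cs$z_index,
             area_um2 = cross_sectional_area(cs),
             axon_diameter_um = ad,
             myelin_thickness_um = th,
             fiber_diameter_um = fd,
             g_ratio = g_ratio(ad, fd),
             decompaction_pct = dp)
}

# fraction of angular bins around a centroid containing myelin voxel centres;
# the binned form of the 50%-ray rule used by the full-stack node scan
myelin_angular_coverage <- function(myelin_coords, centroid_um, spacing,
                                    n_bins = 360) {
  if (is.null(myelin_coords) || nrow(myelin_coords) == 0) return(0)
  cc <- coords_centers_um(myelin_coords, spacing)
  a <- atan2(cc[, 2] - centroid_um[2], cc[, 1] - centroid_um[1])
  b <- floor((a + pi) / (2 * pi) * n_bins)
  b[b >= n_bins] <- n_bins - 1L
  length(unique(b)) / n_bins
}
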