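#' Trace an axon's centerline through the stack
#'
#' Follows one axon instance slice by slice from the first section in which
#' it appears until it leaves the stack, taking the in-plane area centroid of
#' the axon's linked component in every slice. When a slice holds several
#' components with the axon's id, the component with the largest voxel
#' overlap with the previous slice's component is followed; slices with no
#' overlapping component are tolerated up to `max_gap` in a row, after which
#' the trace is terminated with a warning.
#'
#' Arc length is accumulated from consecutive 3D centroid distances in um,
#' so for tilted or tortuous axons the measured length exceeds the z-extent.
#'
#' @param vol a [label_volume()].
#' @param axon_id axon instance id.
#' @param max_gap tolerated consecutive slices without an overlapping
#'   component (segmentation dropouts), default 2.
#' @param index internal volume index (optional, for reuse).
#' @return An object of class `centerline`: `points` data.frame
#'   (`z_index`, `cx_um`, `cy_um`, `s_um`), `measured_length` (um),
#'   `z_extent`, `axon_id`, `dz_um`.
#' @export
trace_axon <- function(vol, axon_id, max_gap = 2, index = NULL) {
  zs <- label_z_range(vol, axon_id, index)
  if (length(zs) < 2L)
    stop("axon ", axon_id, " absent or present in fewer than 2 slices")
  d1 <- dim(vol$stack)[1]
  sp <- spacing_um(vol$spacing)

  z <- zs[1]
  co <- label_coords(vol, z, axon_id, index)
  comp <- mask_components(co)
  pick <- which(comp == which.max(tabulate(comp)))
  co <- co[pick, , drop = FALSE]
  prev_keys <- co[, 1] + (co[, 2] - 1) * d1

  rec_z <- z
  rec_cx <- mean(co[, 2] - 0.5) * sp[["dx"]]
  rec_cy <- mean(co[, 1] - 0.5) * sp[["dy"]]
  gap <- 0L
  zmax <- zs[length(zs)]
  z <- z + 1L
  while (z <= zmax) {
    co <- label_coords(vol, z, axon_id, index)
    chosen <- NULL
    if (!is.null(co)) {
      comp <- mask_components(co)
      keys <- co[, 1] + (co[, 2] - 1) * d1
      ov <- tapply(keys %in% prev_keys, comp, sum)
      if (max(ov) > 0) {
        best <- as.integer(names(ov)[which.max(ov)])
        chosen <- co[comp == best, , drop = FALSE]
      }
    }
    if (is.null(chosen)) {
      gap <- gap + 1L
      if (gap > max_gap) {
        warning(sprintf("axon %d: trace terminated at slice %d (gap > %d slices)",
                        axon_id, z, max_gap))
        break
      }
    } else {
      gap <- 0L
      rec_z <- c(rec_z, z)
      rec_cx <- c(rec_cx, mean(chosen[, 2] - 0.5) * sp[["dx"]])
      rec_cy <- c(rec_cy, mean(chosen[, 1] - 0.5) * sp[["dy"]])
      prev_keys <- chosen[, 1] + (chosen[, 2] - 1) * d1
    }
    z <- z + 1L
  }

  if (length(rec_z) < 2L)
    stop("axon ", axon_id, ": could not link 2 consecutive slices")
  cz <- (rec_z - 0.5) * sp[["dz"]]
  seg <- sqrt(diff(rec_cx)^2 + diff(rec_cy)^2 + diff(cz)^2)
  s <- c(0, cumsum(seg))
  # the centroid polyline joins slice centres; the terminal half-slices are
  # part of the traced extent, so the measured length adds one dz (a straight
  # tube spanning n slices then measures exactly n * dz)
  structure(list(
    axon_id = axon_id,
    points = data.frame(z_index = rec_z, cx_um = rec_cx, cy_um = rec_cy, s_um = s),
    measured_length = s[length(s)] + sp[["dz"]],
    z_extent = c(rec_z[1], rec_z[length(rec_z)]),
    dz_um = sp[["dz"]]), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: axon %d, slices %d-%d, measured length %.2f um\n",
              x$axon_id, x$z_extent[1], x$z_extent[2], x$measured_length))
  invisible(x)
}

#' Slice indices at regular arc-length intervals along a centerline
#'
#' Returns the slices nearest to arc positions 0, interval, 2*interval, ...
#' up to the measured length, mirroring measurement of 2D images at fixed
#' (default 5 um) intervals along each axon. Position 0 (the first traced
#' slice) is always included; duplicate slices are collapsed, so the result
#' is strictly increasing.
#'
#' @param cl a [trace_axon()] centerline.
#' @param interval_um sampling interval in um along the arc (default 5).
#' @return Integer vector of z indices.
#' @export
sample_positions <- function(cl, interval_um = 5) {
  if (!is.numeric(interval_um) || interval_um <= 0)
    stop("interval_um must be positive")
  if (interval_um < cl$dz_um)
    stop(sprintf("interval %.3g um is below the slice thickness %.3g um and cannot be resolved",
                 interval_um, cl$dz_um))
  targets <- seq(0, cl$measured_length, by = interval_um)
  s <- cl$points$s_um
  idx <- vapply(targets, function(t) which.min(abs(s - t)), 1L)
  cl$points$z_index[idx[!duplicated(idx)]]
}
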