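# Internal per-slice index of nonzero voxels, split by raw label.
# Built once per volume by the pipeline functions so that tracing, the
# full-stack node scan and sampled-slice morphometry each avoid rescanning
# the 3D array.

volume_index <- function(vol) {
  d <- dim(vol$stack)
  slices <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    sl <- vol$stack[, , z]
    w <- which(sl != 0L)
    if (!length(w)) { slices[[z]] <- list(); next }
    labs <- sl[w]
    yx <- arrayInd(w, d[1:2])
    sp <- split(seq_along(w), labs)
    slices[[z]] <- lapply(sp, function(i)
      cbind(y = yx[i, 1], x = yx[i, 2], deparse.level = 0))
  }
  structure(list(slices = slices, dim = d), class = "volume_index")
}

# coords (Nx2 matrix, columns y, x) of one raw label in one slice; NULL if absent
label_coords <- function(vol, z, label, index = NULL) {
  if (!is.null(index)) {
    co <- index$slices[[z]][[as.character(label)]]
    if (is.null(co)) return(NULL)
    colnames(co) <- c("y", "x")
    return(co)
  }
  sl <- vol$stack[, , z]
  w <- which(sl == label)
  if (!length(w)) return(NULL)
  co <- arrayInd(w, dim(vol$stack)[1:2])
  colnames(co) <- c("y", "x")
  co
}

# slices (sorted) in which a raw label occurs
label_z_range <- function(vol, label, index = NULL) {
  if (!is.null(index)) {
    key <- as.character(label)
    which(vapply(index$slices, function(s) !is.null(s[[key]]), TRUE))
  } else {
    d <- dim(vol$stack)
    which(vapply(seq_len(d[3]), function(z) any(vol$stack[, , z] == label), TRUE))
  }
}

# 2D connected components (8-connectivity) of a coordinate set, via EBImage
# on the bounding-box submask; returns a component id per input row
mask_components <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(1L)
  ry <- range(coords[, 1]); rx <- range(coords[, 2])
  m <- matrix(0, ry[2] - ry[1] + 1, rx[2] - rx[1] + 1)
  m[cbind(coords[, 1] - ry[1] + 1, coords[, 2] - rx[1] + 1)] <- 1
  lab <- EBImage::bwlabel(m)
  as.integer(lab[cbind(coords[, 1] - ry[1] + 1, coords[, 2] - rx[1] + 1)])
}

# voxel-centre coordinates in um
coords_centers_um <- function(coords, spacing) {
  sp <- spacing_um(spacing)
  cbind(x = (coords[, 2] - 0.5) * sp[["dx"]],
        y = (coords[, 1] - 0.5) * sp[["dy"]])
}
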