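NM_PER_UM <- 1000

#' Voxel spacing of an SBF-SEM stack
#'
#' Anisotropic voxel dimensions in nanometres. The defaults are the common
#' acquisition geometry for serial block-face imaging of optic nerve:
#' 5 nm/pixel in-plane and 50 nm cutting increments, so a 2000-slice stack
#' spans 100 um in z.
#'
#' @param dx,dy in-plane pixel size, nm.
#' @param dz slice thickness (cutting increment), nm.
#' @return An object of class `voxel_spacing`.
#' @export
voxel_spacing <- function(dx = 5, dy = 5, dz = 50) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("voxel spacing components must be strictly positive finite numbers")
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = %g nm, dy = %g nm, dz = %g nm\n",
              x$dx, x$dy, x$dz))
  invisible(x)
}

# spacing in um, as a plain named vector
spacing_um <- function(spacing) {
  c(dx = spacing$dx, dy = spacing$dy, dz = spacing$dz) / NM_PER_UM
}

#' Semantic label-id layout of a label volume
#'
#' All semantic classes live in a single integer stack, distinguished by
#' label ranges. Axon instances carry ids `1..axon_max`; the compact and
#' decompacted myelin of axon `i` carry `myelin_offset + i` and
#' `decompact_offset + i` (explicit axon-myelin pairing); mitochondrion
#' instance `k` carries `mito_offset + k`.
#'
#' @param axon_max largest permitted axon instance id.
#' @param myelin_offset,decompact_offset,mito_offset range offsets.
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(axon_max = 999, myelin_offset = 1000,
                        decompact_offset = 2000, mito_offset = 3000) {
  if (axon_max < 1) stop("axon_max must be >= 1")
  offs <- c(0, myelin_offset, decompact_offset, mito_offset)
  if (any(diff(offs) < axon_max + 1))
    stop("channel ranges overlap: offsets must be spaced by more than axon_max")
  structure(list(axon_max = axon_max, myelin_offset = myelin_offset,
                 decompact_offset = decompact_offset, mito_offset = mito_offset),
            class = "channel_map")
}

# semantic class of raw label values under a channel map
label_class <- function(labels, channels) {
  cls <- rep("background", length(labels))
  cls[labels >= 1 & labels <= channels$axon_max] <- "axon"
  cls[labels > channels$myelin_offset &
        labels <= channels$myelin_offset + channels$axon_max] <- "myelin"
  cls[labels > channels$decompact_offset &
        labels <= channels$decompact_offset + channels$axon_max] <- "decompact"
  cls[labels > channels$mito_offset] <- "mito"
  cls
}

#' Construct a label volume
#'
#' @param stack 3D integer array indexed `[y, x, z]` (1-based; slice `z` is
#'   `stack[, , z]`). Label 0 is background. The physical centre of voxel
#'   `(iy, ix, iz)` is `((ix - 0.5) dx, (iy - 0.5) dy, (iz - 0.5) dz)`.
#' @param spacing a [voxel_spacing()].
#' @param channels a [channel_map()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(stack, spacing = voxel_spacing(),
                         channels = channel_map()) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3D array indexed [y, x, z]")
  if (is.double(stack)) {
    if (any(stack != floor(stack)) || any(stack < 0))
      stop("stack must contain non-negative integer labels")
    storage.mode(stack) <- "integer"
  }
  if (!is.integer(stack)) stop("stack must be integer-valued")
  stopifnot(inherits(spacing, "voxel_spacing"), inherits(channels, "channel_map"))
  structure(list(stack = stack, spacing = spacing, channels = channels),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$stack)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$stack)
  ext <- volume_extent_um(x)
  cat(sprintf("label_volume: %d x %d px, %d slices (%.2f x %.2f x %.2f um)\n",
              d[2], d[1], d[3], ext["x"], ext["y"], ext["z"]))
  ids <- axon_ids(x)
  cat(sprintf("  axon instances: %d%s\n", length(ids),
              if (length(ids)) paste0(" (", paste(utils::head(ids, 10), collapse = ","),
                                      if (length(ids) > 10) ",..." else "", ")") else ""))
  invisible(x)
}

#' Physical extent of a volume in micrometres
#'
#' @param x a `label_volume`, or a dimension vector `c(ny, nx, nz)`.
#' @param spacing a [voxel_spacing()]; taken from `x` when `x` is a volume.
#' @return Named vector `c(x =, y =, z =)` in um.
#' @export
volume_extent_um <- function(x, spacing = voxel_spacing()) {
  if (inherits(x, "label_volume")) {
    d <- dim(x$stack); spacing <- x$spacing
  } else d <- x
  sp <- spacing_um(spacing)
  c(x = d[2] * sp[["dx"]], y = d[1] * sp[["dy"]], z = d[3] * sp[["dz"]])
}

#' Axon instance ids present in a volume
#' @param vol a `label_volume`.
#' @return Sorted integer vector of axon ids.
#' @export
axon_ids <- function(vol) {
  u <- unique(as.vector(vol$stack))
  sort(u[u >= 1 & u <= vol$channels$axon_max])
}

#' Mitochondrion instance ids present in a volume
#' @param vol a `label_volume`.
#' @return Sorted integer vector of mitochondrion instance ids (offset removed).
#' @export
mito_ids <- function(vol) {
  u <- unique(as.vector(vol$stack))
  as.integer(sort(u[u > vol$channels$mito_offset]) - vol$channels$mito_offset)
}

#' Read a label volume from a multi-page TIFF
#'
#' Slices must share one shape and hold integer labels (16- or 32-bit).
#'
#' @param path TIFF file, one integer label image per z-slice.
#' @param spacing a [voxel_spacing()].
#' @param channels a [channel_map()].
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, spacing = voxel_spacing(),
                              channels = channel_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent slice shapes in ", path, ": ", paste(unique(shapes), collapse = ", "))
  if (!all(vapply(pages, is.integer, TRUE)))
    stop("non-integer pixel data in ", path, " (label volumes must be integer TIFFs)")
  d <- dim(pages[[1]])
  stack <- array(0L, c(d[1], d[2], length(pages)))
  for (z in seq_along(pages)) stack[, , z] <- pages[[z]]
  vol <- label_volume(stack, spacing, channels)
  message(sprintf("read %s: %d x %d px, %d slices", path, d[2], d[1], length(pages)))
  vol
}

#' Write a label volume to a multi-page 16-bit TIFF
#'
#' @param vol a [label_volume()]; all labels must be < 65536.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  mx <- max(vol$stack)
  if (mx > 65535L) stop("labels exceed 16-bit TIFF range")
  nz <- dim(vol$stack)[3]
  pages <- lapply(seq_len(nz), function(z) vol$stack[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Read a flat key-value analysis configuration
#'
#' Parses a plain-text file of `key = value` lines (comments start with
#' `#`). Recognized keys: `dx`, `dy`, `dz` (nm), `axon_max`,
#' `myelin_offset`, `decompact_offset`, `mito_offset`, and the analysis
#' parameters `interval_um`, `n_rays`, `threshold_pct`, `nodal_window_um`,
#' `min_node_run`, `seed`; missing keys fall back to package defaults.
#'
#' @param path config file.
#' @return List with `spacing` (a [voxel_spacing()]), `channels`
#'   (a [channel_map()]) and the analysis parameters.
#' @export
read_morph_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2)))),
                          trimws(vapply(kv, `[`, "", 1)))
  if (anyNA(vals)) stop("non-numeric config value for: ",
                        paste(names(vals)[is.na(vals)], collapse = ", "))
  g <- function(key, default) if (key %in% names(vals)) unname(vals[[key]]) else default
  list(spacing = voxel_spacing(g("dx", 5), g("dy", 5), g("dz", 50)),
       channels = channel_map(g("axon_max", 999), g("myelin_offset", 1000),
                              g("decompact_offset", 2000), g("mito_offset", 3000)),
       interval_um = g("interval_um", 5), n_rays = g("n_rays", 360),
       threshold_pct = g("threshold_pct", 40),
       nodal_window_um = g("nodal_window_um", 10),
       min_node_run = g("min_node_run", 3), seed = g("seed", 1))
}

METRIC_UNITS <- c(area_um2 = "um^2", axon_diameter_um = "um",
                  myelin_thickness_um = "um", fiber_diameter_um = "um",
                  g_ratio = "unitless", decompaction_pct = "percent",
                  s_um = "um", gap_um = "um", length_um = "um",
                  decompaction_score = "per_um")

#' Assemble a long-format measurement table
#'
#' One row per (axon_id, z_index, metric); units are fixed per metric.
#'
#' @param axon_id,z_index,metric,value parallel vectors.
#' @param units units per row; defaults looked up from the metric name.
#' @return A `data.frame` of class `measurement_table`.
#' @export
measurement_table <- function(axon_id, z_index, metric, value, units = NULL) {
  if (is.null(units)) {
    units <- unname(METRIC_UNITS[metric])
    units[is.na(units)] <- "unknown"
  }
  tab <- data.frame(axon_id = as.integer(axon_id), z_index = as.integer(z_index),
                    metric = as.character(metric), value = as.numeric(value),
                    units = as.character(units), stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

validate_measurement_table <- function(tab) {
  need <- c("axon_id", "z_index", "metric", "value", "units")
  if (!all(need %in% names(tab)))
    stop("measurement table must have columns ", paste(need, collapse = ", "))
  key <- paste(tab$axon_id, tab$z_index, tab$metric)
  if (anyDuplicated(key))
    stop("duplicate (axon_id, z_index, metric) rows in measurement table")
  bad <- tapply(tab$units, tab$metric, function(u) length(unique(u)) > 1)
  if (any(bad)) stop("mixed units for metric(s): ",
                     paste(names(bad)[bad], collapse = ", "))
  invisible(tab)
}

#' Write a measurement table to CSV
#'
#' Rows are ordered by axon_id, then z_index, then metric name, so output is
#' deterministic; a read-back with [read_measurements()] reproduces the table.
#'
#' @param tab a [measurement_table()] (or compatible data.frame).
#' @param path output CSV file.
#' @param allow_empty permit writing a header-only file.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tab, path, allow_empty = FALSE) {
  validate_measurement_table(tab)
  if (nrow(tab) == 0 && !allow_empty)
    stop("refusing to write an empty measurement table (set allow_empty = TRUE)")
  tab <- tab[order(tab$axon_id, tab$z_index, tab$metric), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV file.
#' @return A `measurement_table`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(axon_id = "integer", z_index = "integer",
                                        metric = "character", value = "numeric",
                                        units = "character"))
  validate_measurement_table(tab)
  class(tab) <- c("measurement_table", "data.frame")
  tab
}
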