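#' Measure one axon along its length
#'
#' Traces the axon, samples slices at fixed arc-length intervals (default
#' 5 um) and measures every sampled cross-section, assembling a longitudinal
#' profile.
#'
#' @param vol a [label_volume()].
#' @param axon_id axon instance id.
#' @param interval_um sampling interval along the arc, um.
#' @param n_rays rays for thickness/decompaction.
#' @param max_gap tracing gap tolerance, slices.
#' @param group,animal optional cohort labels carried on the profile.
#' @param index internal volume index (optional).
#' @return An object of class `axon_profile`: `measurements` data.frame (one
#'   row per sampled slice, with arc position `s_um`), `measured_length`,
#'   `centerline`, `axon_id`, `group`, `animal`.
#' @export
measure_axon <- function(vol, axon_id, interval_um = 5, n_rays = 360,
                         max_gap = 2, group = NA_character_,
                         animal = NA_integer_, index = NULL) {
  cl <- trace_axon(vol, axon_id, max_gap = max_gap, index = index)
  zs <- sample_positions(cl, interval_um)
  rows <- lapply(zs, function(z) {
    i <- match(z, cl$points$z_index)
    cs <- cross_section(vol, axon_id, z,
                        near = c(cl$points$cx_um[i], cl$points$cy_um[i]),
                        index = index)
    cbind(measure_cross_section(cs, n_rays), s_um = cl$points$s_um[i])
  })
  m <- do.call(rbind, rows)
  structure(list(axon_id = axon_id, group = group, animal = animal,
                 measurements = m, measured_length = cl$measured_length,
                 centerline = cl),
            class = "axon_profile")
}

#' @export
print.axon_profile <- function(x, ...) {
  cat(sprintf("axon_profile: axon %d, %d samples over %.2f um\n",
              x$axon_id, nrow(x$measurements), x$measured_length))
  invisible(x)
}

profile_metrics <- c("area_um2", "axon_diameter_um", "myelin_thickness_um",
                     "fiber_diameter_um", "g_ratio", "decompaction_pct")

metric_values <- function(profile, metric) {
  m <- if (inherits(profile, "axon_profile")) profile$measurements else profile
  if (!metric %in% names(m))
    stop("unknown metric '", metric, "' (have: ", paste(names(m), collapse = ", "), ")")
  m[[metric]]
}

#' Range of a metric along one axon
#'
#' Maximum minus minimum of the metric over the sampled slices — the
#' intra-axonal variability index (e.g. per-slice areas with max 12.30 and
#' min 1.04 um^2 give a range of 11.26 um^2).
#'
#' @param profile an [measure_axon()] profile, or a measurements data.frame.
#' @param metric column name, e.g. `"area_um2"`.
#' @return Range in the metric's units (>= 0).
#' @export
metric_range <- function(profile, metric) {
  v <- metric_values(profile, metric)
  if (length(v) < 2) stop("range needs at least 2 sampled slices")
  max(v) - min(v)
}

#' Mean of a metric along one axon
#'
#' Arithmetic mean over the sampled slices, giving a single value per axon.
#'
#' @inheritParams metric_range
#' @return Mean in the metric's units.
#' @export
profile_mean <- function(profile, metric) {
  v <- metric_values(profile, metric)
  if (length(v) < 1) stop("no samples")
  mean(v)
}

#' Decompaction point score per measured length
#'
#' Each sampled slice whose decompaction percentage strictly exceeds
#' `threshold_pct` earns one point; the score is total points divided by the
#' axon's measured length, in points per um. The comparison is strict, so a
#' slice at exactly the threshold is never counted.
#'
#' @param profile an axon profile (or measurements data.frame with attribute
#'   or argument `measured_length`).
#' @param threshold_pct threshold percentage, default 40.
#' @param measured_length length normalizer in um; taken from the profile
#'   when omitted.
#' @return Score in points per um.
#' @export
decompaction_score <- function(profile, threshold_pct = 40,
                               measured_length = NULL) {
  if (is.null(measured_length)) {
    if (!inherits(profile, "axon_profile"))
      stop("measured_length must be supplied for plain tables")
    measured_length <- profile$measured_length
  }
  if (measured_length <= 0) stop("measured length must be positive")
  v <- metric_values(profile, "decompaction_pct")
  sum(v > threshold_pct) / measured_length
}

#' Per-axon summary of a profile
#'
#' @param profile an [measure_axon()] profile.
#' @param threshold_pct decompaction threshold (default 40).
#' @return One-row data.frame: labels, sample count, measured length,
#'   mean/min/max/range of every metric, and the decompaction score.
#' @export
profile_summary <- function(profile, threshold_pct = 40) {
  m <- profile$measurements
  out <- data.frame(axon_id = profile$axon_id, group = profile$group,
                    animal = profile$animal, n_samples = nrow(m),
                    measured_length_um = profile$measured_length)
  for (met in profile_metrics) {
    v <- m[[met]]
    out[[paste0("mean_", met)]] <- mean(v)
    out[[paste0("min_", met)]] <- min(v)
    out[[paste0("max_", met)]] <- max(v)
    out[[paste0("range_", met)]] <- max(v) - min(v)
  }
  out$decompaction_score <- decompaction_score(profile, threshold_pct)
  out
}

#' Single-section 2D sampling at a fixed arc position
#'
#' Measures, for every profile that is long enough, the slice nearest the
#' given arc-length position — the single-section counterpart used to
#' compare 3D per-axon averages with isolated 2D sections (e.g. at 30, 60
#' and 90 um along the axons).
#'
#' @param vol a [label_volume()].
#' @param profiles list of [measure_axon()] profiles.
#' @param position_um arc position in um.
#' @param n_rays rays for thickness/decompaction.
#' @param index internal volume index (optional).
#' @return A [measurement_table()] in long format (one row per axon and
#'   metric); profiles shorter than `position_um` are skipped with a warning.
#' @export
single_section_sample <- function(vol, profiles, position_um, n_rays = 360,
                                  index = NULL) {
  rows <- list()
  for (p in profiles) {
    if (p$measured_length < position_um) {
      warning(sprintf("axon %d (%.1f um) shorter than position %.1f um; skipped",
                      p$axon_id, p$measured_length, position_um))
      next
    }
    cl <- p$centerline
    i <- which.min(abs(cl$points$s_um - position_um))
    z <- cl$points$z_index[i]
    cs <- cross_section(vol, p$axon_id, z,
                        near = c(cl$points$cx_um[i], cl$points$cy_um[i]),
                        index = index)
    rows[[length(rows) + 1]] <- measure_cross_section(cs, n_rays)
  }
  if (!length(rows)) stop("no profile covers position ", position_um, " um")
  wide_to_table(do.call(rbind, rows))
}

#' Measure randomly selected axons in one 2D section
#'
#' The traditional single-section approach: `n` distinct axons present at
#' slice `z_index` are drawn uniformly without replacement (reproducibly for
#' a given seed) and measured in that section only.
#'
#' @param vol a [label_volume()].
#' @param z_index slice to sample.
#' @param n number of axons.
#' @param seed RNG seed (optional; `NULL` uses the current RNG state).
#' @param n_rays rays for thickness/decompaction.
#' @param index internal volume index (optional).
#' @return A [measurement_table()], axons ordered by id.
#' @export
random_axon_section_sample <- function(vol, z_index, n, seed = NULL,
                                       n_rays = 360, index = NULL) {
  sl <- vol$stack[, , z_index]
  u <- unique(as.vector(sl))
  ids <- sort(u[u >= 1 & u <= vol$channels$axon_max])
  if (length(ids) < n)
    stop(sprintf("slice %d has %d axons, fewer than n = %d", z_index, length(ids), n))
  if (!is.null(seed)) set.seed(seed)
  sel <- sort(sample(ids, n))
  rows <- lapply(sel, function(id)
    measure_cross_section(cross_section(vol, id, z_index, index = index), n_rays))
  wide_to_table(do.call(rbind, rows))
}

# wide per-slice measurement rows -> long measurement_table
wide_to_table <- function(wide) {
  mets <- intersect(profile_metrics, names(wide))
  do.call(rbind, lapply(mets, function(met)
    measurement_table(wide$axon_id, wide$z_index, met, wide[[met]])))
}
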