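#' Measure every axon in a label volume
#'
#' Runs the full measurement chain on one volume: traces every axon
#' instance, measures longitudinal profiles at `interval_um` spacing,
#' detects nodes of Ranvier with paranodal gaps, and tabulates mitochondria
#' with nodal assignment. Axons shorter than two sampling intervals are
#' excluded from the summaries with a message (a range needs two samples).
#'
#' @param vol a [label_volume()].
#' @param interval_um sampling interval along each axon, um (default 5).
#' @param n_rays rays for thickness/decompaction (default 360).
#' @param threshold_pct decompaction point threshold (default 40).
#' @param nodal_window_um nodal mitochondrion window, um (default 10).
#' @param min_node_run minimum myelin-free run for a node, slices (default 3).
#' @param group,animal cohort labels attached to all outputs.
#' @return List: `profiles` (per axon), `summaries` (one row per axon),
#'   `nodes`, `mitos`, `node_mito` (per-node stats), `points` (all sampled
#'   diameter/thickness pairs for regression).
#' @export
measure_volume <- function(vol, interval_um = 5, n_rays = 360,
                           threshold_pct = 40, nodal_window_um = 10,
                           min_node_run = 3, group = NA_character_,
                           animal = NA_integer_) {
  idx <- volume_index(vol)
  ids <- axon_ids(vol)
  profiles <- list(); summaries <- list(); nodes <- list(); cls <- list()
  for (id in ids) {
    pr <- measure_axon(vol, id, interval_um = interval_um, n_rays = n_rays,
                       group = group, animal = animal, index = idx)
    if (nrow(pr$measurements) < 3) {
      message("axon ", id, " shorter than 2 sampling intervals; excluded from summaries")
      next
    }
    profiles[[length(profiles) + 1]] <- pr
    summaries[[length(summaries) + 1]] <- profile_summary(pr, threshold_pct)
    cls[[length(cls) + 1]] <- pr$centerline
    nd <- detect_nodes(vol, pr$centerline, min_run = min_node_run, index = idx)
    if (nrow(nd)) nodes[[length(nodes) + 1]] <- nd
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(axon_id = integer(), node_id = integer(), z_first = integer(),
               z_last = integer(), s_center_um = numeric(), gap_um = numeric())
  mitos <- mito_records(vol, cls, nodes, window_um = nodal_window_um, index = idx)
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  pts <- do.call(rbind, lapply(profiles, function(p)
    p$measurements[, c("axon_id", "axon_diameter_um", "myelin_thickness_um")]))
  if (nrow(nodes)) { nodes$group <- group; nodes$animal <- animal }
  if (nrow(mitos)) { mitos$group <- group; mitos$animal <- animal }
  if (!is.null(pts) && nrow(pts)) { pts$group <- group; pts$animal <- animal }
  list(profiles = profiles, summaries = summaries, nodes = nodes,
       mitos = mitos,
       node_mito = nodal_mito_stats(mitos, nodes, nodal_window_um),
       points = pts)
}

#' Simulate and measure a phantom cohort
#'
#' Generates `n_animals` preset phantom volumes (each one animal's field of
#' view with `axons_per_animal` axons) and runs [measure_volume()] on each,
#' pooling axon summaries, nodes, mitochondria and regression points across
#' animals.
#'
#' @param group `"normal"` or `"injured"`.
#' @param n_animals animals per group (default 3).
#' @param axons_per_animal axons per animal (default 10).
#' @param seed base seed; animal `i` uses `seed * 100 + i`.
#' @param interval_um sampling interval, um.
#' @param ... passed to [phantom_preset()] (e.g. `dim`, `spacing`).
#' @return As [measure_volume()], pooled, plus `group`.
#' @export
simulate_cohort <- function(group, n_animals = 3, axons_per_animal = 10,
                            seed = 1, interval_um = 5, ...) {
  summaries <- list(); nodes <- list(); mitos <- list(); points <- list()
  node_mito <- list()
  for (i in seq_len(n_animals)) {
    cfg <- phantom_preset(group, seed = seed * 100 + i,
                          n_axons = axons_per_animal, ...)
    ph <- generate_phantom(cfg)
    res <- measure_volume(ph$volume, interval_um = interval_um,
                          group = group, animal = i)
    res$summaries$axon_id <- res$summaries$axon_id + (i - 1) * axons_per_animal
    if (nrow(res$nodes)) res$nodes$axon_id <- res$nodes$axon_id + (i - 1) * axons_per_animal
    summaries[[i]] <- res$summaries
    nodes[[i]] <- res$nodes
    mitos[[i]] <- res$mitos
    points[[i]] <- res$points
    node_mito[[i]] <- res$node_mito
    rm(ph, res); gc(verbose = FALSE)
  }
  list(group = group,
       summaries = do.call(rbind, summaries),
       nodes = do.call(rbind, nodes),
       mitos = do.call(rbind, mitos),
       node_mito = do.call(rbind, node_mito),
       points = do.call(rbind, points))
}

#' Compare two measured cohorts
#'
#' Reproduces the comparative layer on two [simulate_cohort()] (or pooled
#' [measure_volume()]) results: Levene-gated unpaired t-tests on per-axon
#' means (area, diameter, thickness, G-ratio), the decompaction score,
#' paranodal gap, and nodal mitochondrion length and per-node count, plus
#' the diameter-thickness regression per group.
#'
#' @param a,b cohort results (conventionally normal and injured).
#' @param alpha Levene gate level (default 0.05).
#' @return List: `stats` (one row per metric with Levene F/p, t, df, p and
#'   group means) and `regression` (per-group `regression_result`s).
#' @export
cohort_comparison <- function(a, b, alpha = 0.05) {
  pull <- function(res, what) switch(
    what,
    mean_area = res$summaries$mean_area_um2,
    mean_diameter = res$summaries$mean_axon_diameter_um,
    mean_thickness = res$summaries$mean_myelin_thickness_um,
    mean_g_ratio = res$summaries$mean_g_ratio,
    decompaction_score = res$summaries$decompaction_score,
    paranodal_gap = res$nodes$gap_um,
    nodal_mito_length = res$mitos$length_um[res$mitos$is_nodal],
    nodal_mito_count = res$node_mito$n_mito)
  metrics <- c("mean_area", "mean_diameter", "mean_thickness", "mean_g_ratio",
               "decompaction_score", "paranodal_gap", "nodal_mito_length",
               "nodal_mito_count")
  rows <- lapply(metrics, function(m) {
    va <- pull(a, m); vb <- pull(b, m)
    if (length(va) < 2 || length(vb) < 2)
      return(cbind(data.frame(metric = m), n_a = length(va), n_b = length(vb),
                   levene_F = NA, levene_p = NA, equal_var = NA,
                   t = NA, df = NA, p = NA,
                   mean_a = mean(va), mean_b = mean(vb)))
    cbind(data.frame(metric = m), compare_two_groups(va, vb, alpha))
  })
  myel <- function(p) p[p$myelin_thickness_um > 0, , drop = FALSE]  # drop nodal slices
  pa <- myel(a$points); pb <- myel(b$points)
  reg <- list(
    a = fit_diameter_thickness(pa$axon_diameter_um, pa$myelin_thickness_um),
    b = fit_diameter_thickness(pb$axon_diameter_um, pb$myelin_thickness_um))
  names(reg) <- c(if (is.character(a$group)) a$group[1] else "a",
                  if (is.character(b$group)) b$group[1] else "b")
  list(stats = do.call(rbind, rows), regression = reg)
}
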