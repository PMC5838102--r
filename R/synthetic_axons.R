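#' Specification of one synthetic axon
#'
#' Describes a tortuous myelinated tube: a centerline that wanders about a
#' home position (two sinusoidal components per axis, optionally plus a
#' constant tilt), a sinusoidally varying radius, a myelin sheath following
#' the thickness rule `t = slope * (2 r) + intercept` with optional smooth
#' noise, and optional node of Ranvier, decompaction patches and
#' mitochondria.
#'
#' @param x0_um,y0_um home position of the centerline, um.
#' @param base_radius_um base axon radius, um.
#' @param radius_amp fractional amplitude of the sinusoidal radius variation.
#' @param radius_period_um spatial period of the radius variation, um.
#' @param tilt_deg constant centerline tilt from the z axis, degrees.
#' @param tilt_azimuth_deg in-plane direction of the tilt, degrees.
#' @param tort_amp_um amplitudes (um) of the two tortuosity sinusoids per axis.
#' @param tort_period_um periods (um) of the two tortuosity sinusoids.
#' @param node `NULL`, or `list(z_um =, gap_um =)`: a node of Ranvier at
#'   `z_um` with a myelin-free paranodal gap of `gap_um`.
#' @param decomp `NULL`, or data.frame with columns `z0_um`, `z1_um`, `frac`
#'   (angular fraction in (0,1]) and `phi0` (sector start angle, rad):
#'   decompacted-myelin patches.
#' @param mitos `NULL`, or data.frame with columns `zc_um`, `length_um`,
#'   `radius_um`: intra-axonal mitochondria (ellipsoids, z-span
#'   `length_um`).
#' @param thickness_noise_sd_um sd (um) of smooth additive thickness noise.
#' @param thickness_noise_period_um periods of the two noise sinusoids, um.
#' @return A list of class `axon_spec`.
#' @export
axon_spec <- function(x0_um, y0_um, base_radius_um,
                      radius_amp = 0, radius_period_um = 20,
                      tilt_deg = 0, tilt_azimuth_deg = 0,
                      tort_amp_um = c(0, 0), tort_period_um = c(22, 9),
                      node = NULL, decomp = NULL, mitos = NULL,
                      thickness_noise_sd_um = 0,
                      thickness_noise_period_um = c(8, 3.1)) {
  stopifnot(base_radius_um > 0, radius_amp >= 0, radius_amp < 1,
            tilt_deg >= 0, tilt_deg < 90)
  structure(list(x0_um = x0_um, y0_um = y0_um, base_radius_um = base_radius_um,
                 radius_amp = radius_amp, radius_period_um = radius_period_um,
                 tilt_deg = tilt_deg, tilt_azimuth_deg = tilt_azimuth_deg,
                 tort_amp_um = rep_len(tort_amp_um, 2),
                 tort_period_um = rep_len(tort_period_um, 2),
                 node = node, decomp = decomp, mitos = mitos,
                 thickness_noise_sd_um = thickness_noise_sd_um,
                 thickness_noise_period_um = rep_len(thickness_noise_period_um, 2)),
            class = "axon_spec")
}

#' Phantom configuration
#'
#' @param axons list of [axon_spec()]s.
#' @param dim volume dimensions `c(ny, nx, nz)` in voxels. The default
#'   test-scale geometry (256 x 256 x 400 at 20 x 20 x 100 nm) preserves the
#'   strong anisotropy of the acquisition (5 x 5 x 50 nm, 10000 px, 2000
#'   slices) at desk-scale size.
#' @param spacing a [voxel_spacing()].
#' @param myelin_slope,myelin_intercept thickness rule
#'   `t = slope * diameter + intercept` (um), defaults 0.20 and 0.13.
#' @param decomp_widen radial widening factor of decompacted myelin (1.5).
#' @param seed RNG seed controlling the phases of the tortuosity, radius and
#'   thickness-noise sinusoids.
#' @param ... further fields stored on the config (presets record group-level
#'   defaults here).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(axons, dim = c(256, 256, 400),
                           spacing = voxel_spacing(20, 20, 100),
                           myelin_slope = 0.20, myelin_intercept = 0.13,
                           decomp_widen = 1.5, seed = 1, ...) {
  stopifnot(length(dim) == 3, all(dim >= 1), inherits(spacing, "voxel_spacing"))
  if (!all(vapply(axons, inherits, TRUE, "axon_spec")))
    stop("axons must be a list of axon_spec objects")
  sp <- spacing_um(spacing)
  for (a in axons) {
    if (a$base_radius_um * (1 - a$radius_amp) < 2 * max(sp[["dx"]], sp[["dy"]]))
      stop("axon radius falls below the 2-voxel floor")
    if (!is.null(a$node) && a$node$gap_um < sp[["dz"]])
      stop("paranodal gap must span at least one slice")
  }
  structure(list(axons = axons, dim = dim, spacing = spacing,
                 myelin_slope = myelin_slope, myelin_intercept = myelin_intercept,
                 decomp_widen = decomp_widen, seed = seed, ...),
            class = "phantom_config")
}

# analytic per-slice geometry of one axon, phases already drawn
axon_profile_truth <- function(a, zc, config, phases) {
  tiltr <- a$tilt_deg * pi / 180
  az <- a$tilt_azimuth_deg * pi / 180
  zm <- mean(zc)
  w1 <- 2 * pi / a$tort_period_um[1]; w2 <- 2 * pi / a$tort_period_um[2]
  x <- a$x0_um + tan(tiltr) * cos(az) * (zc - zm) +
    a$tort_amp_um[1] * sin(w1 * zc + phases$tx1) +
    a$tort_amp_um[2] * sin(w2 * zc + phases$tx2)
  y <- a$y0_um + tan(tiltr) * sin(az) * (zc - zm) +
    a$tort_amp_um[1] * sin(w1 * zc + phases$ty1) +
    a$tort_amp_um[2] * sin(w2 * zc + phases$ty2)
  dxdz <- tan(tiltr) * cos(az) +
    a$tort_amp_um[1] * w1 * cos(w1 * zc + phases$tx1) +
    a$tort_amp_um[2] * w2 * cos(w2 * zc + phases$tx2)
  dydz <- tan(tiltr) * sin(az) +
    a$tort_amp_um[1] * w1 * cos(w1 * zc + phases$ty1) +
    a$tort_amp_um[2] * w2 * cos(w2 * zc + phases$ty2)
  r <- a$base_radius_um *
    (1 + a$radius_amp * sin(2 * pi * zc / a$radius_period_um + phases$r))
  tnom <- config$myelin_slope * 2 * r + config$myelin_intercept
  if (a$thickness_noise_sd_um > 0) {
    s <- a$thickness_noise_sd_um
    noise <- 1.2 * s * sin(2 * pi * zc / a$thickness_noise_period_um[1] + phases$n1) +
      0.8 * s * sin(2 * pi * zc / a$thickness_noise_period_um[2] + phases$n2)
    noise <- pmin(pmax(noise, -2 * s), 2 * s)
  } else noise <- 0
  sp <- spacing_um(config$spacing)
  thick <- pmax(tnom + noise, 2 * max(sp[["dx"]], sp[["dy"]]))
  in_gap <- if (!is.null(a$node))
    abs(zc - a$node$z_um) <= a$node$gap_um / 2 else rep(FALSE, length(zc))
  frac <- numeric(length(zc)); phi0 <- numeric(length(zc))
  if (!is.null(a$decomp) && nrow(a$decomp)) {
    for (k in seq_len(nrow(a$decomp))) {
      inpatch <- zc >= a$decomp$z0_um[k] & zc <= a$decomp$z1_um[k]
      frac[inpatch] <- a$decomp$frac[k]
      phi0[inpatch] <- a$decomp$phi0[k]
    }
  }
  list(x = x, y = y, dxdz = dxdz, dydz = dydz, r = r, thick = thick,
       in_gap = in_gap, frac = frac, phi0 = phi0)
}

#' Generate a labeled phantom volume with ground truth
#'
#' Rasterizes each axon as a true 3D tube: every voxel within `r(z)` of the
#' centerline curve (so a tilted axon has an elliptical in-plane footprint,
#' semi-minor axis `r`, semi-major `r / cos(tilt)` — area inflates with
#' obliquity while the minimum caliper diameter stays `2r`). Compact myelin
#' is a concentric annulus of the per-slice thickness, omitted inside a
#' node's paranodal gap; decompacted patches replace the compact annulus
#' over an angular sector, radially widened by `decomp_widen`; mitochondria
#' are ellipsoids inside the axon carrying their own instance labels.
#' Generation is a pure function of `(config, config$seed)`.
#'
#' @param config a [phantom_config()].
#' @return `list(volume = label_volume, truth = list(profiles, nodes, mitos,
#'   config))`. Truth tables give, per axon and slice, the true centerline
#'   point, radius, realized myelin thickness, decompacted angular fraction
#'   and gap membership; designed nodes (centre, gap) and realized
#'   mitochondrion z-spans.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- config$dim
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  sp <- spacing_um(config$spacing)
  dx <- sp[["dx"]]; dy <- sp[["dy"]]; dz <- sp[["dz"]]
  zc <- (seq_len(nz) - 0.5) * dz
  ch <- channel_map()
  axons <- config$axons
  n_ax <- length(axons)
  if (n_ax > ch$axon_max) stop("too many axons for the channel map")

  profs <- vector("list", n_ax)
  for (i in seq_len(n_ax)) {
    ph <- list(tx1 = stats::runif(1, 0, 2 * pi), tx2 = stats::runif(1, 0, 2 * pi),
               ty1 = stats::runif(1, 0, 2 * pi), ty2 = stats::runif(1, 0, 2 * pi),
               r = stats::runif(1, 0, 2 * pi), n1 = stats::runif(1, 0, 2 * pi),
               n2 = stats::runif(1, 0, 2 * pi))
    profs[[i]] <- axon_profile_truth(axons[[i]], zc, config, ph)
  }

  stack <- array(0L, d)
  mito_rows <- list(); mito_id <- 0L
  # realized mito slice spans, per axon
  mito_plan <- vector("list", n_ax)
  for (i in seq_len(n_ax)) {
    a <- axons[[i]]
    if (!is.null(a$mitos) && nrow(a$mitos)) {
      pl <- list()
      for (k in seq_len(nrow(a$mitos))) {
        mito_id <- mito_id + 1L
        half <- a$mitos$length_um[k] / 2
        zs <- which(abs(zc - a$mitos$zc_um[k]) <= half)
        if (!length(zs)) stop("mitochondrion span covers no slice")
        pl[[k]] <- list(id = mito_id, zs = zs, zc_um = a$mitos$zc_um[k],
                        half = half, radius = a$mitos$radius_um[k])
        mito_rows[[mito_id]] <- data.frame(
          mito_id = mito_id, axon_id = i,
          z_first = zs[1], z_last = zs[length(zs)],
          zc_um = a$mitos$zc_um[k], length_um = length(zs) * dz)
      }
      mito_plan[[i]] <- pl
    }
  }

  for (z in seq_len(nz)) {
    slice <- matrix(0L, ny, nx)
    for (i in seq_len(n_ax)) {
      p <- profs[[i]]
      r <- p$r[z]; th <- p$thick[z]
      widen <- if (p$frac[z] > 0 && !p$in_gap[z]) config$decomp_widen else 1
      r_out <- r + if (p$in_gap[z]) 0 else widen * th
      tanA <- sqrt(p$dxdz[z]^2 + p$dydz[z]^2)
      cosA <- 1 / sqrt(1 + tanA^2)
      a_out <- r_out / cosA + max(dx, dy)
      cx <- p$x[z]; cy <- p$y[z]
      ix0 <- max(1L, floor((cx - a_out) / dx)); ix1 <- min(nx, ceiling((cx + a_out) / dx) + 1L)
      iy0 <- max(1L, floor((cy - a_out) / dy)); iy1 <- min(ny, ceiling((cy + a_out) / dy) + 1L)
      if (ix0 > ix1 || iy0 > iy1) next
      ix <- ix0:ix1; iy <- iy0:iy1
      px <- (ix - 0.5) * dx - cx; py <- (iy - 0.5) * dy - cy
      if (tanA > 0) { ex <- p$dxdz[z] / tanA; ey <- p$dydz[z] / tanA } else { ex <- 1; ey <- 0 }
      # in-plane coords along the tilt direction (ex,ey) and perpendicular
      U <- outer(rep(1, length(iy)), px) * ex + outer(py, rep(1, length(ix))) * ey
      V <- -outer(rep(1, length(iy)), px) * ey + outer(py, rep(1, length(ix))) * ex
      rho <- sqrt((U * cosA)^2 + V^2)
      new <- matrix(0L, length(iy), length(ix))
      new[rho <= r] <- i
      if (!p$in_gap[z]) {
        ann <- rho > r & rho <= r + th
        new[ann] <- ch$myelin_offset + i
        if (p$frac[z] > 0) {
          phi <- atan2(V, U * cosA) %% (2 * pi)
          rel <- (phi - p$phi0[z]) %% (2 * pi)
          sect <- rel < 2 * pi * p$frac[z]
          dec <- rho > r & rho <= r + config$decomp_widen * th & sect
          new[ann & sect] <- 0L  # compact removed in the sector
          new[dec] <- ch$decompact_offset + i
        }
      }
      cur <- slice[iy, ix, drop = FALSE]
      clash <- cur != 0L & new != 0L
      if (any(clash))
        stop(sprintf("axon overlap at slice %d between axon %d and label %d",
                     z, i, cur[which(clash)[1]]))
      cur[new != 0L] <- new[new != 0L]
      slice[iy, ix] <- cur
    }
    # mitochondria: overwrite their own axon's interior voxels only
    for (i in seq_len(n_ax)) {
      pl <- mito_plan[[i]]
      if (is.null(pl)) next
      p <- profs[[i]]
      for (m in pl) {
        if (!(z %in% m$zs)) next
        rel <- (zc[z] - m$zc_um) / m$half
        rho_m <- max(m$radius * sqrt(max(0, 1 - rel^2)), 1.5 * max(dx, dy))
        cx <- p$x[z]; cy <- p$y[z]
        ix0 <- max(1L, floor((cx - rho_m) / dx)); ix1 <- min(nx, ceiling((cx + rho_m) / dx) + 1L)
        iy0 <- max(1L, floor((cy - rho_m) / dy)); iy1 <- min(ny, ceiling((cy + rho_m) / dy) + 1L)
        if (ix0 > ix1 || iy0 > iy1) next
        ix <- ix0:ix1; iy <- iy0:iy1
        px <- (ix - 0.5) * dx - cx; py <- (iy - 0.5) * dy - cy
        D <- sqrt(outer(rep(1, length(iy)), px^2) + outer(py^2, rep(1, length(ix))))
        cur <- slice[iy, ix, drop = FALSE]
        put <- D <= rho_m & cur == i
        cur[put] <- ch$mito_offset + m$id
        slice[iy, ix] <- cur
      }
    }
    stack[, , z] <- slice
  }

  empty_prof <- data.frame(axon_id = integer(), z_index = integer(),
                           z_um = numeric(), cx_um = numeric(), cy_um = numeric(),
                           radius_um = numeric(), thickness_um = numeric(),
                           decomp_frac = numeric(), in_gap = logical(),
                           tilt_deg = numeric())
  prof_tab <- do.call(rbind, lapply(seq_len(n_ax), function(i) {
    p <- profs[[i]]
    data.frame(axon_id = i, z_index = seq_len(nz), z_um = zc,
               cx_um = p$x, cy_um = p$y, radius_um = p$r,
               thickness_um = ifelse(p$in_gap, 0, p$thick),
               decomp_frac = ifelse(p$in_gap, 0, p$frac),
               in_gap = p$in_gap,
               tilt_deg = atan(sqrt(p$dxdz^2 + p$dydz^2)) * 180 / pi)
  }))
  if (is.null(prof_tab)) prof_tab <- empty_prof
  node_tab <- do.call(rbind, lapply(seq_len(n_ax), function(i) {
    nd <- axons[[i]]$node
    if (is.null(nd)) return(NULL)
    data.frame(axon_id = i, z_um = nd$z_um, gap_um = nd$gap_um)
  }))
  if (is.null(node_tab))
    node_tab <- data.frame(axon_id = integer(), z_um = numeric(), gap_um = numeric())
  mito_tab <- if (length(mito_rows)) do.call(rbind, mito_rows) else
    data.frame(mito_id = integer(), axon_id = integer(), z_first = integer(),
               z_last = integer(), zc_um = numeric(), length_um = numeric())

  list(volume = label_volume(stack, config$spacing, ch),
       truth = list(profiles = prof_tab, nodes = node_tab, mitos = mito_tab,
                    config = config))
}

#' Study-condition phantom presets
#'
#' Builds a full [phantom_config()] for a "normal" or "injured" optic-nerve
#' phantom cohort member (one animal's field of view). The injured preset
#' differs from normal by heavier myelin decompaction (25% of each axon's
#' z-length at angular fractions around 0.6, vs 2% around 0.2), longer
#' paranodal gaps (mean 3.0 vs 1.5 um), shorter nodal mitochondria (mean
#' 0.8 vs 1.4 um) and a weaker diameter-thickness coupling (larger smooth
#' thickness noise).
#'
#' @param name `"normal"` or `"injured"`.
#' @param seed RNG seed for both the drawn per-axon parameters and the
#'   generator phases.
#' @param n_axons axons in the field of view (default 10, one animal).
#' @param dim,spacing volume geometry (defaults 512 x 512 x 400 voxels at
#'   20 x 20 x 100 nm, i.e. 10.24 x 10.24 x 40 um).
#' @return A [phantom_config()] with group-level defaults recorded as fields
#'   `group`, `gap_mean_um`, `decomp_coverage`, `decomp_frac_mean`,
#'   `mito_length_mean_um`, `thickness_noise_sd_um`.
#' @export
phantom_preset <- function(name, seed = 1, n_axons = 10,
                           dim = c(512, 512, 400),
                           spacing = voxel_spacing(20, 20, 100)) {
  if (!name %in% c("normal", "injured"))
    stop("unknown preset '", name, "' (use \"normal\" or \"injured\")")
  inj <- name == "injured"
  gap_mean <- if (inj) 3.0 else 1.5
  gap_sd <- if (inj) 0.3 else 0.2
  coverage <- if (inj) 0.25 else 0.02
  frac_rng <- if (inj) c(0.45, 0.75) else c(0.05, 0.35)
  mito_mean <- if (inj) 0.8 else 1.4
  mito_sd <- if (inj) 0.15 else 0.2
  noise_sd <- if (inj) 0.039 else 0.025

  set.seed(seed)
  sp <- spacing_um(spacing)
  Lz <- dim[3] * sp[["dz"]]
  W <- dim[2] * sp[["dx"]]; H <- dim[1] * sp[["dy"]]
  margin <- 1.35
  ncol_ <- ceiling(sqrt(n_axons))
  nrow_ <- ceiling(n_axons / ncol_)
  gx <- if (ncol_ > 1) seq(margin, W - margin, length.out = ncol_) else (W / 2)
  gy <- if (nrow_ > 1) seq(margin, H - margin, length.out = nrow_) else (H / 2)
  pos <- expand.grid(x = gx, y = gy)[seq_len(n_axons), ]

  axons <- vector("list", n_axons)
  for (i in seq_len(n_axons)) {
    base_r <- stats::runif(1, 0.10, 0.28)
    node <- NULL; mitos <- NULL
    if (stats::runif(1) < 0.6) {
      node_z <- stats::runif(1, 0.35, 0.65) * Lz
      gap <- max(3 * sp[["dz"]], stats::rnorm(1, gap_mean, gap_sd))
      node <- list(z_um = node_z, gap_um = gap)
      n_m <- stats::rpois(1, 1.5)
      if (n_m > 0) {
        lens <- pmax(0.3, stats::rnorm(n_m, mito_mean, mito_sd))
        zc_m <- numeric(n_m)
        for (k in seq_len(n_m)) {
          repeat {
            cand <- node_z + stats::runif(1, -6, 6)
            cand <- min(max(cand, lens[k] / 2 + sp[["dz"]]), Lz - lens[k] / 2 - sp[["dz"]])
            if (k == 1 || all(abs(cand - zc_m[seq_len(k - 1)]) >
                                (lens[k] + lens[seq_len(k - 1)]) / 2 + 0.2)) break
          }
          zc_m[k] <- cand
        }
        mitos <- data.frame(zc_um = zc_m, length_um = lens,
                            radius_um = pmax(0.4 * base_r, 1.6 * max(sp[["dx"]], sp[["dy"]])))
      }
    }
    decomp <- NULL
    target <- coverage * Lz
    if (target > 0) {
      spans <- list(); tot <- 0; tries <- 0
      while (tot < target && tries < 200) {
        tries <- tries + 1
        len <- if (coverage <= 0.05) target else stats::runif(1, 2, 4)
        len <- min(len, target - tot + 0.5)
        z0 <- stats::runif(1, 0.5, Lz - len - 0.5)
        ok <- all(vapply(spans, function(s) z0 > s[2] + 0.5 || z0 + len < s[1] - 0.5, TRUE))
        if (ok) { spans[[length(spans) + 1]] <- c(z0, z0 + len); tot <- tot + len }
      }
      decomp <- do.call(rbind, lapply(spans, function(s)
        data.frame(z0_um = s[1], z1_um = s[2],
                   frac = stats::runif(1, frac_rng[1], frac_rng[2]),
                   phi0 = stats::runif(1, 0, 2 * pi))))
    }
    axons[[i]] <- axon_spec(
      x0_um = pos$x[i], y0_um = pos$y[i], base_radius_um = base_r,
      radius_amp = 0.15, radius_period_um = stats::runif(1, 15, 30),
      tort_amp_um = c(0.16, 0.09), tort_period_um = stats::runif(2, c(18, 7), c(30, 11)),
      node = node, decomp = decomp, mitos = mitos,
      thickness_noise_sd_um = noise_sd)
  }
  phantom_config(axons, dim = dim, spacing = spacing, seed = seed,
                 group = name, gap_mean_um = gap_mean,
                 decomp_coverage = coverage, decomp_frac_mean = mean(frac_rng),
                 mito_length_mean_um = mito_mean,
                 thickness_noise_sd_um = noise_sd)
}
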