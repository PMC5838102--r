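# Independent oracles and fixture builders used across the suite.

# Brute-force minimum directional width of a mask: projection span of the
# voxel-corner points swept over a 0.5-degree angle grid, then refined by
# golden-section search on the (projection-based) width function around the
# grid minimum. Evaluates widths by projection only — independent of the
# edge-based rotating-calipers code under test.
brute_force_min_width <- function(coords, spacing, step_deg = 0.5) {
  sp <- c(spacing$dx, spacing$dy) / 1000
  x0 <- (coords[, 2] - 1) * sp[1]; x1 <- coords[, 2] * sp[1]
  y0 <- (coords[, 1] - 1) * sp[2]; y1 <- coords[, 1] * sp[2]
  pts <- cbind(c(x0, x1, x0, x1), c(y0, y0, y1, y1))
  width_at <- function(theta) {
    proj <- pts[, 1] * cos(theta) + pts[, 2] * sin(theta)
    max(proj) - min(proj)
  }
  grid <- seq(0, pi, by = step_deg * pi / 180)
  w <- vapply(grid, width_at, 1)
  k <- which.min(w)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- width_at(c1); f2 <- width_at(c2)
  while (b - a > 1e-10) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- width_at(c1) }
    else { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- width_at(c2) }
  }
  min(min(w), width_at((a + b) / 2))
}

# rasterize a rotated ellipse (semi-axes in um) into voxel coords at `spacing`
ellipse_coords <- function(cx, cy, a, b, theta = 0, spacing = axonmorph::voxel_spacing(20, 20, 100),
                           n = 256) {
  sp <- c(spacing$dx, spacing$dy) / 1000
  xs <- (seq_len(n) - 0.5) * sp[1]; ys <- (seq_len(n) - 0.5) * sp[2]
  X <- outer(rep(1, n), xs) - cx; Y <- outer(ys, rep(1, n)) - cy
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  inside <- (U / a)^2 + (V / b)^2 <= 1
  w <- which(inside)
  co <- arrayInd(w, c(n, n))
  colnames(co) <- c("y", "x")
  co
}

# build a cross_section object directly from concentric disk/annulus radii
# (um), bypassing the generator: axon r <= r_ax, compact myelin
# r_ax < r <= r_my, with an optional decompacted angular sector
synthetic_annulus_cs <- function(r_ax, r_my = NA, dec_frac = 0, dec_phi0 = 0,
                                 spacing = axonmorph::voxel_spacing(20, 20, 100),
                                 n = 256) {
  sp <- c(spacing$dx, spacing$dy) / 1000
  cx <- n / 2 * sp[1]; cy <- n / 2 * sp[2]
  xs <- (seq_len(n) - 0.5) * sp[1]; ys <- (seq_len(n) - 0.5) * sp[2]
  X <- outer(rep(1, n), xs) - cx; Y <- outer(ys, rep(1, n)) - cy
  R <- sqrt(X^2 + Y^2)
  get <- function(m) { w <- which(m); co <- arrayInd(w, c(n, n)); colnames(co) <- c("y", "x"); co }
  ax <- get(R <= r_ax)
  my_c <- NULL; my_d <- NULL
  if (!is.na(r_my)) {
    ann <- R > r_ax & R <= r_my
    if (dec_frac > 0) {
      phi <- atan2(Y, X) %% (2 * pi)
      sect <- ((phi - dec_phi0) %% (2 * pi)) < 2 * pi * dec_frac
      my_d <- get(ann & sect)
      my_c <- get(ann & !sect)
    } else my_c <- get(ann)
  }
  structure(list(axon_id = 1L, z_index = 1L, axon = ax,
                 myelin_c = my_c, myelin_d = my_d,
                 centroid_um = c(cx, cy), spacing = spacing),
            class = "cross_section")
}

# small straight-tube label volume built by hand (no generator): axon radius
# r_ax, optional myelin to r_my, spanning nz slices; myelin omitted inside
# [gap_z0, gap_z1] (slice indices)
straight_tube_volume <- function(nz = 100, n = 96, r_ax = 0.4, r_my = NA,
                                 gap_z = NULL,
                                 spacing = axonmorph::voxel_spacing(20, 20, 50)) {
  sp <- c(spacing$dx, spacing$dy) / 1000
  cx <- n / 2 * sp[1]; cy <- n / 2 * sp[2]
  xs <- (seq_len(n) - 0.5) * sp[1]; ys <- (seq_len(n) - 0.5) * sp[2]
  X <- outer(rep(1, n), xs) - cx; Y <- outer(ys, rep(1, n)) - cy
  R <- sqrt(X^2 + Y^2)
  base <- matrix(0L, n, n)
  base[R <= r_ax] <- 1L
  withmy <- base
  if (!is.na(r_my)) withmy[R > r_ax & R <= r_my] <- 1001L
  stack <- array(0L, c(n, n, nz))
  for (z in seq_len(nz)) {
    stack[, , z] <- if (!is.null(gap_z) && z >= gap_z[1] && z <= gap_z[2]) base else withmy
  }
  axonmorph::label_volume(stack, spacing)
}
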