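test_that("the myelin thickness rule is honoured in the truth table", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.5)
  ph <- generate_phantom(phantom_config(list(a), dim = c(256, 256, 40), seed = 1))
  # t = 0.20 * (2 * 0.5) + 0.13 = 0.33 um, constant along z
  expect_equal(unique(ph$truth$profiles$thickness_um), 0.33)
  expect_equal(unique(ph$truth$profiles$radius_um), 0.5)
})

test_that("an empty config produces an empty volume and empty truth", {
  ph <- generate_phantom(phantom_config(list(), dim = c(64, 64, 20), seed = 1))
  expect_identical(axon_ids(ph$volume), integer(0))
  expect_equal(nrow(ph$truth$profiles), 0)
  expect_equal(nrow(ph$truth$nodes), 0)
  expect_equal(nrow(ph$truth$mitos), 0)
})

test_that("generation is a pure function of (config, seed)", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.3,
                 radius_amp = 0.15, tort_amp_um = c(0.2, 0.1))
  cfg <- phantom_config(list(a), dim = c(256, 256, 80), seed = 42)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$volume$stack, ph2$volume$stack)
  expect_equal(ph1$truth$profiles, ph2$truth$profiles)
})

test_that("different seeds move the centerline but preserve radius statistics", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.3,
                 radius_amp = 0.15, radius_period_um = 7,
                 tort_amp_um = c(0.2, 0.1))
  cfg1 <- phantom_config(list(a), dim = c(256, 256, 150), seed = 1)
  cfg2 <- phantom_config(list(a), dim = c(256, 256, 150), seed = 2)
  t1 <- generate_phantom(cfg1)$truth$profiles
  t2 <- generate_phantom(cfg2)$truth$profiles
  expect_gt(max(abs(t1$cx_um - t2$cx_um)), 0.05)
  expect_false(isTRUE(all.equal(t1$radius_um, t2$radius_um)))
  expect_lt(abs(mean(t1$radius_um) - mean(t2$radius_um)) / mean(t1$radius_um), 0.05)
  expect_lt(abs(sd(t1$radius_um) - sd(t2$radius_um)) / sd(t1$radius_um), 0.25)
})

test_that("semantic classes are disjoint and mitochondria sit inside the axon", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.4,
                 node = list(z_um = 10, gap_um = 1.5),
                 decomp = data.frame(z0_um = 2, z1_um = 5, frac = 0.4, phi0 = 1),
                 mitos = data.frame(zc_um = 6, length_um = 1, radius_um = 0.12))
  ph <- generate_phantom(phantom_config(list(a), dim = c(256, 256, 200), seed = 9))
  v <- ph$volume
  # one label per voxel partitions classes by construction; verify the ranges
  labs <- unique(as.vector(v$stack))
  expect_true(all(labs %in% c(0L, 1L, 1001L, 2001L, 3001L)))
  # mitochondrion voxels lie within the true axon radius of the centerline
  tr <- ph$truth$profiles
  for (z in ph$truth$mitos$z_first:ph$truth$mitos$z_last) {
    co <- which(v$stack[, , z] == 3001L, arr.ind = TRUE)
    cc <- cbind((co[, 2] - 0.5) * 0.02, (co[, 1] - 0.5) * 0.02)
    row <- tr[tr$z_index == z, ]
    d <- sqrt((cc[, 1] - row$cx_um)^2 + (cc[, 2] - row$cy_um)^2)
    expect_true(all(d <= row$radius_um + 0.03))
  }
})

test_that("rasterized axial sections recover the designed area and radius", {
  for (r in c(0.2, 0.35, 0.5)) {
    a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = r)
    ph <- generate_phantom(phantom_config(list(a), dim = c(256, 256, 10), seed = 1))
    cs <- cross_section(ph$volume, 1, 5)
    vox <- 0.02 * 0.02
    bound <- 2 * vox + 2 * pi * r * 0.02   # 2 voxel-areas + perimeter band
    expect_lt(abs(cross_sectional_area(cs) - pi * r^2), bound)
    expect_lt(abs(min_caliper_diameter(cs$axon, ph$volume$spacing) - 2 * r), 0.03)
  }
})

test_that("overlapping axons are reported, not clipped", {
  a1 <- axon_spec(x0_um = 2.5, y0_um = 2.5, base_radius_um = 0.4)
  a2 <- axon_spec(x0_um = 2.8, y0_um = 2.5, base_radius_um = 0.4)
  cfg <- phantom_config(list(a1, a2), dim = c(256, 256, 5), seed = 1)
  expect_error(generate_phantom(cfg), "overlap")
})

test_that("config invariants reject sub-voxel radii and sub-slice gaps", {
  tiny <- axon_spec(x0_um = 1, y0_um = 1, base_radius_um = 0.03)
  expect_error(phantom_config(list(tiny)), "2-voxel floor")
  a <- axon_spec(x0_um = 2, y0_um = 2, base_radius_um = 0.3,
                 node = list(z_um = 5, gap_um = 0.05))
  expect_error(phantom_config(list(a)), "at least one slice")
})

test_that("presets encode the normal vs injured study conditions", {
  nm <- phantom_preset("normal", seed = 1, n_axons = 2)
  inj <- phantom_preset("injured", seed = 1, n_axons = 2)
  expect_equal(nm$decomp_coverage, 0.02)
  expect_equal(inj$decomp_coverage, 0.25)
  expect_gt(inj$gap_mean_um, nm$gap_mean_um)
  expect_lt(inj$mito_length_mean_um, nm$mito_length_mean_um)
  expect_gt(inj$thickness_noise_sd_um, nm$thickness_noise_sd_um)
  expect_gt(inj$decomp_frac_mean, nm$decomp_frac_mean)
  expect_error(phantom_preset("sham"), "unknown preset")
})
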