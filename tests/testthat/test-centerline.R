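test_that("a straight axial tube measures exactly its z extent", {
  vol <- straight_tube_volume(nz = 100, r_ax = 0.4,
                              spacing = voxel_spacing(20, 20, 50))
  cl <- trace_axon(vol, 1)
  expect_equal(cl$measured_length, 5.0)          # 100 slices x 50 nm
  expect_equal(sd(cl$points$cx_um), 0)
  expect_equal(sd(cl$points$cy_um), 0)
  expect_equal(cl$z_extent, c(1, 100))
})

test_that("a 45-degree tilted tube measures sqrt(2) times its z extent", {
  a <- axon_spec(x0_um = 5.12, y0_um = 2.56, base_radius_um = 0.3, tilt_deg = 45)
  ph <- generate_phantom(phantom_config(list(a), dim = c(256, 512, 60),
                                        spacing = voxel_spacing(20, 20, 100),
                                        seed = 1))
  cl <- trace_axon(ph$volume, 1)
  zext <- 60 * 0.1
  expect_lt(abs(cl$measured_length - zext * sqrt(2)) / (zext * sqrt(2)), 0.01)
})

test_that("arc length matches the generator's centerline on tortuous phantoms", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.3,
                 radius_amp = 0.1, tort_amp_um = c(0.25, 0.12),
                 tort_period_um = c(8, 3.5))
  ph <- generate_phantom(phantom_config(list(a), dim = c(256, 256, 200), seed = 4))
  cl <- trace_axon(ph$volume, 1)
  tr <- ph$truth$profiles
  seg <- sqrt(diff(tr$cx_um)^2 + diff(tr$cy_um)^2 + diff(tr$z_um)^2)
  truth_len <- sum(seg) + 0.1
  expect_lt(abs(cl$measured_length - truth_len) / truth_len, 0.02)
})

test_that("arc length dominates the endpoint chord and survives z reversal", {
  a <- axon_spec(x0_um = 2.56, y0_um = 2.56, base_radius_um = 0.3,
                 tort_amp_um = c(0.3, 0.1), tort_period_um = c(7, 3))
  ph <- generate_phantom(phantom_config(list(a), dim = c(256, 256, 120), seed = 8))
  cl <- trace_axon(ph$volume, 1)
  p <- cl$points
  chord <- sqrt((p$cx_um[nrow(p)] - p$cx_um[1])^2 + (p$cy_um[nrow(p)] - p$cy_um[1])^2 +
                  ((p$z_index[nrow(p)] - p$z_index[1]) * 0.1)^2)
  expect_gte(cl$measured_length, chord)
  flipped <- label_volume(ph$volume$stack[, , rev(seq_len(120))],
                          ph$volume$spacing, ph$volume$channels)
  cl2 <- trace_axon(flipped, 1)
  expect_equal(cl2$measured_length, cl$measured_length, tolerance = 1e-10)
  expect_equal(rev(cl2$points$cx_um), cl$points$cx_um, tolerance = 1e-10)
})

test_that("traces tolerate short dropouts and terminate on long gaps", {
  vol <- straight_tube_volume(nz = 60, r_ax = 0.3)
  stack <- vol$stack
  stack[, , 30:31] <- 0L                # 2-slice dropout: bridged
  v2 <- label_volume(stack, vol$spacing)
  cl <- trace_axon(v2, 1, max_gap = 2)
  expect_equal(cl$z_extent, c(1, 60))
  stack[, , 29:32] <- 0L                # 4-slice hole: terminated
  v3 <- label_volume(stack, vol$spacing)
  expect_warning(cl3 <- trace_axon(v3, 1, max_gap = 2), "terminated")
  expect_equal(cl3$z_extent, c(1, 28))
})

test_that("sampling positions follow arc length at the requested interval", {
  vol <- straight_tube_volume(nz = 100, r_ax = 0.4,
                              spacing = voxel_spacing(20, 20, 50))
  cl <- trace_axon(vol, 1)                       # 5 um long
  expect_equal(sample_positions(cl, 1), c(seq(1, 81, by = 20), 100))
  expect_error(sample_positions(cl, 0.01), "slice thickness")
  expect_error(sample_positions(cl, -1), "positive")

  # 12.4 um axon at 5 um intervals -> 3 samples (0, 5, 10)
  vol2 <- straight_tube_volume(nz = 124, r_ax = 0.4,
                               spacing = voxel_spacing(20, 20, 100))
  cl2 <- trace_axon(vol2, 1)
  expect_equal(cl2$measured_length, 12.4)
  expect_length(sample_positions(cl2, 5), 3)

  # tilted tube: samples 5 um apart in arc, less than 5 um apart in z
  a <- axon_spec(x0_um = 7, y0_um = 1.6, base_radius_um = 0.3, tilt_deg = 40)
  ph <- generate_phantom(phantom_config(list(a), dim = c(160, 704, 120), seed = 2))
  cl3 <- trace_axon(ph$volume, 1)
  zs <- sample_positions(cl3, 5)
  s <- cl3$points$s_um[match(zs, cl3$points$z_index)]
  expect_true(all(abs(diff(s) - 5) < 0.2))
  expect_true(all(diff(zs) * 0.1 < 5))
})
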