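# Shape metrics: analytic fixtures (straight / arc / helix / cylinder),
# voxelization bounds, algebraic identities, rigid-motion invariance.

test_that("streamline_length handles lines, points and curves", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(10, 0, 0))), 10)
  expect_equal(streamline_length(matrix(c(1, 2, 3), 1)), 0)
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(streamline_length(semi), pi * 10, tolerance = 1e-3)
  expect_error(streamline_length(rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
})

test_that("length/span/curl on analytic bundles", {
  b <- gen_bundle(bundle_spec("straight", n_streamlines = 4, length_mm = 100,
                              radius_mm = 1, seed = 1))
  m <- bundle_length_and_span(b)
  expect_equal(unname(m["mean_length_mm"]), 100, tolerance = 1e-9)
  expect_equal(unname(m["span_mm"]), 100, tolerance = 1e-9)
  expect_equal(curl(m[["mean_length_mm"]], m[["span_mm"]]), 1, tolerance = 1e-9)
  arc <- gen_bundle(bundle_spec("arc", n_streamlines = 1, radius_mm = 0,
                                arc_angle_rad = pi, curvature_radius_mm = 7,
                                n_points = 1000, seed = 1))
  ma <- bundle_length_and_span(arc)
  expect_equal(unname(ma["span_mm"]), 14, tolerance = 1e-6)  # chord = 2r
  expect_equal(curl(ma[["mean_length_mm"]], ma[["span_mm"]]), pi / 2,
               tolerance = 1e-3)
  expect_equal(elongation(100, 8), 12.5)
  expect_error(curl(10, 0), "undefined")
  expect_error(elongation(10, 0), "undefined")
})

test_that("voxelize marks at least the continuity lower bound", {
  # one streamline inside a single voxel
  b1 <- streamline_bundle(list(rbind(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8))),
                          voxel_size_mm = 2)
  expect_equal(nrow(voxelize(b1)), 1L)
  # straight 10 mm line at 2 mm voxels: at least 5 voxels
  b2 <- streamline_bundle(list(rbind(c(0, 0, 0), c(10, 0, 0))), voxel_size_mm = 2)
  expect_gte(nrow(voxelize(b2)), 5L)
})

test_that("volume and surface of small voxel blocks", {
  b <- streamline_bundle(list(rbind(c(1, 1, 1), c(1.2, 1, 1))), voxel_size_mm = 2)
  vs <- volume_and_surface(voxelize(b))
  expect_equal(unname(vs), c(8, 24))  # one 2 mm cube
  b2 <- streamline_bundle(list(rbind(c(1, 1, 1), c(3, 1, 1))), voxel_size_mm = 2)
  vs2 <- volume_and_surface(voxelize(b2))
  expect_equal(unname(vs2), c(16, 40))  # 2x1x1 block of 2 mm cubes
})

test_that("cylinder fixture: volume, diameter, surface within measured bounds", {
  b <- gen_bundle(bundle_spec("straight", length_mm = 100, radius_mm = 4,
                              n_points = 201, layout = "grid",
                              grid_spacing_mm = 1, seed = 1))
  s <- compute_shape(b, voxel_size_mm = 1)
  v_true <- pi * 16 * 100
  expect_lt(abs(s$volume_mm3 / v_true - 1), 0.10)
  expect_lt(abs(s$diameter_mm / 8 - 1), 0.10)
  a_true <- 2 * pi * 4 * 100 + 2 * pi * 16
  expect_lt(abs(s$surface_area_mm2 / a_true - 1), 0.30)  # measured ~0.28
  # diameter algebra: inverse of the equivalent-cylinder volume
  expect_equal(diameter_from_volume(pi * 16 * 100, 100), 8)
  expect_equal(diameter_from_volume(0, 100), 0)
})

test_that("elongation * diameter equals mean length identically", {
  for (seed in 1:3) {
    b <- gen_bundle(bundle_spec("helix", n_streamlines = 8, length_mm = 60,
                                radius_mm = 1.5, jitter_sd_mm = 0.2, seed = seed))
    s <- compute_shape(b)
    expect_equal(s$elongation * s$diameter_mm, s$mean_length_mm,
                 tolerance = 1e-12)
    expect_gte(s$curl, 1 - 1e-9)
  }
})

test_that("length, span, curl are exactly rigid-motion invariant", {
  b <- gen_bundle(bundle_spec("arc", n_streamlines = 5, radius_mm = 1,
                              arc_angle_rad = 2, curvature_radius_mm = 15,
                              jitter_sd_mm = 0.1, seed = 2))
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- streamline_bundle(
    lapply(b$streamlines, function(p) sweep(p %*% t(Rz), 2, c(5, -3, 11), "+")),
    voxel_size_mm = b$voxel_size_mm)
  m0 <- bundle_length_and_span(b)
  m1 <- bundle_length_and_span(moved)
  expect_equal(m1, m0, tolerance = 1e-9)
})

test_that("volume is monotone nondecreasing under adding streamlines", {
  full <- gen_bundle(bundle_spec("straight", n_streamlines = 20, length_mm = 50,
                                 radius_mm = 3, seed = 4))
  part <- streamline_bundle(full$streamlines[1:5], voxel_size_mm = 2)
  v_part <- volume_and_surface(voxelize(part))[["volume_mm3"]]
  v_full <- volume_and_surface(voxelize(full))[["volume_mm3"]]
  expect_gte(v_full, v_part)
})
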