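# Mirror, boolean subtraction, volume scaling.

test_that("mirroring is an exact involution and preserves volume", {
  set.seed(21)
  arr <- array(runif(20 * 16 * 12) < 0.3, c(20, 16, 12))
  m <- binary_mask(arr, 0.7, c(-3, 2, 1))
  mm <- mirror_mask(m, axis = 2)
  expect_equal(sum(mm$data), sum(m$data)) # isometry
  expect_identical(mirror_mask(mm, axis = 2)$data, m$data) # involution
  # plane snapped to half-voxel: mirroring about an off-centre plane too
  m1 <- mirror_mask(m, axis = 1, offset = m$origin[1] + 9.5 * 0.7)
  expect_identical(mirror_mask(m1, axis = 1,
                               offset = m$origin[1] + 9.5 * 0.7)$data, m$data)
  expect_error(mirror_mask(m, axis = 1, offset = 1000), "outside")
})

test_that("mirrored healthy side matches the uninjured contralateral anatomy", {
  spec <- wound_phantom_spec(limb_radius = 15, limb_length = 30,
                             spacing = 0.7, crater_depth = 7,
                             crater_extent = c(10, 8), noise_sd = 0)
  bi0 <- make_bilateral_phantom(spec, missing_fraction = 0)
  m <- mirror_mask(bi0$muscle_mask, axis = 2, offset = bi0$mirror_plane$offset)
  a <- m$data
  b <- bi0$injured_muscle_mask$data # uninjured contralateral compartment
  expect_gt(2 * sum(a & b) / (sum(a) + sum(b)), 0.99)
  # with an injury, the injured compartment is a subset of the mirror
  bi <- coarse_bilateral()
  mi <- mirror_mask(bi$muscle_mask, axis = 2, offset = bi$mirror_plane$offset)
  expect_true(all(!bi$injured_muscle_mask$data[!mi$data]))
})

test_that("boolean subtraction obeys set identities", {
  set.seed(5)
  a <- binary_mask(array(runif(1000) < 0.4, c(10, 10, 10)), 1)
  b <- binary_mask(array(runif(1000) < 0.4, c(10, 10, 10)), 1)
  expect_equal(sum(boolean_subtract(a, a)$data), 0)
  disj <- binary_mask(array(FALSE, c(10, 10, 10)), 1)
  expect_identical(boolean_subtract(a, disj)$data, a$data)
  got <- boolean_subtract(a, b)
  expect_equal(sum(got$data), sum(a$data) - sum(a$data & b$data))
  wrong_grid <- binary_mask(array(FALSE, c(5, 5, 5)), 1)
  expect_error(boolean_subtract(a, wrong_grid), "grid")
})

test_that("mirror + subtract recovers the missing muscle volume", {
  bi <- coarse_bilateral()
  m <- mirror_mask(bi$muscle_mask, axis = 2, offset = bi$mirror_plane$offset)
  diff <- boolean_subtract(m, bi$injured_muscle_mask)
  expect_equal(mask_volume_mm3(diff), bi$removed_mm3, tolerance = 1e-12)
})

test_that("volume scaling hits the requested fraction exactly", {
  cube <- box_mesh(1)
  same <- scale_mesh_to_volume_fraction(cube, 1)
  expect_equal(same$vertices, cube$vertices)
  scaled <- scale_mesh_to_volume_fraction(cube, 0.7)
  expect_equal(mesh_volume(scaled), 0.7, tolerance = 1e-9)
  # edge length becomes 0.7^(1/3) ~ 0.8879
  edge <- max(scaled$vertices[, 1]) - min(scaled$vertices[, 1])
  expect_equal(edge, 0.7^(1 / 3), tolerance = 1e-9)
  # fraction 8 doubles all pairwise distances
  oct <- scale_mesh_to_volume_fraction(cube, 8)
  d0 <- as.matrix(dist(cube$vertices))
  d8 <- as.matrix(dist(oct$vertices))
  expect_equal(d8, 2 * d0, tolerance = 1e-9)
  expect_error(scale_mesh_to_volume_fraction(cube, -1), "positive")
  open_mesh <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(scale_mesh_to_volume_fraction(open_mesh, 0.7), "watertight")
})

test_that("the full contralateral workflow yields a scaled scaffold mesh", {
  bi <- coarse_bilateral()
  sc <- contralateral_scaffold(bi$muscle_mask, bi$injured_muscle_mask,
                               fraction = 0.7,
                               offset = bi$mirror_plane$offset)
  expect_true(is_watertight(sc$mesh))
  v_unscaled <- mesh_volume(mask_to_mesh(sc$difference))
  expect_equal(mesh_volume(sc$mesh) / v_unscaled, 0.7, tolerance = 1e-6)
  # the difference mask volume matches the ground truth
  expect_equal(mask_volume_mm3(sc$difference), bi$removed_mm3)
})
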