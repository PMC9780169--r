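# Synthetic phantoms: determinism, analytic ground truth, engineered voids,
# bilateral symmetry.

test_that("default phantom spec emulates the study wound scale", {
  spec <- wound_phantom_spec()
  expect_equal(spec$crater_extent, c(100, 70)) # 10 cm x 7 cm wound
  expect_equal(spec$crater_depth, 25)          # ~2-3 cm deep
  expect_equal(spec$spacing, 0.35)             # CT voxel size
  expect_equal(spec$tissue_value, 40)
  expect_equal(spec$air_value, -1000)
})

test_that("invalid phantom specs are rejected", {
  expect_error(wound_phantom_spec(crater_depth = 30, limb_radius = 25),
               "smaller than limb_radius")
  expect_error(wound_phantom_spec(crater_extent = c(50, 200),
                                  limb_radius = 60), "wider")
  expect_error(wound_phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("phantom generation is bitwise deterministic under a fixed seed", {
  spec <- wound_phantom_spec(limb_radius = 15, limb_length = 25,
                             crater_shape = "hemisphere", crater_depth = 8,
                             spacing = 0.7, noise_sd = 15, seed = 99)
  a <- make_limb_wound_phantom(spec)
  b <- make_limb_wound_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
})

test_that("noiseless hemisphere crater is recovered by midpoint threshold", {
  ph <- coarse_phantom()
  mid <- (ph$spec$tissue_value + ph$spec$air_value) / 2
  air <- threshold_volume(ph$volume, "fixed", mid)
  got <- air$data & woundpatch:::roi_mask_array(ph$volume, crater_roi(ph))
  truth <- ph$crater_mask$data
  dice <- 2 * sum(got & truth) / (sum(got) + sum(truth))
  expect_gt(dice, 0.99)
})

test_that("analytic crater surface vertices lie on the crater shape", {
  for (shape in c("hemisphere", "superellipsoid", "lobed")) {
    spec <- wound_phantom_spec(limb_radius = 25, limb_length = 60,
                               crater_shape = shape, crater_depth = 12,
                               crater_extent = c(30, 20), spacing = 0.7)
    ph <- make_limb_wound_phantom(spec)
    v <- ph$surface$vertices
    g <- ph$geometry
    dz <- g$z_top - v[, 3]
    dfun <- woundpatch:::crater_depth_fn(spec, v[, 1] - g$crater_center[1],
                                         v[, 2] - g$crater_center[2])
    expect_lt(max(abs(dz - dfun)), 0.01)
  }
})

test_that("placed patch with no voids and no offset has empty ground truth", {
  placed <- hemi_placed()
  expect_equal(placed$voids$count, 0)
  expect_equal(placed$voids$total_volume, 0)
  expect_null(placed$placement_offset)
  # voxelizing the designed patch back in place reproduces the shell mask
  expect_identical(placed$patch_mask$data, hemi_design()$shell$data)
})

test_that("engineered void volumes match carved voxel counts exactly", {
  ph <- hemi_phantom()
  g <- ph$geometry
  cc <- g$crater_center
  ctrs <- rbind(c(cc[1], cc[2], g$z_top - 20),
                c(cc[1] - 10, cc[2], g$z_top - 17.2),
                c(cc[1] + 8, cc[2] + 8, g$z_top - 16.4))
  placed <- make_placed_patch_phantom(ph$volume, hemi_design()$mesh,
    placed_patch_spec(void_centers = ctrs, void_radii = c(1, 2, 3)))
  expect_equal(placed$voids$count, 3)
  expect_equal(placed$voids$voids$volume_mm3,
               placed$voids$voids$voxels * voxel_mm3(ph$volume))
  expect_equal(placed$voids$total_volume, sum(placed$voids$voids$volume_mm3))
})

test_that("voids away from the interface are rejected", {
  ph <- coarse_phantom()
  des <- design_patch(ph$volume, crater_roi(ph), shell_params(3, 1))
  far <- rbind(c(5, 0, ph$geometry$z_top + 5)) # in open air above the plane
  expect_error(
    make_placed_patch_phantom(ph$volume, des$mesh,
      placed_patch_spec(void_centers = far, void_radii = 2)),
    "interface")
})

test_that("a rigid placement perturbation is recorded in provenance", {
  ph <- coarse_phantom()
  des <- design_patch(ph$volume, crater_roi(ph), shell_params(3, 1))
  off <- rigid_rotation(2, c(0, 0, 1), center = mesh_centroid(des$mesh),
                        translation = c(1, 0, 0))
  placed <- make_placed_patch_phantom(ph$volume, des$mesh,
                                      placed_patch_spec(placement_offset = off))
  expect_identical(placed$placement_offset, off)
})

test_that("bilateral phantom with no injury gives exact mirror images", {
  spec <- wound_phantom_spec(limb_radius = 15, limb_length = 30,
                             spacing = 0.7, crater_depth = 7,
                             crater_extent = c(10, 8), noise_sd = 0)
  bi <- make_bilateral_phantom(spec, missing_fraction = 0)
  ny <- dim(bi$healthy$data)[2]
  expect_identical(bi$injured$data, bi$healthy$data[, rev(seq_len(ny)), ])
  expect_equal(bi$removed_mm3, 0)
})

test_that("missing_fraction removes the requested share of muscle volume", {
  bi <- coarse_bilateral()
  frac <- bi$removed_mm3 / mask_volume_mm3(bi$muscle_mask)
  expect_lt(abs(frac - 0.5), 0.05) # within one voxel layer at the cut plane
  expect_equal(mask_volume_mm3(bi$injured_muscle_mask),
               mask_volume_mm3(bi$muscle_mask) - bi$removed_mm3)
})
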