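# Void detection, top/bottom splitting, contact percentage, void statistics.

test_that("engineered voids are detected with volumes within 5%", {
  ph <- hemi_phantom()
  g <- ph$geometry
  cc <- g$crater_center
  ctrs <- rbind(c(cc[1], cc[2], g$z_top - 20),
                c(cc[1] - 10, cc[2], g$z_top - 17.2),
                c(cc[1] + 8, cc[2] + 8, g$z_top - 16.4))
  placed <- make_placed_patch_phantom(ph$volume, hemi_design()$mesh,
    placed_patch_spec(void_centers = ctrs, void_radii = c(1, 2, 3)))
  voids <- detect_voids(placed$volume, ph$tissue_mask, placed$patch_mask)
  expect_equal(voids$count, 3)
  got <- sort(voids$voids$volume_mm3)
  truth <- sort(placed$voids$voids$volume_mm3)
  expect_true(all(abs(got - truth) / truth <= 0.05))
  expect_lt(abs(voids$total_volume - placed$voids$total_volume) /
            placed$voids$total_volume, 0.05)
})

test_that("a perfectly conformal placement has zero voids", {
  placed <- hemi_placed()
  voids <- detect_voids(placed$volume, hemi_phantom()$tissue_mask,
                        placed$patch_mask)
  expect_equal(voids$count, 0)
  expect_equal(voids$total_volume, 0)
})

test_that("sub-floor specks are disregarded and grids must match", {
  # fine grid so one voxel (1.25e-4 mm^3) sits below the 0.001 mm^3 floor
  h <- 0.05
  n <- 24L
  vol <- array(40, c(n, n, n))
  wound <- array(FALSE, c(n, n, n)); wound[, , 1:10] <- TRUE
  patch <- array(FALSE, c(n, n, n)); patch[, , 12:20] <- TRUE
  vol[!wound & !patch] <- -1000
  vol[, , 11] <- 40 # contact layer
  vol[12, 12, 11] <- -1000 # single-voxel speck at the interface
  vv <- voxel_volume(vol, h)
  vs <- detect_voids(vv, binary_mask(wound, h), binary_mask(patch, h))
  expect_equal(vs$count, 0) # 1.25e-4 < 0.001 mm^3
  # enlarge to a 3x3x1 pocket -> 1.125e-3 mm^3, above the floor
  vol[11:13, 11:13, 11] <- -1000
  vv2 <- voxel_volume(vol, h)
  vs2 <- detect_voids(vv2, binary_mask(wound, h), binary_mask(patch, h))
  expect_equal(vs2$count, 1)
  expect_equal(vs2$total_volume, 9 * h^3)
  wrong <- binary_mask(array(FALSE, c(4, 4, 4)), h)
  expect_error(detect_voids(vv, wrong, binary_mask(patch, h)), "grid")
})

test_that("top/bottom splitting excludes vertical walls and is symmetric", {
  slab <- box_mesh(10, 8, 2)
  sp <- split_top_bottom(slab)
  expect_equal(mesh_area(sp$bottom), 80) # footprint exactly
  expect_equal(mesh_area(sp$top), 80)
  sph <- uv_sphere_mesh(5, 32, 64)
  hs <- split_top_bottom(sph)
  expect_equal(mesh_area(hs$top), mesh_area(hs$bottom), tolerance = 1e-9)
  expect_equal(mesh_area(hs$top) + mesh_area(hs$bottom), mesh_area(sph),
               tolerance = 1e-9)
})

test_that("patch bottom submesh hugs the ground-truth crater surface", {
  des <- hemi_design()
  bottom <- split_top_bottom(des$mesh)$bottom
  fp <- woundpatch:::mask_footprint2d(des$shell, erode = 1.5)
  core <- woundpatch:::crop_faces_footprint(bottom, fp,
                                            des$shell$origin[1:2],
                                            des$shell$spacing[1:2])
  pts <- sample_surface(core, 5000, seed = 2)
  rep <- cloud_to_cloud(pts, hemi_phantom()$surface, mesh_samples = 100000)
  expect_lt(rep$max, 0.35) # within one voxel of the analytic surface
})

test_that("contact percentage is 100 for identical surfaces, < 100 for a flat sheet", {
  slab <- box_mesh(10, 10, 1)
  expect_equal(contact_percentage(slab, slab)$contact_percent, 100)
  # contoured "wound": an inverted pyramid surface exceeds its footprint area
  wound <- surface_mesh(
    rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0), c(5, 5, -4)),
    rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))) # top-facing
  flat <- box_mesh(10, 10, 1, origin = c(0, 0, 1))
  rep <- contact_percentage(flat, wound)
  expect_lt(rep$contact_percent, 100)
  expect_equal(rep$sa_bottom, 100)
})

test_that("contact percentage is invariant to a joint rigid transform", {
  placed <- hemi_placed()
  seg <- hemi_design()$segmentation
  pm <- mask_to_mesh(placed$patch_mask)
  wm <- mask_to_mesh(seg$tissue)
  r0 <- contact_percentage(pm, wm, crop_margin = 0.7)
  tf <- rigid_rotation(90, c(0, 0, 1), center = c(30, 0, 0),
                       translation = c(4, -7, 2))
  r1 <- contact_percentage(transform_mesh(pm, tf), transform_mesh(wm, tf),
                           crop_margin = 0.7)
  expect_equal(r0$contact_percent, r1$contact_percent, tolerance = 1e-3)
})

test_that("void-volume comparison mirrors the study's statistical sequence", {
  a <- void_set(data.frame(id = 1:5, volume_mm3 = c(1, 2, 3, 4, 5),
                           cx = 0, cy = 0, cz = 0, voxels = 1:5))
  same <- compare_void_volumes(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$fold_change_total, 1)
  # totals 2 vs 9.6 -> 4.8-fold
  s1 <- void_set(data.frame(id = 1:3, volume_mm3 = c(0.5, 0.5, 1),
                            cx = 0, cy = 0, cz = 0, voxels = 1))
  s2 <- void_set(data.frame(id = 1:3, volume_mm3 = c(2.4, 3.2, 4.0),
                            cx = 0, cy = 0, cz = 0, voxels = 1))
  expect_equal(compare_void_volumes(s1, s2)$fold_change_total, 4.8)
  tiny <- void_set(data.frame(id = 1:2, volume_mm3 = c(1, 2),
                              cx = 0, cy = 0, cz = 0, voxels = 1))
  expect_error(compare_void_volumes(tiny, a), "at least 3")
})

test_that("the log-scale t-test detects a 10x shift in void volumes", {
  mkset <- function(vols) void_set(data.frame(
    id = seq_along(vols), volume_mm3 = vols, cx = 0, cy = 0, cz = 0,
    voxels = seq_along(vols)))
  hits <- 0L
  reps <- 200L
  with_seed <- woundpatch:::with_seed
  with_seed(42L, {
    for (r in seq_len(reps)) {
      a <- mkset(10^rnorm(50, mean = -1, sd = 0.5))
      b <- mkset(10^rnorm(50, mean = 0, sd = 0.5)) # 10x median shift
      cmp <- compare_void_volumes(a, b)
      if (cmp$p.value < 0.05) hits <- hits + 1L
    }
  })
  expect_gte(hits / reps, 0.95)
})
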