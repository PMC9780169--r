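# Surface sampling, rigid alignment, ICP, cloud-to-cloud deviations.

test_that("surface sampling is area-weighted, uniform and deterministic", {
  # single square face pair: mean position at the centroid
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  n <- 20000
  pts <- sample_surface(sq, n, seed = 4)
  se <- sqrt(1 / 12 / n) # sd of uniform[0,1] mean
  expect_lt(abs(mean(pts[, 1]) - 0.5), 3 * se)
  expect_lt(abs(mean(pts[, 2]) - 0.5), 3 * se)
  expect_identical(pts, sample_surface(sq, n, seed = 4))
  # two faces with areas 1 : 4 -> sample counts ~ proportional (binomial)
  two <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0),
                            c(10, 0, 0), c(14, 0, 0), c(10, 2, 0)),
                      rbind(c(1, 2, 3), c(4, 5, 6)))
  pts2 <- sample_surface(two, n, seed = 8)
  n_small <- sum(pts2[, 1] < 5)
  p <- 1 / 5
  expect_lt(abs(n_small - n * p), 4 * sqrt(n * p * (1 - p)))
  expect_error(sample_surface(sq, 2), "3 samples")
})

test_that("bounding-box alignment is a pure translation", {
  set.seed(2)
  a <- matrix(rnorm(300), ncol = 3)
  t_id <- align_bbox_centers(a, a)
  expect_equal(t_id$translation, c(0, 0, 0))
  expect_identical(t_id$rotation, diag(3))
  b <- sweep(a, 2, c(5, 0, 0), `+`)
  t_sh <- align_bbox_centers(a, b)
  expect_equal(t_sh$translation, c(5, 0, 0))
  expect_identical(t_sh$rotation, diag(3))
})

test_that("ICP recovers known rigid perturbations on noiseless clouds", {
  set.seed(13)
  pts <- matrix(rnorm(3000, sd = 10), ncol = 3) # asymmetric blob
  tf <- rigid_rotation(10, c(0.2, -0.5, 1), center = c(2, 1, 0),
                       translation = c(5, -3, 2))
  dst <- apply_transform(tf, pts)
  est <- icp_refine(pts, dst, init = align_bbox_centers(pts, dst))
  ang_err <- woundpatch:::rotation_angle_deg(t(est$rotation) %*% tf$rotation)
  expect_lt(ang_err, 0.05)
  expect_lt(sqrt(sum((est$translation - tf$translation)^2)), 0.05)
  # exact init converges immediately
  est2 <- icp_refine(pts, dst, init = tf)
  expect_lte(est2$iterations, 2)
  expect_true(est2$converged)
  # objective is non-increasing
  expect_true(all(diff(est$objective_trace) <= 1e-9))
})

test_that("cloud-to-cloud deviations match constructed offsets", {
  set.seed(31)
  plane <- cbind(runif(2000, 0, 50), runif(2000, 0, 50), 0)
  self <- cloud_to_cloud(plane, plane)
  expect_equal(self$mean_abs, 0)
  expect_equal(self$max, 0)
  # parallel plane 1.55 mm away (dense reference grid)
  ref <- as.matrix(expand.grid(x = seq(0, 50, 0.5), y = seq(0, 50, 0.5),
                               z = 1.55))
  offset <- cloud_to_cloud(plane, ref)
  expect_equal(offset$mean_abs, 1.55, tolerance = 0.01)
  expect_equal(sum(offset$histogram$count), offset$n)
  # concentric spheres differing by delta in radius
  s1 <- sample_surface(uv_sphere_mesh(10, 48, 96), 5000, seed = 1)
  s2 <- sample_surface(uv_sphere_mesh(10.5, 64, 128), 50000, seed = 2)
  conc <- cloud_to_cloud(s1, s2)
  expect_equal(conc$mean_abs, 0.5, tolerance = 0.05)
})

test_that("deviation histogram uses the requested bin width", {
  d <- cloud_to_cloud(cbind(0, 0, c(0.05, 0.14, 0.31)),
                      cbind(0, 0, 0), bin_width = 0.1)
  expect_equal(d$histogram$bin_start, c(0, 0.1, 0.2, 0.3))
  expect_equal(d$histogram$count, c(1L, 1L, 0L, 1L))
})

test_that("gauging between near-coincident surfaces is symmetric", {
  a <- uv_sphere_mesh(10, 48, 96)
  b <- uv_sphere_mesh(10.3, 48, 96)
  ab <- gauge_meshes(a, b, samples = 4000, seed = 3)
  ba <- gauge_meshes(b, a, samples = 4000, seed = 3)
  expect_equal(ab$mean_abs, ba$mean_abs, tolerance = 0.1)
})

test_that("rigid transforms validate orthonormality", {
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
  bad <- diag(3)
  bad[1, 1] <- -1
  expect_error(rigid_transform(bad), "proper")
  tf <- rigid_rotation(30, c(1, 1, 0))
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-12)
  inv <- invert_transform(tf)
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(inv, apply_transform(tf, p)), p,
               tolerance = 1e-12)
})
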