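# Slicing, perimeters, rectilinear infill, regional modifiers, G-code
# planning.

test_that("a 10 mm cube slices into 62 square layers", {
  m <- box_mesh(10)
  sl <- slice_mesh(m, 0.16)
  expect_equal(length(sl$z), 62)
  areas <- vapply(sl$layers, polygon_area, numeric(1))
  expect_equal(areas, rep(100, 62), tolerance = 1e-9)
  L <- sl$layers[[31]][[1]]
  expect_equal(range(L[, 1]), c(0, 10))
  expect_equal(range(L[, 2]), c(0, 10))
  open_mesh <- surface_mesh(m$vertices, m$faces[-1, ])
  expect_error(slice_mesh(open_mesh, 0.16), "watertight")
})

test_that("sphere slice areas follow pi (r^2 - z^2) and integrate to the volume", {
  sph <- uv_sphere_mesh(10, nlat = 64, nlon = 128)
  sl <- slice_mesh(sph, 0.5)
  areas <- vapply(sl$layers, polygon_area, numeric(1))
  truth <- pi * pmax(0, 100 - sl$z^2)
  sel <- abs(sl$z) < 8
  expect_lt(max(abs(areas[sel] - truth[sel]) / truth[sel]), 0.02)
  expect_lt(abs(sum(areas * 0.5) - mesh_volume(sph)) / mesh_volume(sph), 0.02)
})

test_that("perimeters sit at (i + 1/2) width insets and shrink monotonically", {
  sq <- list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  peri <- make_perimeters(sq, 2, 0.4)
  expect_length(peri, 2)
  for (i in 1:2) {
    L <- peri[[i]][[1]]
    inset <- pmin(L[, 1], 10 - L[, 1], L[, 2], 10 - L[, 2])
    expect_equal(mean(inset), (i - 0.5) * 0.4, tolerance = 0.03)
  }
  len <- vapply(peri, function(p) {
    L <- p[[1]]
    sum(sqrt(diff(c(L[, 1], L[1, 1]))^2 + diff(c(L[, 2], L[1, 2]))^2))
  }, numeric(1))
  expect_lt(len[2], len[1]) # convex polygon: inner loop is shorter
  # a 0.5 mm sliver cannot hold two perimeters
  sliver <- list(cbind(c(0, 10, 10, 0), c(0, 0, 0.5, 0.5)))
  expect_lte(length(make_perimeters(sliver, 2, 0.4)), 1)
})

test_that("infill spacing is width / density and the fill fraction is exact", {
  sq <- list(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50)))
  fill <- rectilinear_infill(sq, 0.4, 0, 0.4, connect = FALSE)
  ys <- sort(vapply(fill, function(L) L[1, 2], numeric(1)))
  expect_equal(unique(round(diff(ys), 9)), 1.0) # 0.4 mm / 40% -> 1000 um
  len <- sum(vapply(fill, function(L)
    sum(sqrt(diff(L[, 1])^2 + diff(L[, 2])^2)), numeric(1)))
  frac <- len * 0.4 * 0.16 / (2500 * 0.16)
  expect_equal(frac, 0.40, tolerance = 1e-9)
  # connected zigzags stay within the band
  fillc <- rectilinear_infill(sq, 0.4, 0, 0.4, connect = TRUE)
  lenc <- sum(vapply(fillc, function(L)
    sum(sqrt(diff(L[, 1])^2 + diff(L[, 2])^2)), numeric(1)))
  expect_equal(lenc * 0.4 * 0.16 / (2500 * 0.16), 0.40, tolerance = 0.02)
  # density 1 -> solid: spacing equals the width
  solid <- rectilinear_infill(sq, 1, 0, 0.4, connect = FALSE)
  ys2 <- sort(vapply(solid, function(L) L[1, 2], numeric(1)))
  expect_equal(unique(round(diff(ys2), 9)), 0.4)
})

test_that("infill lines stay inside the polygon dilated by the overlap band", {
  sq <- list(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50)))
  for (ang in c(0, 37, 45, 90)) {
    fill <- rectilinear_infill(sq, 0.4, ang, 0.4, connect = TRUE)
    pts <- do.call(rbind, fill)
    tol <- 0.5 * 0.4 + 1e-9
    expect_true(all(pts[, 1] >= -tol & pts[, 1] <= 50 + tol))
    expect_true(all(pts[, 2] >= -tol & pts[, 2] <= 50 + tol))
  }
})

test_that("regional thirds at 20/30/40% extrude volume in ratio 2:3:4", {
  m <- box_mesh(60, 20, 3)
  mods <- list(region_modifier(0.2, angle = 45, span = c(0, 1/3), axis = 1),
               region_modifier(0.3, angle = 45, span = c(1/3, 2/3), axis = 1),
               region_modifier(0.4, angle = 45, span = c(2/3, 1), axis = 1))
  tp <- make_toolpath(m, print_settings(perimeters = 0, top_bottom_layers = 0,
                                        connect_infill = FALSE,
                                        infill_angle = 45),
                      modifiers = mods)
  vol3 <- c(0, 0, 0)
  angs <- numeric(0)
  for (lay in tp$layers) for (p in lay$paths) {
    P <- p$points
    mid <- (P[1, 1] + P[nrow(P), 1]) / 2
    third <- pmin(3, floor(mid / 20) + 1)
    seg <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
    vol3[third] <- vol3[third] + sum(seg) * 0.4 * 0.16
    d <- diff(P)
    angs <- c(angs, (atan2(d[, 2], d[, 1]) * 180 / pi) %% 180)
  }
  expect_equal(vol3 / vol3[1] * 2, c(2, 3, 4), tolerance = 0.05)
  # unipennate: every infill direction at 45 degrees (mod 180)
  expect_true(all(abs(angs - 45) < 0.1))
})

test_that("overlapping region modifiers are rejected and empty lists are identity", {
  m <- box_mesh(30, 10, 2)
  bad <- list(region_modifier(0.2, span = c(0, 0.6), axis = 1),
              region_modifier(0.4, span = c(0.5, 1), axis = 1))
  expect_error(make_toolpath(m, print_settings(), modifiers = bad), "overlap")
  s <- print_settings(perimeters = 0, top_bottom_layers = 0,
                      connect_infill = FALSE)
  tp0 <- make_toolpath(m, s)
  tp1 <- make_toolpath(m, s, modifiers = list())
  expect_identical(tp0$layers, tp1$layers)
})

test_that("G-code E totals are exact length x width x height x flow sums", {
  m <- box_mesh(20, 20, 2)
  s <- print_settings(perimeters = 0, top_bottom_layers = 0,
                      connect_infill = FALSE)
  tp <- make_toolpath(m, s)
  plan <- plan_gcode(tp)
  total_len <- 0
  for (lay in tp$layers) for (p in lay$paths) {
    P <- p$points
    total_len <- total_len + sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
  }
  expect_equal(max(plan$program$moves$e),
               total_len * 0.4 * 0.16 * 1.0, tolerance = 1e-9)
  # doubling flow doubles volume, not time
  s2 <- print_settings(perimeters = 0, top_bottom_layers = 0,
                       connect_infill = FALSE, flow = 2)
  plan2 <- plan_gcode(make_toolpath(m, s2), s2)
  expect_equal(plan2$estimate$bioink_volume_ml,
               2 * plan$estimate$bioink_volume_ml)
  expect_equal(plan2$estimate$print_time_s, plan$estimate$print_time_s)
})

test_that("bioink volume tracks infill density and stays below solid", {
  # height an exact multiple of the layer height so sliced volume = mesh volume
  m <- box_mesh(20, 20, 1.92)
  est <- function(density) {
    s <- print_settings(perimeters = 0, top_bottom_layers = 0,
                        infill_density = density, connect_infill = FALSE)
    plan_gcode(make_toolpath(m, s), s)$estimate$bioink_volume_ml * 1000
  }
  v40 <- est(0.4)
  v100 <- est(1.0)
  expect_lt(v40, v100)
  # volumetric consistency: bioink volume / mesh volume = density +- 2%
  expect_equal(v40 / mesh_volume(m), 0.40, tolerance = 0.02)
})

test_that("identical settings and mesh give byte-identical G-code", {
  m <- box_mesh(15, 10, 1.5)
  s <- print_settings()
  f1 <- withr::local_tempfile(fileext = ".gcode")
  f2 <- withr::local_tempfile(fileext = ".gcode")
  write_gcode(plan_gcode(make_toolpath(m, s), s)$program, f1)
  write_gcode(plan_gcode(make_toolpath(m, s), s)$program, f2)
  expect_identical(readLines(f1), readLines(f2))
})
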