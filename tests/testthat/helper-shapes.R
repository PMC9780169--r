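# Shared geometric fixtures, all built in code.

# axis-aligned box mesh (12 triangles, outward normals)
box_mesh <- function(a = 1, b = a, c_ = a, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, b), z = c(0, c_)))
  v <- sweep(v, 2, origin, `+`)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = c
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = b
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = a
  surface_mesh(v, f, "box")
}

# parametric UV sphere (watertight)
uv_sphere_mesh <- function(r = 1, nlat = 32, nlon = 64, center = c(0, 0, 0)) {
  lat <- seq(0, pi, length.out = nlat + 1)[-c(1, nlat + 1)]
  lon <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  ring <- function(phi) cbind(r * sin(phi) * cos(lon),
                              r * sin(phi) * sin(lon),
                              r * cos(phi))
  v <- rbind(c(0, 0, r), do.call(rbind, lapply(lat, ring)), c(0, 0, -r))
  v <- sweep(v, 2, center, `+`)
  idx <- function(i, j) 1 + (i - 1) * nlon + ((j - 1) %% nlon) + 1
  f <- list()
  for (j in seq_len(nlon)) f[[length(f) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in seq_len(nlat - 2)) for (j in seq_len(nlon)) {
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  last <- nrow(v)
  for (j in seq_len(nlon))
    f[[length(f) + 1]] <- c(last, idx(nlat - 1, j + 1), idx(nlat - 1, j))
  surface_mesh(v, do.call(rbind, f), "uv sphere")
}

# voxelized ball mask
ball_mask <- function(r = 10, h = 0.35, pad = 2) {
  xs <- seq(-r - pad, r + pad, by = h)
  n <- length(xs)
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- outer(xs^2, xs^2, `+`) + xs[k]^2 <= r^2
  binary_mask(arr, h, rep(-r - pad, 3))
}

# cached expensive fixtures (built once per test session)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the study-resolution hemisphere wound phantom (0.35 mm voxels, 20 mm deep)
hemi_phantom <- function() fixture("hemi_phantom", function() {
  make_limb_wound_phantom(wound_phantom_spec(
    limb_radius = 28, limb_length = 60, crater_shape = "hemisphere",
    crater_depth = 20, spacing = 0.35, noise_sd = 0, seed = 1))
})

hemi_design <- function() fixture("hemi_design", function() {
  ph <- hemi_phantom()
  design_patch(ph$volume, crater_roi(ph), shell_params(thickness = 4,
                                                       smooth_window = 3))
})

hemi_placed <- function() fixture("hemi_placed", function() {
  make_placed_patch_phantom(hemi_phantom()$volume, hemi_design()$mesh)
})

# a coarse phantom for cheaper tests
coarse_phantom <- function() fixture("coarse_phantom", function() {
  make_limb_wound_phantom(wound_phantom_spec(
    limb_radius = 20, limb_length = 45, crater_shape = "hemisphere",
    crater_depth = 12, spacing = 0.7, noise_sd = 0, seed = 3))
})

coarse_bilateral <- function() fixture("coarse_bilateral", function() {
  make_bilateral_phantom(wound_phantom_spec(
    limb_radius = 25, limb_length = 70, spacing = 0.7, crater_depth = 10,
    crater_extent = c(20, 15), noise_sd = 0, seed = 2),
    missing_fraction = 0.5)
})
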