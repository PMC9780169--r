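# Synthetic CT phantoms with analytic ground truth.
#
# The phantom limb is a cylinder (axis along x) whose top is cut by a flat
# "surgical field" plane; the wound crater is carved into that plane. The flat
# top makes the crater cavity equal the analytic crater shape exactly, so
# segmentation and shell accuracy can always be judged against closed forms.

# evaluate `code` under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a limb-with-wound CT phantom
#'
#' Defaults emulate the standardized open wound of the study: a crater
#' roughly 10 cm long by 7 cm wide and 2.5 cm deep in soft tissue
#' (approximately 40 HU), imaged at 0.35 mm isotropic voxels, with air at
#' -1000 HU. \code{crater_shape} "hemisphere" uses \code{crater_depth} as its
#' radius; "superellipsoid" (exponent 4) gives the boxy template-like wound;
#' "lobed" modulates an ellipsoid with three angular lobes.
#'
#' @param limb_radius cylinder radius (mm).
#' @param limb_length cylinder length along x (mm).
#' @param crater_shape "hemisphere", "superellipsoid" or "lobed".
#' @param crater_depth crater depth below the surgical plane (mm).
#' @param crater_extent length and width of the crater footprint (mm).
#' @param tissue_value,air_value HU-like grey values.
#' @param noise_sd standard deviation of additive Gaussian noise (HU-like).
#' @param spacing isotropic voxel size (mm).
#' @param seed RNG seed for the noise.
#' @param flat_cut fraction of the radius at which the top of the limb is cut
#'   flat (plane z = centre + flat_cut * radius).
#' @param air_margin air padding above the surgical plane (mm).
#' @return A list of class \code{wound_phantom_spec}.
#' @export
wound_phantom_spec <- function(limb_radius = 60, limb_length = 140,
                               crater_shape = c("superellipsoid", "hemisphere",
                                                "lobed"),
                               crater_depth = 25, crater_extent = c(100, 70),
                               tissue_value = 40, air_value = -1000,
                               noise_sd = 0, spacing = 0.35, seed = 1L,
                               flat_cut = 0.5, air_margin = 10) {
  crater_shape <- match.arg(crater_shape)
  if (crater_shape == "hemisphere") crater_extent <- rep(2 * crater_depth, 2)
  spec <- list(limb_radius = limb_radius, limb_length = limb_length,
               crater_shape = crater_shape, crater_depth = crater_depth,
               crater_extent = crater_extent, tissue_value = tissue_value,
               air_value = air_value, noise_sd = noise_sd, spacing = spacing,
               seed = as.integer(seed), flat_cut = flat_cut,
               air_margin = air_margin)
  class(spec) <- "wound_phantom_spec"
  validate_wound_spec(spec)
  spec
}

validate_wound_spec <- function(spec) {
  if (spec$crater_depth >= spec$limb_radius)
    stop("crater_depth must be smaller than limb_radius")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$spacing <= 0) stop("spacing must be positive")
  flat_halfwidth <- spec$limb_radius * sqrt(1 - spec$flat_cut^2)
  if (spec$crater_extent[2] / 2 > flat_halfwidth)
    stop("crater wider than the flat top of the limb")
  if (spec$crater_extent[1] > spec$limb_length)
    stop("crater longer than the limb")
  if (spec$crater_depth > spec$limb_radius * (1 + spec$flat_cut) - spec$spacing)
    stop("crater would pierce the bottom of the limb")
  invisible(spec)
}

# crater membership for world coordinates (vectorized); dz = z_top - z >= 0
crater_depth_fn <- function(spec, dx, dy) {
  a <- spec$crater_extent[1] / 2
  b <- spec$crater_extent[2] / 2
  D <- spec$crater_depth
  switch(spec$crater_shape,
    hemisphere = {
      r2 <- dx^2 + dy^2
      out <- numeric(length(dx))
      inside <- r2 < D^2
      out[inside] <- sqrt(D^2 - r2[inside])
      out
    },
    superellipsoid = {
      u <- (abs(dx) / a)^4 + (abs(dy) / b)^4
      out <- numeric(length(dx))
      inside <- u < 1
      out[inside] <- D * (1 - u[inside])^(1 / 4)
      out
    },
    lobed = {
      th <- atan2(dy / b, dx / a)
      rho <- 1 + 0.15 * cos(3 * th)
      u <- (dx / (a * rho))^2 + (dy / (b * rho))^2
      out <- numeric(length(dx))
      inside <- u < 1
      out[inside] <- D * sqrt(1 - u[inside])
      out
    })
}

phantom_geometry <- function(spec) {
  h <- spec$spacing
  R <- spec$limb_radius
  cz <- 0
  z_top <- cz + spec$flat_cut * R
  margin <- 2
  list(h = h, R = R, cy = 0, cz = cz, z_top = z_top,
       x0 = -margin, x1 = spec$limb_length + margin,
       y0 = -R - margin, y1 = R + margin,
       z0 = cz - R - margin, z1 = z_top + spec$air_margin,
       crater_center = c(spec$limb_length / 2, 0))
}

#' Generate a limb CT phantom with an open wound crater
#'
#' @param spec a [wound_phantom_spec()].
#' @return A list with \code{volume} (the [voxel_volume()]),
#'   \code{surface} (analytic crater-surface [surface_mesh()], vertices lying
#'   exactly on the crater shape), \code{crater_mask} (ground-truth cavity
#'   [binary_mask()]), \code{tissue_mask}, \code{geometry} (internal
#'   coordinates: surgical plane height, crater centre) and \code{spec}.
#' @export
make_limb_wound_phantom <- function(spec) {
  stopifnot(inherits(spec, "wound_phantom_spec"))
  validate_wound_spec(spec)
  g <- phantom_geometry(spec)
  h <- g$h
  xs <- seq(g$x0, g$x1, by = h)
  ys <- seq(g$y0, g$y1, by = h)
  zs <- seq(g$z0, g$z1, by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  # tissue: cylinder cross-section in (y,z), cut flat at z_top
  yz_in <- outer(ys - g$cy, zs - g$cz,
                 function(y, z) y^2 + z^2 <= g$R^2) &
           outer(rep(TRUE, ny), zs <= g$z_top + 1e-12)
  x_in <- xs >= 0 & xs <= spec$limb_length
  tissue <- array(FALSE, c(nx, ny, nz))
  tissue[x_in, , ] <- rep(yz_in, each = sum(x_in))
  # crater cavity: depth function below the surgical plane
  dx <- xs - g$crater_center[1]
  dy <- ys - g$crater_center[2]
  depth_xy <- matrix(crater_depth_fn(spec, rep(dx, ny), rep(dy, each = nx)),
                     nx, ny)
  zrel <- g$z_top - zs # depth of each slice below the plane
  crater <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    if (zrel[k] < 0) next
    crater[, , k] <- depth_xy > zrel[k]
  }
  crater <- crater & tissue
  tissue <- tissue & !crater
  vol <- array(spec$air_value, c(nx, ny, nz))
  vol[tissue] <- spec$tissue_value
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(spec$seed,
                           array(rnorm(length(vol), 0, spec$noise_sd),
                                 dim(vol)))
  origin <- c(xs[1], ys[1], zs[1])
  vv <- voxel_volume(vol, h, origin)
  list(volume = vv,
       surface = crater_surface_mesh(spec, g),
       crater_mask = binary_mask(crater, h, origin, "wound"),
       tissue_mask = binary_mask(tissue, h, origin, "tissue"),
       geometry = g,
       spec = spec)
}

#' Region of interest bounding a phantom's crater
#'
#' The inversion ROI for [invert_wound()] / [segment_wound()]: the crater
#' footprint plus a margin laterally, reaching from below the crater floor up
#' to the surgical plane (so the complement of tissue within it is the
#' cavity and nothing else).
#'
#' @param phantom a [make_limb_wound_phantom()] result, or its \code{spec}
#'   plus \code{geometry}.
#' @param margin lateral/depth margin in mm.
#' @export
crater_roi <- function(phantom, margin = 2) {
  spec <- phantom$spec
  g <- phantom$geometry
  cc <- g$crater_center
  roi_box(cc[1] + c(-1, 1) * (spec$crater_extent[1] / 2 + margin),
          cc[2] + c(-1, 1) * (spec$crater_extent[2] / 2 + margin),
          c(g$z_top - spec$crater_depth - margin, g$z_top))
}

# analytic triangulated crater surface (polar grid over the footprint)
crater_surface_mesh <- function(spec, g, n_r = 60, n_th = 120) {
  a <- spec$crater_extent[1] / 2
  b <- spec$crater_extent[2] / 2
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  # footprint boundary radius for each angle (unit-scaled)
  rmax <- switch(spec$crater_shape,
    hemisphere = rep(spec$crater_depth, n_th),
    superellipsoid = {
      u <- (abs(cos(th)))^4 / a^4 + (abs(sin(th)))^4 / b^4
      u^(-1 / 4)
    },
    lobed = {
      # along the ray (cos th, sin th) the lobe phase is fixed:
      psi <- atan2(sin(th) / b, cos(th) / a)
      rho <- 1 + 0.15 * cos(3 * psi)
      1 / sqrt((cos(th) / (a * rho))^2 + (sin(th) / (b * rho))^2)
    })
  fr <- seq(0, 1, length.out = n_r + 1)
  verts <- matrix(0, nrow = 1 + n_r * n_th, ncol = 3)
  cc <- g$crater_center
  verts[1, ] <- c(cc[1], cc[2],
                  g$z_top - crater_depth_fn(spec, 0, 0))
  idx <- function(i_r, i_th) 1 + (i_r - 1) * n_th + ((i_th - 1) %% n_th) + 1
  for (i_r in seq_len(n_r)) {
    r <- fr[i_r + 1] * rmax
    x <- cc[1] + r * cos(th)
    y <- cc[2] + r * sin(th)
    z <- g$z_top - crater_depth_fn(spec, x - cc[1], y - cc[2])
    # boundary ring sits exactly on the surgical plane
    if (i_r == n_r) z <- rep(g$z_top, n_th)
    verts[idx(i_r, seq_len(n_th)), ] <- cbind(x, y, z)
  }
  faces <- list()
  for (i_th in seq_len(n_th)) {
    faces[[length(faces) + 1]] <- c(1, idx(1, i_th), idx(1, i_th + 1))
  }
  for (i_r in seq_len(n_r - 1)) {
    for (i_th in seq_len(n_th)) {
      v00 <- idx(i_r, i_th); v01 <- idx(i_r, i_th + 1)
      v10 <- idx(i_r + 1, i_th); v11 <- idx(i_r + 1, i_th + 1)
      faces[[length(faces) + 1]] <- c(v00, v10, v11)
      faces[[length(faces) + 1]] <- c(v00, v11, v01)
    }
  }
  surface_mesh(verts, do.call(rbind, faces),
               provenance = sprintf("analytic %s crater surface",
                                    spec$crater_shape))
}

# ------------------------------------------------------------- placed patch

#' Specification for voxelizing a printed patch onto a wound CT
#'
#' Emulates the post-implantation scan: the printed patch (contrast-enhanced,
#' default 300 HU-like as with barium sulfate doping) rests in the wound
#' cavity; optional spherical air voids of known volume are carved at the
#' patch-wound interface, and an optional rigid placement perturbation can be
#' applied to the patch before voxelization.
#'
#' @param patch_value grey value of the patch (HU-like).
#' @param void_centers NULL or an n x 3 matrix of void centres (mm).
#' @param void_radii numeric vector of void radii (mm), one per centre.
#' @param placement_offset NULL or a [rigid_transform()] applied to the patch
#'   mesh before voxelization.
#' @export
placed_patch_spec <- function(patch_value = 300, void_centers = NULL,
                              void_radii = NULL, placement_offset = NULL) {
  if (is.null(void_centers)) {
    void_centers <- matrix(numeric(0), ncol = 3)
    void_radii <- numeric(0)
  }
  void_centers <- matrix(as.numeric(void_centers), ncol = 3)
  if (nrow(void_centers) != length(void_radii))
    stop("need one radius per void centre")
  structure(list(patch_value = patch_value, void_centers = void_centers,
                 void_radii = as.numeric(void_radii),
                 placement_offset = placement_offset),
            class = "placed_patch_spec")
}

#' Voxelize a patch onto a wound phantom with engineered interface voids
#'
#' @param wound a wound phantom [voxel_volume()] (air-filled crater).
#' @param patch the patch [surface_mesh()] (watertight, world mm).
#' @param spec a [placed_patch_spec()].
#' @param air_threshold grey value below which a voxel counts as air.
#' @return A list with \code{volume} (patch at \code{patch_value}, voids
#'   carved back to air), \code{patch_mask}, and \code{voids}: the ground
#'   truth [void_set()] whose volumes are the exactly carved voxel volumes.
#' @export
make_placed_patch_phantom <- function(wound, patch, spec = placed_patch_spec(),
                                      air_threshold = -500) {
  stopifnot(inherits(wound, "voxel_volume"), inherits(patch, "surface_mesh"),
            inherits(spec, "placed_patch_spec"))
  mesh <- patch
  if (!is.null(spec$placement_offset))
    mesh <- transform_mesh(mesh, spec$placement_offset)
  bb <- apply(mesh$vertices, 2, range)
  ax <- voxel_axes(wound)
  if (bb[1, 1] < ax$x[1] - wound$spacing[1] ||
      bb[2, 1] > tail(ax$x, 1) + wound$spacing[1] ||
      bb[1, 2] < ax$y[1] - wound$spacing[2] ||
      bb[2, 2] > tail(ax$y, 1) + wound$spacing[2] ||
      bb[1, 3] < ax$z[1] - wound$spacing[3] ||
      bb[2, 3] > tail(ax$z, 1) + wound$spacing[3])
    stop("patch does not fit within the volume bounds after placement")
  inside <- cpp_voxelize(mesh$vertices, mesh$faces, dim(wound$data),
                         wound$spacing, wound$origin)
  dim(inside) <- dim(wound$data)
  air <- wound$data < air_threshold
  patch_vox <- inside & air # patch occupies air space only
  vol <- wound$data
  vol[patch_vox] <- spec$patch_value
  tissue <- !air
  nv <- nrow(spec$void_centers)
  void_rows <- list()
  carved_total <- array(FALSE, dim(vol))
  for (v in seq_len(nv)) {
    ctr <- spec$void_centers[v, ]
    rad <- spec$void_radii[v]
    if (rad <= max(wound$spacing))
      stop("void radius must exceed the voxel spacing to be resolvable")
    sph <- sphere_voxels(wound, ctr, rad)
    carved <- sph & patch_vox
    near <- dilate1(sph, dim(vol))
    if (!any(carved) || !any(near & tissue))
      stop("void ", v, " is not at the wound-patch interface")
    vol[carved] <- wound$data[carved] # back to (air) background values
    carved_total <- carved_total | carved
    void_rows[[v]] <- data.frame(
      id = v,
      volume_mm3 = sum(carved) * voxel_mm3(wound),
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      voxels = sum(carved))
  }
  patch_vox <- patch_vox & !carved_total
  out_vol <- voxel_volume(vol, wound$spacing, wound$origin)
  list(volume = out_vol,
       patch_mask = mask_like(wound, patch_vox, "patch"),
       voids = void_set(do.call(rbind, void_rows)),
       placement_offset = spec$placement_offset)
}

sphere_voxels <- function(vol, center, radius) {
  ax <- voxel_axes(vol)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  d <- dim(vol$data)
  arr <- array(FALSE, d)
  # restrict to the bounding sub-grid of the sphere
  xi <- which(dx2 <= radius^2)
  yi <- which(dy2 <= radius^2)
  zi <- which(dz2 <= radius^2)
  if (!length(xi) || !length(yi) || !length(zi)) return(arr)
  sub <- outer(dx2[xi], dy2[yi], `+`)
  sub <- outer(sub, dz2[zi], `+`) <= radius^2
  arr[xi, yi, zi] <- sub
  arr
}

# 6-neighbourhood binary dilation by one voxel
dilate1 <- function(mask, d) {
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

# --------------------------------------------------------- bilateral phantom

#' Generate a bilateral pair of limbs for the contralateral workflow
#'
#' Both limbs carry an ellipsoidal "muscle" compartment (elevated grey value);
#' the injured side lacks \code{missing_fraction} of that compartment's
#' volume, removed as an open defect (top cap of the ellipsoid set to air).
#' The injured limb is the mirror image of the healthy one, so the two
#' volumes share one grid and the mirror-and-subtract workflow can be tested
#' voxel-exactly.
#'
#' @param spec a [wound_phantom_spec()]; the crater parameters are ignored,
#'   the limb/tissue/noise/spacing parameters are used.
#' @param missing_fraction fraction of the muscle volume missing on the
#'   injured side (0 <= f < 1).
#' @param muscle_value grey value of the muscle compartment.
#' @return List with \code{healthy}, \code{injured} ([voxel_volume()]s),
#'   \code{muscle_mask} (ground-truth full compartment on the healthy side),
#'   \code{injured_muscle_mask}, and \code{removed_mm3}.
#' @export
make_bilateral_phantom <- function(spec, missing_fraction = 0.5,
                                   muscle_value = 80) {
  stopifnot(inherits(spec, "wound_phantom_spec"))
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  g <- phantom_geometry(spec)
  h <- g$h
  xs <- seq(g$x0, g$x1, by = h)
  ys <- seq(g$y0, g$y1, by = h)
  zs <- seq(g$z0, g$z1, by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  yz_in <- outer(ys - g$cy, zs - g$cz,
                 function(y, z) y^2 + z^2 <= g$R^2) &
           outer(rep(TRUE, ny), zs <= g$z_top + 1e-12)
  x_in <- xs >= 0 & xs <= spec$limb_length
  tissue <- array(FALSE, c(nx, ny, nz))
  tissue[x_in, , ] <- rep(yz_in, each = sum(x_in))
  # elongated muscle compartment under the surgical plane
  mc <- c(spec$limb_length / 2, 0, g$z_top - 0.35 * g$R)
  semi <- c(0.30 * spec$limb_length, 0.45 * g$R, 0.28 * g$R)
  ux <- ((xs - mc[1]) / semi[1])^2
  uy <- ((ys - mc[2]) / semi[2])^2
  uz <- ((zs - mc[3]) / semi[3])^2
  uxy <- outer(ux, uy, `+`)
  muscle <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) muscle[, , k] <- uxy + uz[k] < 1
  muscle <- muscle & tissue
  vol <- array(spec$air_value, c(nx, ny, nz))
  vol[tissue] <- spec$tissue_value
  vol[muscle] <- muscle_value
  origin <- c(xs[1], ys[1], zs[1])
  healthy <- vol
  injured <- vol[, rev(seq_len(ny)), ] # mirror across the mid-sagittal plane
  muscle_inj <- muscle[, rev(seq_len(ny)), ]
  removed <- array(FALSE, c(nx, ny, nz))
  if (missing_fraction > 0) {
    # top cap of the (mirrored) ellipsoid holding `missing_fraction` volume
    f <- missing_fraction
    cap_h <- uniroot(function(hh) hh^2 * (3 - hh) / 4 - f, c(0, 2),
                     tol = 1e-12)$root
    w_cut <- 1 - cap_h # unit-sphere height of the cut plane
    uz_rel <- (zs - mc[3]) / semi[3]
    cap <- array(FALSE, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      if (uz_rel[k] < w_cut) next
      cap[, , k] <- TRUE
    }
    removed <- muscle_inj & cap
    injured[removed] <- spec$air_value
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, {
      n1 <- array(rnorm(length(healthy), 0, spec$noise_sd), dim(healthy))
      n2 <- array(rnorm(length(healthy), 0, spec$noise_sd), dim(healthy))
      list(n1, n2)
    })
    healthy <- healthy + noise[[1]]
    injured <- injured + noise[[2]]
  }
  list(healthy = voxel_volume(healthy, h, origin),
       injured = voxel_volume(injured, h, origin),
       muscle_mask = binary_mask(muscle, h, origin, "muscle"),
       injured_muscle_mask = binary_mask(muscle_inj & !removed, h, origin,
                                         "muscle"),
       removed_mm3 = sum(removed) * h^3,
       mirror_plane = list(axis = 2L,
                           offset = (ys[1] + ys[ny]) / 2))
}
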