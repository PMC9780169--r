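# Contralateral workflow: design a scaffold as the difference between the
# mirrored healthy anatomy and the injured side, then scale to a volume
# fraction (syringe-capacity constraint).

#' Mirror a mask across an axis-aligned plane
#'
#' The plane \code{axis = offset} (mm) is snapped to the nearest half-voxel
#' so the reflection is an exact index permutation: volume is preserved
#' exactly and mirroring twice is the identity. Voxels reflected outside the
#' grid are dropped (keep the plane near the grid centre to avoid this).
#'
#' @param mask a [binary_mask()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param offset world position of the mirror plane along \code{axis} (mm);
#'   default: the grid centre.
#' @export
mirror_mask <- function(mask, axis = 2, offset = NULL) {
  stopifnot(axis %in% 1:3)
  d <- dim(mask$data)
  if (is.null(offset))
    offset <- mask$origin[axis] + (d[axis] - 1) / 2 * mask$spacing[axis]
  p <- (offset - mask$origin[axis]) / mask$spacing[axis] # 0-based plane index
  if (p < 0 || p > d[axis] - 1) stop("mirror plane lies outside the grid")
  k2 <- round(2 * p) # reflection: i' = k2 - i (0-based), exact on half-voxels
  idx0 <- seq_len(d[axis]) - 1L
  ref <- k2 - idx0
  out <- array(FALSE, d)
  ok <- ref >= 0 & ref <= d[axis] - 1
  src <- ref[ok] + 1L
  dst <- which(ok)
  if (axis == 1) out[dst, , ] <- mask$data[src, , ]
  if (axis == 2) out[, dst, ] <- mask$data[, src, ]
  if (axis == 3) out[, , dst] <- mask$data[, , src]
  mask_like(mask, out, mask$label)
}

#' Voxelwise boolean subtraction of two masks
#'
#' \code{a AND NOT b}; the result volume equals \code{vol(a) - vol(a AND b)}
#' exactly in voxel counts.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @export
boolean_subtract <- function(a, b) {
  stopifnot_same_grid(a, b)
  mask_like(a, a$data & !b$data, paste0(a$label, "-minus-", b$label))
}

#' Rigid alignment of one mask onto another by centroid and principal axes
#'
#' Automated surrogate for manual alignment of the mirrored healthy anatomy
#' onto the injured side: matches mask centroids and the principal axes of
#' the voxel point clouds (signs fixed to the nearest rotation). Returns the
#' transform; apply with [resample_mask()].
#'
#' @param src,dst [binary_mask()]s.
#' @return A [rigid_transform()] mapping src world coordinates onto dst.
#' @export
align_masks <- function(src, dst) {
  ps <- mask_points(src)
  pd <- mask_points(dst)
  cs <- colMeans(ps)
  cd <- colMeans(pd)
  es <- eigen(stats::cov(ps), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(pd), symmetric = TRUE)$vectors
  # fix axis signs so both frames are right-handed and nearly aligned
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  R <- ed %*% t(es)
  # prefer the sign combination closest to the identity (no flips)
  best <- R
  bestdev <- sum((R - diag(3))^2)
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))
    Rc <- ed %*% S %*% t(es)
    dev <- sum((Rc - diag(3))^2)
    if (dev < bestdev) { best <- Rc; bestdev <- dev }
  }
  rigid_transform(best, cd - as.vector(best %*% cs))
}

mask_points <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Resample a mask through a rigid transform (nearest neighbour)
#'
#' @param mask a [binary_mask()].
#' @param transform a [rigid_transform()] in world mm (src -> dst grid of
#'   \code{mask} itself).
#' @export
resample_mask <- function(mask, transform) {
  inv <- invert_transform(transform)
  d <- dim(mask$data)
  ax <- voxel_axes(mask)
  grid <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  src <- apply_transform(inv, grid)
  i <- round((src[, 1] - mask$origin[1]) / mask$spacing[1]) + 1
  j <- round((src[, 2] - mask$origin[2]) / mask$spacing[2]) + 1
  k <- round((src[, 3] - mask$origin[3]) / mask$spacing[3]) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  lin <- i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  out <- logical(prod(d))
  out[ok] <- mask$data[lin[ok]]
  mask_like(mask, out, mask$label)
}

#' Contralateral scaffold design: mirror, subtract, mesh, scale
#'
#' Mirrors the healthy-side compartment onto the injured side, subtracts the
#' injured anatomy, meshes the missing-volume solid, and scales it to the
#' requested volume fraction (isotropically about the centroid).
#'
#' @param healthy_mask compartment [binary_mask()] on the healthy side.
#' @param injured_mask same compartment on the injured side (same grid).
#' @param fraction volume-scaling fraction (e.g. 0.7).
#' @param axis,offset mirror plane, see [mirror_mask()].
#' @param align optionally refine the mirrored mask onto the injured side
#'   with [align_masks()] before subtracting.
#' @return List with \code{mirrored}, \code{difference} masks and the scaled
#'   \code{mesh}.
#' @export
contralateral_scaffold <- function(healthy_mask, injured_mask, fraction = 0.7,
                                   axis = 2, offset = NULL, align = FALSE) {
  mirrored <- mirror_mask(healthy_mask, axis, offset)
  if (align) {
    tf <- align_masks(mirrored, injured_mask)
    mirrored <- resample_mask(mirrored, tf)
  }
  diff <- boolean_subtract(mirrored, injured_mask)
  mesh <- mask_to_mesh(diff)
  mesh <- scale_mesh_to_volume_fraction(mesh, fraction)
  mesh$provenance <- sprintf("contralateral scaffold (%.0f%% volume)",
                             100 * fraction)
  list(mirrored = mirrored, difference = diff, mesh = mesh)
}
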