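# Patch-to-wound fit: interface void detection and volumes, contact-area
# percentage (bottom-of-scaffold area over top-of-wound area), and the
# void-volume comparison statistics.

#' Set of interface voids
#'
#' @param voids data.frame with columns id, volume_mm3, cx, cy, cz, voxels
#'   (possibly 0 rows).
#' @return An object of class \code{void_set} with \code{total_volume} and
#'   \code{count}.
#' @export
void_set <- function(voids = NULL) {
  if (is.null(voids) || nrow(voids) == 0)
    voids <- data.frame(id = integer(0), volume_mm3 = numeric(0),
                        cx = numeric(0), cy = numeric(0), cz = numeric(0),
                        voxels = integer(0))
  structure(list(voids = voids,
                 total_volume = sum(voids$volume_mm3),
                 count = nrow(voids)),
            class = "void_set")
}

#' @export
print.void_set <- function(x, ...) {
  cat(sprintf("<void_set> %d voids, total %.4f mm^3\n", x$count,
              x$total_volume))
  invisible(x)
}

#' Detect air voids at the wound-patch interface
#'
#' Air voxels (grey value below \code{air_threshold}) within the wound's
#' projected footprint are grouped into 26-connected components; a component
#' is a void when its one-voxel neighbourhood touches both the patch and the
#' wound tissue. Components smaller than \code{min_void} mm^3 are
#' disregarded (study floor: 0.001 mm^3).
#'
#' Ambient air (the component open to the scan boundary) is never a void.
#'
#' @param volume the implanted-scan [voxel_volume()].
#' @param wound_mask tissue [binary_mask()] (same grid).
#' @param patch_mask patch [binary_mask()] (same grid).
#' @param min_void minimum void volume retained (mm^3).
#' @param air_threshold grey value below which a voxel is air.
#' @return A [void_set()].
#' @export
detect_voids <- function(volume, wound_mask, patch_mask, min_void = 0.001,
                         air_threshold = -500) {
  stopifnot_same_grid(volume, wound_mask)
  stopifnot_same_grid(volume, patch_mask)
  d <- dim(volume$data)
  air <- volume$data < air_threshold
  fp <- apply(wound_mask$data | patch_mask$data, c(1, 2), any)
  air <- air & array(fp, d)
  air <- air & !wound_mask$data & !patch_mask$data
  if (!any(air)) return(void_set())
  lab <- cpp_label(as.vector(air), d, 26L)
  dim(lab) <- d
  nlab <- max(lab)
  # component ids whose 1-voxel neighbourhood touches patch and wound
  near_patch <- dilate1(patch_mask$data, d)
  near_wound <- dilate1(wound_mask$data, d)
  touches_p <- unique(lab[lab > 0 & near_patch])
  touches_w <- unique(lab[lab > 0 & near_wound])
  # ambient air: any component reaching the grid boundary
  edge_labs <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                        lab[, , c(1, d[3])]))
  cand <- setdiff(intersect(touches_p, touches_w), edge_labs)
  if (!length(cand)) return(void_set())
  vx <- voxel_mm3(volume)
  counts <- tabulate(lab, nlab)
  rows <- list()
  ax <- voxel_axes(volume)
  for (id in sort(cand)) {
    vol_mm3 <- counts[id] * vx
    if (vol_mm3 < min_void) next
    idx <- which(lab == id, arr.ind = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      id = length(rows) + 1L,
      volume_mm3 = vol_mm3,
      cx = mean(ax$x[idx[, 1]]),
      cy = mean(ax$y[idx[, 2]]),
      cz = mean(ax$z[idx[, 3]]),
      voxels = counts[id])
  }
  void_set(if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Split a mesh into upward- and downward-facing submeshes
#'
#' Faces are assigned by the sign of their normal component along
#' \code{up_axis}: positive to the top, negative to the bottom. Faces with a
#' zero component (vertical walls) belong to neither, so the two areas sum to
#' the area of all faces with a nonzero normal component.
#'
#' @param mesh a [surface_mesh()].
#' @param up_axis 1, 2 or 3 (default z).
#' @param tol normal-component magnitude treated as zero.
#' @return List with \code{top} and \code{bottom} (open) [surface_mesh()]es.
#' @export
split_top_bottom <- function(mesh, up_axis = 3, tol = 1e-9) {
  n <- face_normals(mesh)
  comp <- n[, up_axis]
  top <- surface_mesh(mesh$vertices,
                      mesh$faces[comp > tol, , drop = FALSE],
                      paste(mesh$provenance, "(top)"))
  bottom <- surface_mesh(mesh$vertices,
                         mesh$faces[comp < -tol, , drop = FALSE],
                         paste(mesh$provenance, "(bottom)"))
  list(top = top, bottom = bottom)
}

# keep faces whose centroid projects into [xlim] x [ylim]
crop_faces_xy <- function(mesh, xlim, ylim) {
  f <- mesh$faces
  cx <- (mesh$vertices[f[, 1], 1] + mesh$vertices[f[, 2], 1] +
         mesh$vertices[f[, 3], 1]) / 3
  cy <- (mesh$vertices[f[, 1], 2] + mesh$vertices[f[, 2], 2] +
         mesh$vertices[f[, 3], 2]) / 3
  keep <- cx >= xlim[1] & cx <= xlim[2] & cy >= ylim[1] & cy <= ylim[2]
  surface_mesh(mesh$vertices, f[keep, , drop = FALSE], mesh$provenance)
}

# keep faces whose centroid column falls inside a 2D footprint matrix
crop_faces_footprint <- function(mesh, fp, origin2, h2) {
  f <- mesh$faces
  cx <- (mesh$vertices[f[, 1], 1] + mesh$vertices[f[, 2], 1] +
         mesh$vertices[f[, 3], 1]) / 3
  cy <- (mesh$vertices[f[, 1], 2] + mesh$vertices[f[, 2], 2] +
         mesh$vertices[f[, 3], 2]) / 3
  i <- round((cx - origin2[1]) / h2[1]) + 1
  j <- round((cy - origin2[2]) / h2[2]) + 1
  ok <- i >= 1 & i <= nrow(fp) & j >= 1 & j <= ncol(fp)
  keep <- ok
  keep[ok] <- fp[cbind(i[ok], j[ok])]
  surface_mesh(mesh$vertices, f[keep, , drop = FALSE], mesh$provenance)
}

# 2D footprint of a 3D mask, optionally eroded by `erode` mm
mask_footprint2d <- function(mask, erode = 0) {
  fp <- apply(mask$data, c(1, 2), any)
  if (erode > 0) {
    dd <- cpp_edt(as.vector(!fp), c(dim(fp), 1L), c(mask$spacing[1:2], 1))
    fp <- matrix(dd > erode, nrow(fp), ncol(fp))
  }
  fp
}

#' Contact-area conformality of a patch on a wound
#'
#' Implements the surface-area ratio definition of conformality:
#' \code{contact_percent = area(bottom of scaffold) / area(top of wound) x
#' 100}. Both meshes are first cropped to a common footprint (the
#' intersection of their projected bounding boxes, shrunk by
#' \code{crop_margin}) so the ratio compares the same lateral extent, as in
#' the study's "cropped to the same exact outer bounds" step.
#'
#' @param patch_mesh the scaffold [surface_mesh()].
#' @param wound_mesh the wound-bed [surface_mesh()] (e.g. tissue surface).
#' @param up_axis up direction (3 = z).
#' @param crop_margin inward shrink of the common footprint (mm); defaults to
#'   0 (no shrink).
#' @param footprint optional [binary_mask()] whose 2-D projection (eroded by
#'   \code{crop_margin}) defines the common footprint region exactly; when
#'   given, it replaces the bounding-box crop. Use the patch mask itself for
#'   a patient-specific patch, mirroring the study's crop of both models to
#'   the wound's outer bounds.
#' @param void_set optionally attach a [void_set()] to the report.
#' @return A \code{conformality_report}: list with \code{sa_bottom},
#'   \code{sa_top} (mm^2), \code{contact_percent} and \code{void_set}.
#' @export
contact_percentage <- function(patch_mesh, wound_mesh, up_axis = 3,
                               crop_margin = 0, footprint = NULL,
                               void_set = NULL) {
  if (up_axis != 3) stop("only up_axis = 3 is supported")
  if (!is.null(footprint)) {
    fp <- mask_footprint2d(footprint, erode = crop_margin)
    patch_c <- crop_faces_footprint(patch_mesh, fp, footprint$origin[1:2],
                                    footprint$spacing[1:2])
    wound_c <- crop_faces_footprint(wound_mesh, fp, footprint$origin[1:2],
                                    footprint$spacing[1:2])
    xlim <- ylim <- NULL
  } else {
    bb_p <- apply(patch_mesh$vertices, 2, range)
    bb_w <- apply(wound_mesh$vertices, 2, range)
    xlim <- c(max(bb_p[1, 1], bb_w[1, 1]) + crop_margin,
              min(bb_p[2, 1], bb_w[2, 1]) - crop_margin)
    ylim <- c(max(bb_p[1, 2], bb_w[1, 2]) + crop_margin,
              min(bb_p[2, 2], bb_w[2, 2]) - crop_margin)
    if (xlim[1] >= xlim[2] || ylim[1] >= ylim[2])
      stop("patch and wound meshes share no footprint")
    patch_c <- crop_faces_xy(patch_mesh, xlim, ylim)
    wound_c <- crop_faces_xy(wound_mesh, xlim, ylim)
  }
  sa_bottom <- mesh_area(split_top_bottom(patch_c, up_axis)$bottom)
  sa_top <- mesh_area(split_top_bottom(wound_c, up_axis)$top)
  if (sa_bottom == 0 || sa_top == 0)
    stop("empty top/bottom submesh after cropping")
  rep <- list(sa_bottom = sa_bottom, sa_top = sa_top,
              contact_percent = sa_bottom / sa_top * 100,
              footprint = list(xlim = xlim, ylim = ylim),
              void_set = void_set)
  class(rep) <- "conformality_report"
  rep
}

#' @export
print.conformality_report <- function(x, ...) {
  cat(sprintf("<conformality_report> contact %.2f%% (bottom %.1f mm^2 / top %.1f mm^2)\n",
              x$contact_percent, x$sa_bottom, x$sa_top))
  if (!is.null(x$void_set)) print(x$void_set)
  invisible(x)
}

#' Compare two sets of void volumes
#'
#' Mirrors the study's statistical sequence on log10-transformed volumes:
#' Shapiro-Wilk normality per group, F-test for equal variances, then a
#' two-tailed unpaired t-test (Student, pooled variance). The normality and
#' variance checks are reported, not used as gates; assumption violations are
#' flagged. The fold change of total void volumes (b over a) is included.
#'
#' @param a,b [void_set()]s with at least 3 voids each.
#' @param alpha significance level for the assumption checks.
#' @return List of class \code{void_comparison} with the log-scale test
#'   (statistic, df, p.value), assumption checks and \code{fold_change_total}.
#' @export
compare_void_volumes <- function(a, b, alpha = 0.05) {
  va <- a$voids$volume_mm3
  vb <- b$voids$volume_mm3
  if (length(va) < 3 || length(vb) < 3)
    stop("need at least 3 voids in each set")
  la <- log10(va)
  lb <- log10(vb)
  sw_a <- shapiro.test(la)
  sw_b <- shapiro.test(lb)
  ftest <- var.test(la, lb)
  tt <- t.test(la, lb, var.equal = TRUE)
  structure(list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    mean_log10 = c(a = mean(la), b = mean(lb)),
    shapiro_p = c(a = sw_a$p.value, b = sw_b$p.value),
    f_test_p = ftest$p.value,
    normality_ok = sw_a$p.value > alpha && sw_b$p.value > alpha,
    equal_variance_ok = ftest$p.value > alpha,
    fold_change_total = b$total_volume / a$total_volume,
    alpha = alpha), class = "void_comparison")
}

#' @export
print.void_comparison <- function(x, ...) {
  cat(sprintf("<void_comparison> t = %.3f, df = %.1f, p = %.4g (log10 volumes)\n",
              x$t, x$df, x$p.value))
  cat(sprintf("  total-volume fold change (b/a): %.3g\n", x$fold_change_total))
  if (!x$normality_ok) cat("  note: log-normality assumption questionable (Shapiro-Wilk)\n")
  if (!x$equal_variance_ok) cat("  note: equal-variance assumption questionable (F-test)\n")
  invisible(x)
}
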