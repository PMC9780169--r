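# Uniform-thickness patch design: a shell grown from the wound-facing
# interface of the inverted (cavity) volume by Euclidean distance transform,
# trimmed to the wound footprint, median-smoothed, and meshed.

#' Shell construction parameters
#'
#' Defaults follow the study workflow: a 4 mm uniform-thickness shell,
#' median-smoothed with a 3-voxel window (window = diameter), trimmed to the
#' wound footprint.
#'
#' @param thickness shell wall thickness in mm (> voxel spacing).
#' @param smooth_window odd median-filter window in voxels (1 = no smoothing).
#' @param footprint_trim trim the shell to the wound's projected footprint?
#' @param margin footprint dilation margin in mm when trimming.
#' @export
shell_params <- function(thickness = 4, smooth_window = 3,
                         footprint_trim = TRUE, margin = 0) {
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("smooth_window must be an odd integer >= 1")
  if (thickness <= 0) stop("thickness must be positive")
  structure(list(thickness = thickness, smooth_window = smooth_window,
                 footprint_trim = footprint_trim, margin = margin),
            class = "shell_params")
}

# wound-facing interface: cavity voxels face-adjacent to tissue
interface_layer <- function(inverted, wound_tissue) {
  dilate1(wound_tissue$data, dim(wound_tissue$data)) & inverted$data
}

#' Grow a uniform-thickness shell from the wound-facing interface
#'
#' The shell consists of the cavity voxels whose Euclidean distance to the
#' wound-facing interface (cavity voxels face-adjacent to wound tissue) is
#' strictly below \code{params$thickness}; measured centre-to-centre, this
#' reproduces the "hollow from the external surface" operation and gives a
#' wall uniform to within one voxel.
#'
#' @param inverted the wound-cavity [binary_mask()] (from [invert_wound()]).
#' @param wound_tissue the tissue [binary_mask()] on the same grid.
#' @param params a [shell_params()].
#' @return A [binary_mask()] labelled "shell".
#' @export
make_shell <- function(inverted, wound_tissue, params = shell_params()) {
  stopifnot_same_grid(inverted, wound_tissue)
  if (params$thickness <= max(inverted$spacing))
    stop("shell thickness must exceed the voxel spacing")
  iface <- interface_layer(inverted, wound_tissue)
  if (!any(iface))
    stop("inverted volume and wound tissue share no voxel interface")
  d <- cpp_edt(as.vector(iface), dim(iface), inverted$spacing)
  dim(d) <- dim(iface)
  mask_like(inverted, inverted$data & (d < params$thickness), "shell")
}

#' Trim a shell to the wound's projected footprint
#'
#' Restricts the shell to grid columns (along the up axis) whose projection
#' falls within the wound footprint dilated by \code{margin} mm.
#'
#' @param shell the shell [binary_mask()].
#' @param wound_mask the wound-cavity [binary_mask()] defining the footprint.
#' @param margin footprint dilation in mm (0 = exact footprint).
#' @param up_axis axis the patch faces (3 = z).
#' @export
trim_footprint <- function(shell, wound_mask, margin = 0, up_axis = 3) {
  stopifnot_same_grid(shell, wound_mask)
  if (up_axis != 3) stop("only up_axis = 3 is supported")
  fp <- apply(wound_mask$data, c(1, 2), any)
  if (margin > 0) {
    d2 <- cpp_edt(as.vector(fp), c(dim(fp), 1L),
                  c(shell$spacing[1:2], 1))
    fp <- matrix(d2 <= margin, nrow(fp), ncol(fp))
  }
  keep <- array(fp, dim(shell$data)) # recycled along z (x,y fastest)
  mask_like(shell, shell$data & keep, shell$label)
}

#' Median-smooth a binary mask
#'
#' Voxelwise median (= majority vote) over a \code{window}^3 neighbourhood,
#' truncated at the grid borders. Idempotent on already-smooth convex masks.
#'
#' @param mask a [binary_mask()].
#' @param window odd window size in voxels.
#' @export
smooth_mask <- function(mask, window = 3) {
  if (window %% 2 != 1 || window < 1)
    stop("median window must be an odd integer >= 1")
  if (window == 1) return(mask)
  out <- cpp_binary_median(as.vector(mask$data), dim(mask$data),
                           as.integer(window))
  mask_like(mask, out, mask$label)
}

#' Extract a watertight surface mesh from a binary mask
#'
#' Isosurface of the 0/1 field at \code{iso}, computed by marching tetrahedra
#' (six-tetrahedron cube decomposition) in world millimetres. The field is
#' padded with one background voxel so masks touching the grid boundary still
#' produce closed surfaces. Outward normals, signed volume > 0.
#'
#' @param mask a non-empty [binary_mask()].
#' @param iso iso level in (0, 1); 0.5 places the surface midway between
#'   voxel centres.
#' @return A watertight [surface_mesh()].
#' @export
mask_to_mesh <- function(mask, iso = 0.5) {
  if (!any(mask$data)) stop("cannot mesh an empty mask")
  d <- dim(mask$data)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  res <- cpp_march_tets(as.vector(field), dim(field), mask$spacing,
                        mask$origin - mask$spacing, iso)
  surface_mesh(res$vertices, res$faces,
               provenance = sprintf("isosurface of '%s' mask", mask$label))
}

#' Estimate the wall thickness of a shell mask
#'
#' Distance-transform measure: twice the interior distance to the shell
#' boundary on the medial (ridge) voxels, corrected for the half-voxel
#' centre-to-boundary offset. For a uniform shell this estimates the physical
#' wall thickness to about one voxel.
#'
#' @param shell the shell [binary_mask()].
#' @return List with \code{mean}, \code{max}, \code{median} thickness (mm)
#'   and the per-ridge-voxel sample.
#' @export
measure_shell_thickness <- function(shell) {
  if (!any(shell$data)) stop("empty shell")
  h <- shell$spacing[1]
  d <- cpp_edt(as.vector(!shell$data), dim(shell$data), shell$spacing)
  dim(d) <- dim(shell$data)
  # ridge voxels: interior distance >= all 26 neighbours
  nbmax <- array(-Inf, dim(d))
  dims <- dim(d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- seq_len(dims[1]) + di
    src_j <- seq_len(dims[2]) + dj
    src_k <- seq_len(dims[3]) + dk
    ok_i <- src_i >= 1 & src_i <= dims[1]
    ok_j <- src_j >= 1 & src_j <= dims[2]
    ok_k <- src_k >= 1 & src_k <= dims[3]
    nbmax[ok_i, ok_j, ok_k] <- pmax(nbmax[ok_i, ok_j, ok_k],
                                    d[src_i[ok_i], src_j[ok_j], src_k[ok_k]])
  }
  ridge <- shell$data & d >= nbmax - 1e-9
  est <- 2 * d[ridge] - h
  list(mean = mean(est), max = max(est), median = median(est), samples = est)
}

#' Full patch design pipeline for one wound volume
#'
#' Segment (threshold + largest component), invert within the ROI, grow the
#' uniform-thickness shell, trim to the wound footprint, median-smooth, and
#' mesh. Smoothing never detaches the patch from the wound bed: the
#' wound-facing interface layer is re-added and the smoothed shell is kept
#' inside the cavity, so conformality survives the filter.
#'
#' @param vol the CT-like [voxel_volume()].
#' @param roi a [roi_box()] bounding the cavity (top face at the skin plane).
#' @param params a [shell_params()].
#' @param mode,value thresholding arguments, see [threshold_volume()].
#' @return List with all intermediate masks and the final \code{mesh}.
#' @export
design_patch <- function(vol, roi, params = shell_params(),
                         mode = c("otsu", "fixed"), value = NULL) {
  seg <- segment_wound(vol, roi, mode, value)
  shell <- make_shell(seg$cavity, seg$tissue, params)
  if (params$footprint_trim)
    shell <- trim_footprint(shell, seg$cavity, params$margin)
  if (params$smooth_window > 1) {
    sm <- smooth_mask(shell, params$smooth_window)
    iface <- dilate1(seg$tissue$data, dim(shell$data)) & shell$data
    shell <- mask_like(shell, (sm$data & seg$cavity$data) | iface, "shell")
  }
  mesh <- mask_to_mesh(shell)
  mesh$provenance <- sprintf("patch (thickness %.3g mm)", params$thickness)
  list(segmentation = seg, shell = shell, mesh = mesh, params = params)
}
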