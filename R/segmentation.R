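# Wound extraction from CT-like volumes: automatic (Otsu) or fixed-value
# thresholding, largest-component cleanup, and in-ROI inversion to obtain the
# air volume occupying the wound cavity (the wound-conformal solid).

# Otsu's threshold on a 256-bin histogram; returns the grey value maximizing
# the between-class variance.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot Otsu-threshold a constant volume")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                             all.inside = TRUE), nbins))
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[nbins]
  mt <- m[nbins]
  w0 <- w[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-nbins] / w0
  mu1 <- (mt - m[-nbins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  # the maximum is a plateau for well-separated modes: take its middle so the
  # threshold sits between the classes, not against one of them
  ks <- which(bcv >= max(bcv) * (1 - 1e-12))
  k <- ks[ceiling(length(ks) / 2)]
  br[k + 1L] # boundary between classes
}

#' Threshold a volume into an air-side binary mask
#'
#' Emulates the automatic-thresholding wound extraction: voxels strictly
#' below the threshold (the air side) become TRUE. The threshold used is
#' stored in the returned mask as \code{$threshold}.
#'
#' @param vol a [voxel_volume()].
#' @param mode "otsu" (default) or "fixed".
#' @param value threshold grey value when \code{mode = "fixed"}.
#' @return A [binary_mask()] labelled "wound" with a \code{threshold} field.
#' @export
threshold_volume <- function(vol, mode = c("otsu", "fixed"), value = NULL) {
  mode <- match.arg(mode)
  thr <- switch(mode,
                otsu = otsu_threshold(as.vector(vol$data)),
                fixed = {
                  if (is.null(value)) stop("fixed mode needs `value`")
                  as.numeric(value)
                })
  m <- mask_like(vol, vol$data < thr, "wound")
  m$threshold <- thr
  m
}

#' Keep only the largest connected component of a mask
#'
#' Automated surrogate for manual cleanup of segmentation speckle. Ties are
#' broken by the lowest component label, i.e. the component encountered first
#' in linear scan order.
#'
#' @param mask a non-empty [binary_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @export
largest_component <- function(mask, connectivity = 26) {
  if (!any(mask$data)) stop("mask is empty")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  lab <- cpp_label(as.vector(mask$data), dim(mask$data), connectivity)
  sizes <- tabulate(lab)
  keep <- which.max(sizes) # ties -> lowest label (scan order)
  out <- mask_like(mask, lab == keep, mask$label)
  out$threshold <- mask$threshold
  out
}

#' Axis-aligned region of interest in world mm
#'
#' @param xlim,ylim,zlim length-2 numeric ranges (mm).
#' @export
roi_box <- function(xlim, ylim, zlim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2)
  structure(list(xlim = sort(as.numeric(xlim)), ylim = sort(as.numeric(ylim)),
                 zlim = sort(as.numeric(zlim))), class = "roi_box")
}

roi_mask_array <- function(vol, roi) {
  ax <- voxel_axes(vol)
  inx <- ax$x >= roi$xlim[1] & ax$x <= roi$xlim[2]
  iny <- ax$y >= roi$ylim[1] & ax$y <= roi$ylim[2]
  inz <- ax$z >= roi$zlim[1] & ax$z <= roi$zlim[2]
  arr <- array(FALSE, dim(vol$data))
  if (any(inx) && any(iny) && any(inz)) arr[inx, iny, inz] <- TRUE
  arr
}

#' Invert a segmentation within a region of interest
#'
#' Returns the logical complement of \code{mask} restricted to \code{roi}:
#' applied to the tissue segmentation with an ROI bounded above by the skin
#' surface, this is the air volume occupying the wound cavity, the solid that
#' is directly conformal to the wound-bed surface.
#'
#' @param mask a [binary_mask()] (typically the tissue side of the wound
#'   threshold).
#' @param roi a [roi_box()]; must intersect the mask grid.
#' @return A [binary_mask()] labelled "inverted". Warns if empty.
#' @export
invert_wound <- function(mask, roi) {
  stopifnot(inherits(roi, "roi_box"))
  inroi <- roi_mask_array(mask, roi)
  if (!any(inroi)) stop("roi does not intersect the mask grid")
  out <- inroi & !mask$data
  if (!any(out)) warning("inverted wound volume is empty within the roi")
  mask_like(mask, out, "inverted")
}

#' One-call wound segmentation: threshold, clean, invert
#'
#' Thresholds the volume (air below), keeps the largest air-side component of
#' the complement tissue, and inverts the tissue within the ROI to yield the
#' wound-cavity solid.
#'
#' @param vol the CT-like [voxel_volume()].
#' @param roi a [roi_box()] bounding the wound cavity, its top face at the
#'   skin/surgical plane.
#' @param mode,value passed to [threshold_volume()].
#' @return List with \code{air}, \code{tissue}, \code{cavity} masks.
#' @export
segment_wound <- function(vol, roi, mode = c("otsu", "fixed"), value = NULL) {
  air <- threshold_volume(vol, mode, value)
  tissue <- mask_like(vol, !air$data, "tissue")
  tissue <- largest_component(tissue, 26)
  cavity <- invert_wound(tissue, roi)
  cavity <- largest_component(cavity, 26)
  list(air = air, tissue = tissue, cavity = cavity, threshold = air$threshold)
}
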