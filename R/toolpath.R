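# Minimal scaffold slicer: planar slicing, perimeter insets, rectilinear
# infill with regional density/angle modifiers, and volumetric G-code with
# bioink-volume / print-time estimates.
#
# Perimeters are computed on a signed-distance raster of the slice polygon
# (marching-squares contour at the inset level); infill lines are clipped
# exactly against polygon loops (even-odd rule). The infill line family runs
# at offsets (m + 1/2) * spacing from the world origin along the line normal,
# so line positions are deterministic and never degenerate onto the boundary
# of grid-aligned parts.

#' Print settings
#'
#' Defaults are the study's print parameters: 0.16 mm layer height,
#' 20 mm/s speed, 40 percent rectilinear infill with connected lines and 50
#' percent infill overlap, 2 perimeters, 2 top and bottom layers, 100
#' percent flow, 0.4 mm extrusion width (23-gauge needle, ~400 um filament).
#' \code{infill_angle = NULL} alternates 0/90 degrees between layers
#' (rectilinear); a fixed number prints every layer at that angle
#' (unipennate mode).
#'
#' @param layer_height layer height (mm).
#' @param speed print speed (mm/s).
#' @param perimeters number of perimeter loops.
#' @param top_bottom_layers solid layers at the bottom and at the top.
#' @param infill_density fill fraction in (0, 1].
#' @param infill_angle NULL (alternate 0/90) or a fixed angle in degrees.
#' @param extrusion_width extruded line width (mm).
#' @param flow extrusion multiplier.
#' @param infill_overlap fraction of the width that infill lines extend into
#'   the innermost perimeter.
#' @param connect_infill join consecutive infill lines into zigzags?
#' @param raster_resolution raster pixel size for perimeter offsetting (mm);
#'   default \code{extrusion_width / 4}.
#' @export
print_settings <- function(layer_height = 0.16, speed = 20, perimeters = 2,
                           top_bottom_layers = 2, infill_density = 0.40,
                           infill_angle = NULL, extrusion_width = 0.4,
                           flow = 1.0, infill_overlap = 0.5,
                           connect_infill = TRUE, raster_resolution = NULL) {
  if (infill_density <= 0 || infill_density > 1)
    stop("infill_density must be in (0, 1]")
  if (layer_height >= extrusion_width)
    stop("layer_height must be below the extrusion width")
  if (perimeters < 0 || top_bottom_layers < 0) stop("counts must be >= 0")
  if (is.null(raster_resolution)) raster_resolution <- extrusion_width / 4
  structure(list(layer_height = layer_height, speed = speed,
                 perimeters = as.integer(perimeters),
                 top_bottom_layers = as.integer(top_bottom_layers),
                 infill_density = infill_density,
                 infill_angle = infill_angle,
                 extrusion_width = extrusion_width, flow = flow,
                 infill_overlap = infill_overlap,
                 connect_infill = connect_infill,
                 raster_resolution = raster_resolution),
            class = "print_settings")
}

#' Regional infill modifier
#'
#' Overrides infill density and/or angle inside an axis-aligned region,
#' given either as a fractional span of the part's extent along one axis
#' (e.g. thirds along x) or as an explicit world-mm box.
#'
#' @param density infill density for the region.
#' @param angle fixed infill angle (degrees) for the region; NULL keeps the
#'   global angle rule.
#' @param span length-2 fractions in [0, 1] of the part extent along
#'   \code{axis}.
#' @param axis 1 (x), 2 (y) or 3 (z) for \code{span}.
#' @param box list with any of xlim/ylim/zlim (mm) for an explicit region.
#' @export
region_modifier <- function(density, angle = NULL, span = NULL, axis = 1,
                            box = NULL) {
  if (is.null(span) && is.null(box))
    stop("give either `span` (+ axis) or `box`")
  if (!is.null(span)) {
    if (length(span) != 2 || any(span < 0) || any(span > 1))
      stop("span must be two fractions in [0, 1]")
    span <- sort(span)
  }
  structure(list(density = density, angle = angle, span = span,
                 axis = as.integer(axis), box = box),
            class = "region_modifier")
}

# world-mm box (xlim, ylim, zlim; may contain +-Inf) for a modifier
modifier_box <- function(mod, bbox) {
  if (!is.null(mod$box)) {
    b <- mod$box
    list(xlim = if (is.null(b$xlim)) c(-Inf, Inf) else b$xlim,
         ylim = if (is.null(b$ylim)) c(-Inf, Inf) else b$ylim,
         zlim = if (is.null(b$zlim)) c(-Inf, Inf) else b$zlim)
  } else {
    lims <- list(xlim = c(-Inf, Inf), ylim = c(-Inf, Inf),
                 zlim = c(-Inf, Inf))
    lo <- bbox[1, mod$axis]
    hi <- bbox[2, mod$axis]
    lims[[mod$axis]] <- lo + mod$span * (hi - lo)
    lims
  }
}

boxes_overlap <- function(a, b) {
  all(vapply(c("xlim", "ylim", "zlim"), function(k)
    max(a[[k]][1], b[[k]][1]) < min(a[[k]][2], b[[k]][2]) - 1e-12, logical(1)))
}

check_modifiers <- function(mods, bbox) {
  if (length(mods) < 2) return(invisible(TRUE))
  boxes <- lapply(mods, modifier_box, bbox = bbox)
  for (i in seq_along(boxes)) for (j in seq_len(i - 1)) {
    if (boxes_overlap(boxes[[i]], boxes[[j]]))
      stop("region modifiers ", j, " and ", i, " overlap")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------- mesh slicing

#' Slice a watertight mesh into per-layer polygons
#'
#' Cross-sections at mid-layer heights z_min + (k + 1/2) * layer_height,
#' k = 0, 1, ...; the half-layer offset keeps slicing planes off the
#' vertices of grid-aligned meshes. Loops are closed (first point implied
#' after the last); holes are additional loops (even-odd rule).
#'
#' @param mesh a watertight [surface_mesh()].
#' @param layer_height slice spacing (mm).
#' @return List of class \code{slice_set} with \code{z} and \code{layers}
#'   (each a list of n x 2 loop matrices).
#' @export
slice_mesh <- function(mesh, layer_height) {
  if (!is_watertight(mesh)) stop("mesh must be watertight for slicing")
  zr <- range(mesh$vertices[, 3])
  n <- floor((zr[2] - zr[1]) / layer_height)
  if (n < 1) stop("mesh thinner than one layer")
  zs <- zr[1] + (seq_len(n) - 0.5) * layer_height
  # keep slicing planes off mesh vertices (degenerate crossings)
  vz <- sort(unique(mesh$vertices[, 3]))
  eps <- 1e-6 * layer_height
  for (r in seq_along(zs)) {
    repeat {
      i <- findInterval(zs[r], vz)
      near <- min(abs(vz[c(max(1, i), min(length(vz), i + 1))] - zs[r]))
      if (near > eps) break
      zs[r] <- zs[r] + 1e-3 * layer_height
    }
  }
  layers <- cpp_slice_mesh(mesh$vertices, mesh$faces, zs)
  structure(list(z = zs, layers = layers, layer_height = layer_height),
            class = "slice_set")
}

#' Area enclosed by a set of even-odd loops (mm^2)
#' @param loops list of n x 2 closed loop matrices.
#' @export
polygon_area <- function(loops) {
  if (!length(loops)) return(0)
  areas <- vapply(loops, function(L) {
    n <- nrow(L)
    j <- c(2:n, 1)
    abs(sum(L[, 1] * L[j, 2] - L[j, 1] * L[, 2]) / 2)
  }, numeric(1))
  if (length(loops) == 1) return(areas)
  # even-odd: a loop nested inside an odd number of others is a hole
  signs <- vapply(seq_along(loops), function(i) {
    p <- loops[[i]][1, ]
    inside <- sum(vapply(seq_along(loops), function(j) {
      j != i && point_in_loop(p, loops[[j]])
    }, logical(1)))
    if (inside %% 2 == 1) -1 else 1
  }, numeric(1))
  sum(signs * areas)
}

point_in_loop <- function(p, L) {
  n <- nrow(L)
  j <- c(2:n, 1)
  y1 <- L[, 2]; y2 <- L[j, 2]
  cross <- (y1 > p[2]) != (y2 > p[2])
  if (!any(cross)) return(FALSE)
  xint <- L[cross, 1] + (p[2] - y1[cross]) / (y2[cross] - y1[cross]) *
    (L[j, 1][cross] - L[cross, 1])
  sum(xint > p[1]) %% 2 == 1
}

# -------------------------------------------------- signed distance & insets

# signed distance raster of a layer (positive inside), anchored so pixel
# centres sit at half-pixel offsets from the loop bbox
layer_distance_field <- function(loops, h_r, pad) {
  pts <- do.call(rbind, loops)
  x0 <- min(pts[, 1]) - pad
  y0 <- min(pts[, 2]) - pad
  nx <- ceiling((max(pts[, 1]) + pad - x0) / h_r) + 1L
  ny <- ceiling((max(pts[, 2]) + pad - y0) / h_r) + 1L
  origin2 <- c(x0 + h_r / 2, y0 + h_r / 2)
  inside <- cpp_rasterize_loops(loops, c(nx, ny), origin2, h_r)
  d_out <- cpp_edt(!inside, c(nx, ny, 1L), c(h_r, h_r, 1))
  d_in <- cpp_edt(inside, c(nx, ny, 1L), c(h_r, h_r, 1))
  sd <- ifelse(inside, d_out - h_r / 2, -(d_in - h_r / 2))
  list(field = matrix(sd, nx, ny), origin = origin2, h = h_r)
}

#' Perimeter loops of a slice polygon
#'
#' The i-th perimeter (i = 0 .. count-1) is the polygon inset by
#' (i + 1/2) * width: the contour of the signed-distance field at that
#' level. Degenerate (vanished) insets are dropped.
#'
#' @param loops slice polygon as a list of closed loops.
#' @param count number of perimeters.
#' @param width extrusion width (mm).
#' @param raster_resolution distance-field pixel size (mm).
#' @return List of perimeter path lists, outermost first; each element is a
#'   list of closed loops at that inset.
#' @export
make_perimeters <- function(loops, count, width, raster_resolution = width / 4) {
  if (count < 1 || !length(loops)) return(list())
  sdf <- layer_distance_field(loops, raster_resolution,
                              pad = 2 * raster_resolution)
  out <- list()
  for (i in seq_len(count) - 1L) {
    lv <- (i + 0.5) * width
    cont <- cpp_marching_squares(sdf$field, lv, sdf$origin, sdf$h)
    if (!length(cont)) break
    out[[length(out) + 1]] <- cont
  }
  out
}

# -------------------------------------------------------------- infill lines

# clip the infinite line p0 + t*dir against even-odd loops; returns a matrix
# of inside [t_start, t_end] intervals
clip_line_loops <- function(p0, dir, loops) {
  nrm <- c(-dir[2], dir[1])
  c0 <- sum(p0 * nrm)
  ts <- numeric(0)
  for (L in loops) {
    n <- nrow(L)
    j <- c(2:n, 1)
    pa <- L %*% nrm
    pb <- pa[j]
    den <- pb - pa
    u <- (c0 - pa) / den
    hit <- is.finite(u) & u >= 0 & u < 1
    if (!any(hit)) next
    ex <- L[hit, 1] + u[hit] * (L[j, 1][hit] - L[hit, 1])
    ey <- L[hit, 2] + u[hit] * (L[j, 2][hit] - L[hit, 2])
    ts <- c(ts, (ex - p0[1]) * dir[1] + (ey - p0[2]) * dir[2])
  }
  if (length(ts) < 2) return(matrix(numeric(0), ncol = 2))
  ts <- sort(ts)
  if (length(ts) %% 2 == 1) ts <- ts[-length(ts)]
  matrix(ts, ncol = 2, byrow = TRUE)
}

# intersect [a,b] intervals (rows) with a single [lo,hi]; or subtract boxes
intersect_intervals <- function(iv, lo, hi) {
  if (!nrow(iv)) return(iv)
  s <- pmax(iv[, 1], lo)
  e <- pmin(iv[, 2], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

subtract_interval <- function(iv, lo, hi) {
  if (!nrow(iv)) return(iv)
  out <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(iv))) {
    a <- iv[r, 1]; b <- iv[r, 2]
    if (hi <= a || lo >= b) { out <- rbind(out, c(a, b)); next }
    if (lo > a) out <- rbind(out, c(a, min(lo, b)))
    if (hi < b) out <- rbind(out, c(max(hi, a), b))
  }
  out
}

# t-interval of the line inside an axis-aligned box (xy only; z handled by
# layer selection)
line_box_interval <- function(p0, dir, box) {
  lo <- -Inf
  hi <- Inf
  for (ax in 1:2) {
    lim <- if (ax == 1) box$xlim else box$ylim
    if (abs(dir[ax]) < 1e-12) {
      if (p0[ax] < lim[1] || p0[ax] > lim[2]) return(NULL)
    } else {
      t1 <- (lim[1] - p0[ax]) / dir[ax]
      t2 <- (lim[2] - p0[ax]) / dir[ax]
      lo <- max(lo, min(t1, t2))
      hi <- min(hi, max(t1, t2))
    }
  }
  if (lo >= hi) NULL else c(lo, hi)
}

#' Rectilinear infill for one slice polygon
#'
#' Parallel lines at \code{angle} with centre-to-centre spacing
#' \code{width / density}, clipped (even-odd) to \code{clip_loops}. The line
#' family lies at offsets (m + 1/2) * spacing from the world origin, so
#' output is deterministic and independent of the slice. If \code{connect},
#' consecutive lines whose endpoints are close are chained into zigzag
#' polylines (the connections extrude).
#'
#' @param clip_loops list of closed loops bounding the infill region (the
#'   innermost perimeter inset minus the overlap band, or the slice polygon
#'   itself when there are no perimeters).
#' @param density fill fraction in (0, 1].
#' @param angle line angle in degrees (0 = +x).
#' @param width extrusion width (mm).
#' @param connect chain consecutive lines?
#' @param keep_box,drop_boxes optional world boxes (from region modifiers)
#'   to intersect with / subtract from the lines.
#' @param min_len drop clipped segments shorter than this (mm).
#' @return List of polylines (n x 2 matrices).
#' @export
rectilinear_infill <- function(clip_loops, density, angle, width,
                               connect = TRUE, keep_box = NULL,
                               drop_boxes = list(), min_len = NULL) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (!length(clip_loops)) return(list())
  if (is.null(min_len)) min_len <- width / 2
  s <- width / density
  th <- angle * pi / 180
  dir <- c(cos(th), sin(th))
  nrm <- c(-dir[2], dir[1])
  pts <- do.call(rbind, clip_loops)
  pr <- pts %*% nrm
  ms <- seq(floor(min(pr) / s - 0.5), ceiling(max(pr) / s - 0.5))
  segs <- list()
  for (m in ms) {
    off <- (m + 0.5) * s
    p0 <- off * nrm
    iv <- clip_line_loops(p0, dir, clip_loops)
    if (!is.null(keep_box)) {
      kb <- line_box_interval(p0, dir, keep_box)
      if (is.null(kb)) next
      iv <- intersect_intervals(iv, kb[1], kb[2])
    }
    for (db in drop_boxes) {
      bi <- line_box_interval(p0, dir, db)
      if (!is.null(bi)) iv <- subtract_interval(iv, bi[1], bi[2])
    }
    if (!nrow(iv)) next
    iv <- iv[iv[, 2] - iv[, 1] >= min_len, , drop = FALSE]
    if (!nrow(iv)) next
    # serpentine: alternate direction line-to-line
    ord <- seq_len(nrow(iv))
    flip <- (m %% 2) != 0
    if (flip) ord <- rev(ord)
    for (r in ord) {
      t0 <- if (flip) iv[r, 2] else iv[r, 1]
      t1 <- if (flip) iv[r, 1] else iv[r, 2]
      segs[[length(segs) + 1]] <- rbind(p0 + t0 * dir, p0 + t1 * dir)
    }
  }
  if (!connect || length(segs) < 2) return(segs)
  joined <- list()
  cur <- segs[[1]]
  jmax <- 2.5 * s
  for (i in 2:length(segs)) {
    nxt <- segs[[i]]
    gap <- sqrt(sum((cur[nrow(cur), ] - nxt[1, ])^2))
    if (gap <= jmax) cur <- rbind(cur, nxt) else {
      joined[[length(joined) + 1]] <- cur
      cur <- nxt
    }
  }
  joined[[length(joined) + 1]] <- cur
  joined
}

# ----------------------------------------------------------------- toolpath

#' Build the layered toolpath for a mesh
#'
#' Slices the mesh, generates perimeters, solid top/bottom layers (density
#' 1) and rectilinear infill with optional regional modifiers. Infill angle
#' alternates 0/90 between layers unless fixed in the settings or a region.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param settings a [print_settings()].
#' @param modifiers list of [region_modifier()]s (non-overlapping).
#' @return An object of class \code{toolpath}: list of layers, each with
#'   \code{z} and \code{paths} (list of \code{points}/\code{role}).
#' @export
make_toolpath <- function(mesh, settings = print_settings(),
                          modifiers = list()) {
  bbox <- apply(mesh$vertices, 2, range)
  check_modifiers(modifiers, bbox)
  sl <- slice_mesh(mesh, settings$layer_height)
  w <- settings$extrusion_width
  nlay <- length(sl$z)
  layers <- vector("list", nlay)
  for (k in seq_len(nlay)) {
    loops <- sl$layers[[k]]
    paths <- list()
    if (length(loops)) {
      peri <- make_perimeters(loops, settings$perimeters, w,
                              settings$raster_resolution)
      for (p in peri) for (L in p)
        paths[[length(paths) + 1]] <- list(points = rbind(L, L[1, , drop = FALSE]),
                                           role = "perimeter")
      # infill clip region: innermost perimeter inset minus the overlap band
      inset <- (settings$perimeters - settings$infill_overlap) * w
      if (inset > 1e-9) {
        sdf <- layer_distance_field(loops, settings$raster_resolution,
                                    pad = 2 * settings$raster_resolution)
        clip <- cpp_marching_squares(sdf$field, inset, sdf$origin, sdf$h)
      } else clip <- loops
      solid <- k <= settings$top_bottom_layers ||
        k > nlay - settings$top_bottom_layers
      base_angle <- if (!is.null(settings$infill_angle))
        settings$infill_angle else if (k %% 2 == 1) 0 else 90
      if (length(clip)) {
        if (solid) {
          fill <- rectilinear_infill(clip, 1.0, base_angle, w,
                                     settings$connect_infill)
          for (L in fill)
            paths[[length(paths) + 1]] <- list(points = L, role = "solid")
        } else {
          boxes <- lapply(modifiers, modifier_box, bbox = bbox)
          z <- sl$z[k]
          active <- vapply(boxes, function(b)
            z >= b$zlim[1] && z <= b$zlim[2], logical(1))
          for (mi in which(active)) {
            mod <- modifiers[[mi]]
            ang <- if (is.null(mod$angle)) base_angle else mod$angle
            fill <- rectilinear_infill(clip, mod$density, ang, w,
                                       settings$connect_infill,
                                       keep_box = boxes[[mi]])
            for (L in fill)
              paths[[length(paths) + 1]] <- list(points = L, role = "infill")
          }
          fill <- rectilinear_infill(clip, settings$infill_density,
                                     base_angle, w, settings$connect_infill,
                                     drop_boxes = boxes[active])
          for (L in fill)
            paths[[length(paths) + 1]] <- list(points = L, role = "infill")
        }
      }
    }
    layers[[k]] <- list(z = sl$z[k], paths = paths)
  }
  structure(list(layers = layers, settings = settings,
                 layer_height = settings$layer_height),
            class = "toolpath")
}

#' @export
print.toolpath <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$paths), numeric(1)))
  cat(sprintf("<toolpath> %d layers, %d paths, z %.2f..%.2f mm\n",
              length(x$layers), np, x$layers[[1]]$z,
              x$layers[[length(x$layers)]]$z))
  invisible(x)
}

#' Plan G-code and print estimates from a toolpath
#'
#' Extrusion per segment is length x width x layer height x flow (volumetric
#' E, cumulative); print time sums segment length over speed for extruding
#' and travel moves alike.
#'
#' @param toolpath a [make_toolpath()] result.
#' @param settings a [print_settings()]; defaults to the toolpath's own.
#' @return List with \code{program} (a [gcode_program()]) and
#'   \code{estimate}: bioink volume (mL, total and infill-only), print time
#'   (s), path length (mm).
#' @export
plan_gcode <- function(toolpath, settings = NULL) {
  if (is.null(settings)) settings <- toolpath$settings
  w <- settings$extrusion_width
  h <- settings$layer_height
  feed <- settings$speed * 60
  xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
  de <- numeric(0); travel <- logical(0); role <- character(0)
  for (lay in toolpath$layers) {
    for (p in lay$paths) {
      P <- p$points
      n <- nrow(P)
      if (n < 2) next
      seg <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
      xs <- c(xs, P[, 1]); ys <- c(ys, P[, 2])
      zs <- c(zs, rep(lay$z, n))
      de <- c(de, 0, seg * w * h * settings$flow)
      travel <- c(travel, TRUE, rep(FALSE, n - 1))
      role <- c(role, "travel", rep(p$role, n - 1))
    }
  }
  if (!length(xs)) stop("empty toolpath")
  moves <- data.frame(x = xs, y = ys, z = zs, e = cumsum(de), feed = feed,
                      travel = travel, role = role)
  lens <- c(0, sqrt(diff(xs)^2 + diff(ys)^2 + diff(zs)^2))
  time_s <- sum(lens) / settings$speed
  vol_total <- sum(de)
  vol_infill <- sum(de[role == "infill"])
  list(program = gcode_program(moves, settings),
       estimate = list(bioink_volume_ml = vol_total / 1000,
                       infill_volume_ml = vol_infill / 1000,
                       print_time_s = time_s,
                       path_length_mm = sum(lens)))
}
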