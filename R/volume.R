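#' Voxel volume with physical geometry
#'
#' A 3-D scalar grid (Hounsfield-like units) with per-axis voxel spacing (mm)
#' and the world position of the centre of the first voxel (mm). The world
#' coordinate of voxel \code{(i,j,k)} (1-based) is
#' \code{origin + (c(i,j,k) - 1) * spacing}.
#'
#' @param data numeric 3-D array, at least 2 voxels along each axis.
#' @param spacing numeric length-1 or length-3, voxel edge lengths in mm (> 0).
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An object of class \code{voxel_volume}.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("`data` must have at least 2 voxels along every axis")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' Binary mask on a voxel grid
#'
#' Shares the geometry (spacing, origin) of its source volume and carries a
#' free-text role label (e.g. "wound", "inverted", "shell", "patch",
#' "air-void", "muscle").
#'
#' @param data logical 3-D array.
#' @param spacing,origin grid geometry, as in [voxel_volume()].
#' @param label free-text role of the mask.
#' @return An object of class \code{binary_mask} (also \code{voxel_volume}).
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0), label = "") {
  storage.mode(data) <- "logical"
  v <- voxel_volume(data, spacing, origin)
  v$label <- as.character(label)[1L]
  class(v) <- c("binary_mask", "voxel_volume")
  v
}

# mask sharing geometry with `geom` (a voxel_volume or binary_mask)
mask_like <- function(geom, data, label = "") {
  dim(data) <- dim(geom$data)
  binary_mask(data, geom$spacing, geom$origin, label)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, values in [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> '%s' %d x %d x %d voxels, %d set (%.3g mm^3)\n",
              x$label, d[1], d[2], d[3], sum(x$data), mask_volume_mm3(x)))
  invisible(x)
}

#' World coordinates of the voxel-centre grid
#'
#' @param vol a [voxel_volume()] or [binary_mask()].
#' @return List with numeric vectors \code{x}, \code{y}, \code{z} (mm).
#' @export
voxel_axes <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

#' Volume of one voxel in mm^3
#' @param vol a [voxel_volume()].
#' @export
voxel_mm3 <- function(vol) prod(vol$spacing)

#' Physical volume of a mask in mm^3
#' @param mask a [binary_mask()].
#' @export
mask_volume_mm3 <- function(mask) sum(mask$data) * voxel_mm3(mask)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("masks/volumes are not on the same grid")
  invisible(TRUE)
}

# ------------------------------------------------------------------ volume IO

detect_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("cannot infer volume format from extension of '", path, "'")
}

#' Read a CT-like volume from NIfTI or NRRD
#'
#' Honours the voxel-centre convention; spacing is taken from the sform (or
#' pixdim) for NIfTI and from \code{space directions} for NRRD. Only
#' axis-aligned volumes are supported.
#'
#' @param path file path.
#' @param format "auto" (by extension), "nifti" or "nrrd".
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  if (format == "nifti") read_nifti_volume(path) else read_nrrd_volume(path)
}

#' Write a volume to NIfTI or NRRD
#'
#' @param vol a [voxel_volume()] or [binary_mask()] (written as 0/1).
#' @param path destination; extension selects the format unless given.
#' @param format "auto", "nifti" or "nrrd".
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path)
  data <- vol$data
  storage.mode(data) <- "double"
  if (format == "nifti") {
    im <- RNifti::asNifti(data)
    m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
    attr(m, "code") <- 2L
    im <- RNifti::`sform<-`(im, m)
    im <- RNifti::`qform<-`(im, m)
    RNifti::writeNifti(im, path)
  } else {
    write_nrrd_volume(data, vol$spacing, vol$origin, path)
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e) stop("unreadable NIfTI file: ",
                                          conditionMessage(e)))
  x <- RNifti::xform(im, useQuaternionFirst = FALSE)
  if (!is.null(attr(x, "code")) && attr(x, "code") > 0) {
    spacing <- sqrt(colSums(x[1:3, 1:3]^2))
    origin <- x[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(im)[1:3]
    origin <- c(0, 0, 0)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header is missing a valid voxel spacing")
  voxel_volume(array(as.numeric(im), dim = dim(im)), spacing, origin)
}

# Minimal NRRD (format 0004): raw little-endian encoding, axis-aligned
# space directions. Covers what this pipeline writes plus common numeric types.
write_nrrd_volume <- function(data, spacing, origin, path) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            origin[1], origin[2], origin[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(data), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("truncated NRRD header in ", path)
  lines <- strsplit(rawToChar(raw[seq_len(hdr_end - 2L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD000[1-5]$", lines[1])) stop("not a NRRD file: ", path)
  fields <- list()
  for (line in lines[-1]) {
    if (grepl("^#", line) || line == "") next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing '", k, "' in ", path)
    fields[[k]]
  }
  sizes <- as.integer(strsplit(trimws(need("sizes")), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3-D NRRD volumes are supported")
  type <- need("type")
  enc <- need("encoding")
  if (!identical(enc, "raw")) stop("only raw NRRD encoding is supported")
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  if (is.null(fields[["space directions"]]))
    stop("NRRD header is missing 'space directions' (voxel spacing)")
  dirs <- regmatches(fields[["space directions"]],
                     gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
  dm <- vapply(dirs, function(s) {
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  }, numeric(3))
  if (any(abs(dm[row(dm) != col(dm)]) > 1e-12))
    stop("only axis-aligned NRRD volumes are supported")
  spacing <- abs(diag(dm))
  if (any(spacing <= 0)) stop("NRRD header has a non-positive voxel spacing")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  tspec <- switch(type,
    "double" = list(what = "double", size = 8),
    "float"  = list(what = "double", size = 4),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2),
    "int" = , "int32" = list(what = "integer", size = 4),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1,
                                                   signed = FALSE),
    stop("unsupported NRRD type '", type, "'"))
  if (hdr_end >= length(raw)) stop("truncated NRRD data block in ", path)
  payload <- raw[seq.int(hdr_end + 1L, length(raw))]
  vals <- readBin(payload, what = tspec$what, n = n, size = tspec$size,
                  signed = if (is.null(tspec$signed)) TRUE else tspec$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NRRD data block in ", path)
  voxel_volume(array(as.numeric(vals), dim = sizes), spacing, origin)
}
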