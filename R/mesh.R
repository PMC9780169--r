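#' Triangle surface mesh in world millimetres
#'
#' @param vertices numeric n x 3 matrix of points (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param provenance free-text description of where the mesh came from.
#' @return An object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, provenance = "") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix of triangles")
  storage.mode(faces) <- "integer"
  storage.mode(vertices) <- "double"
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)[1L]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1,1], bb[2,1], bb[1,2], bb[2,2], bb[1,3], bb[2,3]))
  }
  invisible(x)
}

#' Signed volume of a watertight mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for outward
#' normals. Errors if the mesh is not watertight.
#'
#' @param mesh a [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh)) stop("mesh is not watertight; volume is undefined")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(numeric(0))
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Is every edge of the mesh shared by exactly two faces?
#'
#' @param mesh a [surface_mesh()].
#' @return TRUE for a closed 2-manifold triangle soup.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

mesh_centroid <- function(mesh) {
  # volume centroid of a watertight mesh (divergence theorem)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det6) / 6
  ctr <- colSums((a + b + c_) / 4 * det6 / 6) / vol
  unname(ctr)
}

#' Apply a rigid transform to mesh vertices
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_transform(transform, mesh$vertices)
  mesh
}

# ----------------------------------------------------------------- binary STL

#' Write a mesh as binary STL
#'
#' Little-endian binary STL: 80-byte header, uint32 triangle count, then per
#' triangle a float32 normal, three float32 vertices and a zero attribute.
#'
#' @param mesh a non-empty [surface_mesh()].
#' @param path destination path.
#' @export
write_stl <- function(mesh, path) {
  if (nrow(mesh$faces) == 0) stop("cannot write an empty mesh")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "woundpatch binary STL"))[1:80]
  writeBin(hdr, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  n <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats + 1 uint16 per triangle, assembled in one numeric block
  block <- matrix(0, nrow = 12, ncol = nf)
  block[1:3, ] <- t(n)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  fl <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  fl <- matrix(fl, nrow = 48)
  out <- rbind(fl, matrix(as.raw(0), nrow = 2, ncol = nf))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices appearing in several triangles are merged on exact float32
#' equality, so meshes written by [write_stl()] round-trip their topology.
#'
#' @param path STL file path.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 84) stop("not a binary STL file (too short): ", path)
  nf <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  need <- 84 + 50 * nf
  if (nf < 0 || length(raw) < need)
    stop("truncated or invalid binary STL: ", path)
  tri <- matrix(raw[85:need], nrow = 50)
  coords <- readBin(as.vector(tri[1:48, ]), "double", n = 12 * nf, size = 4,
                    endian = "little")
  coords <- matrix(coords, nrow = 12)
  pts <- rbind(t(coords[4:6, , drop = FALSE]),
               t(coords[7:9, , drop = FALSE]),
               t(coords[10:12, , drop = FALSE]))
  # rows interleave: A1..Anf, B1..Bnf, C1..Cnf
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[seq_len(nf)], uid[nf + seq_len(nf)], uid[2 * nf + seq_len(nf)])
  surface_mesh(verts, faces, provenance = paste0("stl:", basename(path)))
}

#' Uniformly scale a mesh to a target volume fraction
#'
#' Vertices are scaled isotropically about the volume centroid by
#' \code{fraction^(1/3)}, so the mesh volume changes by exactly
#' \code{fraction} (shape preserved).
#'
#' @param mesh a watertight [surface_mesh()].
#' @param fraction target volume ratio (> 0), e.g. 0.7 for 70 percent.
#' @return The scaled [surface_mesh()].
#' @export
scale_mesh_to_volume_fraction <- function(mesh, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0)
    stop("`fraction` must be a single positive number")
  if (!is_watertight(mesh)) stop("mesh must be watertight to scale by volume")
  ctr <- mesh_centroid(mesh)
  s <- fraction^(1 / 3)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr), 2, rep(s, 3), `*`)
  mesh$vertices <- sweep(mesh$vertices, 2, ctr, `+`)
  mesh$provenance <- sprintf("%s (scaled to %.4g volume fraction)",
                             mesh$provenance, fraction)
  mesh
}
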