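#' Triangle mesh of a body part
#'
#' A `trimesh` is the geometric substrate for all annotation analysis: a set
#' of 3D vertices plus triangular faces indexing into them. Faces are wound
#' counter-clockwise when viewed from outside, so face normals point outward.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z)
#'   in dimensionless model units.
#' @param faces integer matrix, one row per face, three columns of 1-based
#'   vertex indices.
#' @param drop_degenerate drop faces with area below `1e-12` (with a warning)
#'   instead of erroring. The vertex set is never touched, so vertex-indexed
#'   annotations stay valid.
#' @return An object of class `trimesh` with components `vertices` and `faces`.
#' @export
trimesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3,
                  dimnames = NULL)
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range [1, ", nrow(vertices), "]")
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (nrow(faces) > 0) {
    bad <- face_areas(m) < 1e-12
    if (any(bad)) {
      if (!drop_degenerate) stop(sum(bad), " degenerate face(s)")
      warning("dropping ", sum(bad), " degenerate face(s) with area < 1e-12")
      m$faces <- m$faces[!bad, , drop = FALSE]
    }
  }
  if (nrow(m$faces) == 0L) stop("mesh has no faces after cleaning")
  m
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(x) == 3L && nrow(x) == 3L) x <- matrix(x, 1L, 3L)
  if (ncol(x) != 3L) stop(what, " must have 3 columns")
  if (anyNA(x) || any(!is.finite(x))) stop(what, " contain non-finite values")
  dimnames(x) <- NULL
  x
}

#' @export
print.trimesh <- function(x, ...) {
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' @rdname trimesh
#' @param x object to test.
#' @export
is_trimesh <- function(x) inherits(x, "trimesh")

face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face geometry
#'
#' `face_normals()` returns outward unit normals (right-hand rule over the
#' counter-clockwise winding), `face_areas()` the positive triangle areas and
#' `face_centroids()` the vertex means. These drive the palmar/dorsal/oblique
#' partition, obliqueness scoring and the transfer-matrix k-NN search.
#'
#' @param mesh a [trimesh].
#' @return a numeric matrix (normals, centroids) or vector (areas), one row or
#'   element per face.
#' @export
face_normals <- function(mesh) {
  co <- face_corners(mesh)
  n <- cross3(co$b - co$a, co$c - co$a)
  n / sqrt(rowSums(n^2))
}

#' @rdname face_normals
#' @export
face_areas <- function(mesh) {
  co <- face_corners(mesh)
  0.5 * sqrt(rowSums(cross3(co$b - co$a, co$c - co$a)^2))
}

#' @rdname face_normals
#' @export
face_centroids <- function(mesh) {
  co <- face_corners(mesh)
  (co$a + co$b + co$c) / 3
}

#' Mirror a mesh across a coordinate plane
#'
#' Used to build contralateral models: a scan of the intact limb is reflected
#' across the midline to stand in for the amputated side. Face winding is
#' reversed so normals keep pointing outward.
#'
#' @param mesh a [trimesh].
#' @param plane one of `"x"`, `"y"`, `"z"`: the coordinate set to zero on the
#'   mirror plane (e.g. `"x"` reflects across the x = 0 plane).
#' @return the mirrored [trimesh].
#' @export
mirror_mesh <- function(mesh, plane = c("x", "y", "z")) {
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  v <- mesh$vertices
  v[, ax] <- -v[, ax]
  structure(list(vertices = v, faces = mesh$faces[, c(1L, 3L, 2L), drop = FALSE]),
            class = "trimesh")
}

#' Structural checks on a mesh
#'
#' Reports whether every edge is shared by exactly two faces (closed surface),
#' whether winding is consistent (each interior edge traversed once in each
#' direction) and the Euler characteristic V - E + F (2 for a genus-0 closed
#' surface).
#'
#' @param mesh a [trimesh].
#' @return list with `closed`, `consistent_winding`, `euler_characteristic`.
#' @export
mesh_checks <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key <- paste(he[, 1], he[, 2])
  ukey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  edge_count <- table(ukey)
  closed <- all(edge_count == 2L)
  nV <- length(unique(as.vector(f)))
  nE <- length(edge_count)
  list(closed = closed,
       consistent_winding = !anyDuplicated(key),
       euler_characteristic = nV - nE + nrow(f))
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume (positive for outward-wound closed surfaces).
#' Mainly a diagnostic that mirroring preserved orientation.
#'
#' @param mesh a [trimesh].
#' @return scalar signed volume in model units cubed.
#' @export
mesh_volume <- function(mesh) {
  co <- face_corners(mesh)
  sum(rowSums(co$a * cross3(co$b, co$c))) / 6
}
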