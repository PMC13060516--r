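#' Partition mesh faces into palmar/dorsal aspects and flag oblique faces
#'
#' Each face's angle from the depth (viewing) vector is
#' `acos(normal . depth)` in degrees. Faces with angle in \[0, 90) are
#' palmar, \[90, 180\] dorsal (the 90-degree boundary is assigned to dorsal as
#' a deterministic tie-break). Faces with angle strictly between 60 and 120
#' degrees are additionally flagged oblique — poorly visible in a flat
#' projection — without being excluded from their palmar/dorsal class.
#'
#' @param mesh a [trimesh].
#' @param depth_vector unit 3-vector pointing from the model toward the
#'   viewer; the default `+z` matches the convention that the 2D illustration
#'   lives in the z = 0 plane.
#' @return object of class `face_partition`: data frame with per-face columns
#'   `aspect` (`"palmar"`/`"dorsal"`), `oblique` (logical) and
#'   `angle_from_depth` (degrees).
#' @export
partition_faces <- function(mesh, depth_vector = c(0, 0, 1)) {
  depth_vector <- as.numeric(depth_vector)
  nrm <- sqrt(sum(depth_vector^2))
  if (nrm < 1e-12) stop("depth vector must be nonzero")
  depth_vector <- depth_vector / nrm
  ang <- acos(pmin(pmax(face_normals(mesh) %*% depth_vector, -1), 1)) * 180 / pi
  ang <- as.vector(ang)
  structure(data.frame(
    aspect = ifelse(ang < 90, "palmar", "dorsal"),
    oblique = ang > 60 & ang < 120,
    angle_from_depth = ang), class = c("face_partition", "data.frame"))
}

#' Split a mesh into palmar and dorsal submeshes
#'
#' @param mesh a [trimesh].
#' @param partition a `face_partition` for `mesh`.
#' @return list of two entries `palmar` and `dorsal`, each either `NULL` (no
#'   faces of that aspect) or a list with the submesh `mesh` and `face_map`
#'   (submesh face index -> source mesh face index).
#' @export
split_aspect_meshes <- function(mesh, partition) {
  if (nrow(partition) != nrow(mesh$faces))
    stop("partition does not match mesh face count")
  one <- function(aspect) {
    keep <- which(partition$aspect == aspect)
    if (!length(keep)) return(NULL)
    f <- mesh$faces[keep, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- match(f, used)
    sub <- structure(list(vertices = mesh$vertices[used, , drop = FALSE],
                          faces = matrix(remap, ncol = 3)),
                     class = "trimesh")
    list(mesh = sub, face_map = keep, vertex_map = used)
  }
  list(palmar = one("palmar"), dorsal = one("dorsal"))
}

#' Flatten a mesh along the depth vector
#'
#' Sets the component of every vertex along the depth vector to zero, leaving
#' in-plane coordinates unchanged; idempotent.
#'
#' @inheritParams partition_faces
#' @return the flattened [trimesh].
#' @export
flatten_mesh <- function(mesh, depth_vector = c(0, 0, 1)) {
  depth_vector <- as.numeric(depth_vector)
  depth_vector <- depth_vector / sqrt(sum(depth_vector^2))
  v <- mesh$vertices
  v <- v - (v %*% depth_vector) %*% t(depth_vector)
  structure(list(vertices = v, faces = mesh$faces), class = "trimesh")
}

#' Binary pixel masks
#'
#' A `pixel_mask` is a binary raster comparable to a binarized 2D annotation
#' illustration. `values[j, i]` covers the pixel whose center is at
#' `origin + (i - 0.5, j - 0.5) * pixel_size` (row 1 at the bottom edge).
#'
#' @param width,height raster size in pixels.
#' @param origin length-2 numeric, model/illustration coordinates of the
#'   raster's lower-left corner.
#' @param pixel_size side length of a (square) pixel in model units.
#' @param values optional height x width 0/1 matrix (default all zero).
#' @return object of class `pixel_mask`.
#' @export
pixel_mask <- function(width, height, origin = c(0, 0), pixel_size = 1,
                       values = NULL) {
  if (pixel_size <= 0) stop("pixel size must be positive")
  if (width < 1 || height < 1) stop("mask must be at least 1 x 1")
  if (is.null(values)) values <- matrix(0L, height, width)
  values <- matrix(as.integer(values != 0), height, width)
  structure(list(width = as.integer(width), height = as.integer(height),
                 origin = as.numeric(origin), pixel_size = pixel_size,
                 values = values), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat("pixel_mask:", x$width, "x", x$height, "px, pixel size", x$pixel_size,
      ",", sum(x$values), "set\n")
  invisible(x)
}

pixel_centers <- function(mask) {
  list(x = mask$origin[1] + (seq_len(mask$width) - 0.5) * mask$pixel_size,
       y = mask$origin[2] + (seq_len(mask$height) - 0.5) * mask$pixel_size)
}

#' Rasterize annotated faces of a flattened mesh into a pixel mask
#'
#' A pixel is set iff its center lies inside (or on the boundary of) at least
#' one annotated projected triangle. Overlapping faces of the same aspect are
#' not occlusion-resolved: the mask records the union silhouette.
#'
#' @param mesh2d a flattened [trimesh] (geometry in the x-y plane).
#' @param faces integer vector of annotated face indices on `mesh2d`.
#' @param grid a [pixel_mask] giving the raster geometry (its values are
#'   ignored).
#' @return a [pixel_mask] on the same grid.
#' @export
rasterize <- function(mesh2d, faces, grid) {
  out <- pixel_mask(grid$width, grid$height, grid$origin, grid$pixel_size)
  if (!length(faces)) return(out)
  ctr <- pixel_centers(out)
  px <- out$pixel_size
  eps <- 1e-12 * max(1, max(abs(mesh2d$vertices[, 1:2])))
  for (f in faces) {
    tri <- mesh2d$vertices[mesh2d$faces[f, ], 1:2, drop = FALSE]
    is_ <- which(ctr$x >= min(tri[, 1]) - px & ctr$x <= max(tri[, 1]) + px)
    js <- which(ctr$y >= min(tri[, 2]) - px & ctr$y <= max(tri[, 2]) + px)
    if (!length(is_) || !length(js)) next
    pts <- cbind(rep(ctr$x[is_], each = length(js)),
                 rep(ctr$y[js], times = length(is_)))
    inside <- points_in_triangle(pts, tri, eps)
    if (any(inside)) {
      jj <- rep(js, times = length(is_))[inside]
      ii <- rep(is_, each = length(js))[inside]
      out$values[cbind(jj, ii)] <- 1L
    }
  }
  out
}

# sign-consistent edge test; boundary points (within eps) count as inside
points_in_triangle <- function(pts, tri, eps = 1e-12) {
  e <- function(a, b) (pts[, 1] - a[1]) * (b[2] - a[2]) -
    (pts[, 2] - a[2]) * (b[1] - a[1])
  d1 <- e(tri[1, ], tri[2, ]); d2 <- e(tri[2, ], tri[3, ])
  d3 <- e(tri[3, ], tri[1, ])
  (d1 <= eps & d2 <= eps & d3 <= eps) | (d1 >= -eps & d2 >= -eps & d3 >= -eps)
}

#' Jaccard index of two binary masks
#'
#' Intersection over union of the set pixels; 0 indicates no overlap and 1
#' perfect correspondence. Two empty masks return 0 by convention (no
#' annotation agreement claimable).
#'
#' @param a,b [pixel_mask]s on identical grids.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (a$width != b$width || a$height != b$height ||
      any(a$origin != b$origin) || a$pixel_size != b$pixel_size)
    stop("pixel masks are on different grids")
  uni <- sum(a$values | b$values)
  if (uni == 0) return(0)
  sum(a$values & b$values) / uni
}

#' Obliqueness of an annotation
#'
#' The proportion of an annotation's surface area lying on oblique faces
#' (normals 60-120 degrees from the depth vector): annotated-oblique area
#' over total annotated area.
#'
#' @param field a [projected_field].
#' @param partition `face_partition` of the annotated mesh.
#' @param areas per-face areas from [face_areas()].
#' @return scalar in \[0, 1\].
#' @export
obliqueness <- function(field, partition, areas) {
  if (!length(field$faces)) stop("obliqueness undefined for an empty field")
  ann <- field$faces
  sum(areas[ann][partition$oblique[ann]]) / sum(areas[ann])
}

#' Read / write pixel masks as PNG with a JSON sidecar
#'
#' The PNG holds the binary grid (nonzero = annotated, image row 1 at the
#' top); the sidecar `<path>.json` records `origin` and `pixel_size` so the
#' mask's mapping into model coordinates survives the round trip.
#'
#' @param path PNG file path.
#' @return `load_mask()` returns a [pixel_mask].
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path) else list(origin = c(0, 0), pixel_size = 1)
  vals <- (img[rev(seq_len(nrow(img))), , drop = FALSE] > 0.5)  # flip to y-up
  pixel_mask(ncol(img), nrow(img), as.numeric(meta$origin), meta$pixel_size,
             vals)
}

#' @rdname load_mask
#' @param mask a [pixel_mask].
#' @export
save_mask <- function(mask, path) {
  img <- mask$values[rev(seq_len(mask$height)), , drop = FALSE]
  png::writePNG(matrix(as.numeric(img), mask$height, mask$width), path)
  jsonlite::write_json(list(origin = mask$origin,
                            pixel_size = mask$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
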