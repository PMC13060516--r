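#' Projected-field annotations
#'
#' A `projected_field` records one stimulation-evoked sensation annotated on a
#' mesh: the set of painted faces, optional hotspot points (loci of most
#' intense sensation, placed on the mesh surface), three visual-analog scale
#' ratings normalized to \[0, 1\] (naturalness, pain, overall intensity) and a
#' list of quality descriptors, each with its own intensity and a depth locale
#' (above, at or below the skin).
#'
#' The canonical storage is face-level — faces are the paint/erase unit — and
#' per-vertex binary arrays are derived views used by the transfer matrix.
#'
#' @param mesh_id identifier of the mesh the annotation lives on.
#' @param faces integer vector of annotated face indices (1-based).
#' @param hotspots numeric matrix of 3D points (0 rows if none).
#' @param naturalness,pain,overall_intensity scale ratings in \[0, 1\].
#' @param qualities data frame with columns `name`, `intensity` (in \[0, 1\])
#'   and `depth` (one of `"above_skin"`, `"at_skin"`, `"below_skin"`).
#' @return object of class `projected_field`.
#' @export
projected_field <- function(mesh_id, faces, hotspots = NULL,
                            naturalness = 0, pain = 0, overall_intensity = 0,
                            qualities = NULL) {
  faces <- sort(unique(as.integer(faces)))
  if (length(faces) && min(faces) < 1L) stop("face indices must be >= 1")
  if (is.null(hotspots) || (is.matrix(hotspots) && nrow(hotspots) == 0)) {
    hotspots <- matrix(numeric(0), 0, 3)
  } else hotspots <- as_coord_matrix(hotspots, "hotspots")
  for (nm in c("naturalness", "pain", "overall_intensity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a single value in [0, 1]")
  }
  if (is.null(qualities)) {
    qualities <- data.frame(name = character(), intensity = numeric(),
                            depth = character())
  } else {
    qualities <- as.data.frame(qualities)
    if (!all(c("name", "intensity", "depth") %in% names(qualities)))
      stop("qualities need columns name, intensity, depth")
    if (any(qualities$intensity < 0 | qualities$intensity > 1))
      stop("quality intensity out of [0, 1]")
    if (!all(qualities$depth %in% c("above_skin", "at_skin", "below_skin")))
      stop("quality depth must be above_skin, at_skin or below_skin")
  }
  structure(list(mesh_id = as.character(mesh_id), faces = faces,
                 hotspots = hotspots, naturalness = naturalness, pain = pain,
                 overall_intensity = overall_intensity, qualities = qualities),
            class = "projected_field")
}

#' @export
print.projected_field <- function(x, ...) {
  cat("projected_field on '", x$mesh_id, "': ", length(x$faces), " faces, ",
      nrow(x$hotspots), " hotspot(s), ", nrow(x$qualities), " qualit(ies)\n",
      sep = "")
  invisible(x)
}

#' Validate a field against the mesh it annotates
#'
#' Checks that every face index exists on the mesh and that every hotspot lies
#' on the mesh surface (point-to-triangle distance below `tol`).
#'
#' @param field a [projected_field].
#' @param mesh a [trimesh].
#' @param tol maximum allowed hotspot off-surface distance.
#' @return `field`, invisibly; errors on violation.
#' @export
validate_field <- function(field, mesh, tol = 1e-6) {
  if (length(field$faces) && max(field$faces) > nrow(mesh$faces))
    stop("field annotates face ", max(field$faces), " but mesh has only ",
         nrow(mesh$faces), " faces")
  if (nrow(field$hotspots)) {
    d <- apply(field$hotspots, 1, function(p) min_dist_to_mesh(p, mesh))
    if (any(d > tol))
      stop("hotspot(s) off the mesh surface by up to ",
           format(max(d)), " (> ", tol, ")")
  }
  invisible(field)
}

# exact point-to-triangle distance, minimized over all faces
min_dist_to_mesh <- function(p, mesh) {
  co <- face_corners(mesh)
  min(point_triangle_dist(p, co$a, co$b, co$c))
}

# vectorized over triangles given as row-matrices a, b, c
point_triangle_dist <- function(p, a, b, c) {
  # project onto triangle plane, clamp barycentrics edge-wise (Eberly-style)
  ab <- b - a; ac <- c - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  denom <- d00 * d11 - d01^2
  v <- (d11 * d1 - d01 * d2) / denom
  w <- (d00 * d2 - d01 * d1) / denom
  v <- pmin(pmax(v, 0), 1); w <- pmin(pmax(w, 0), 1)
  s <- v + w
  scale <- ifelse(s > 1, 1 / s, 1)
  v <- v * scale; w <- w * scale
  q <- a + ab * v + ac * w
  d_int <- sqrt(rowSums((q - matrix(p, nrow(a), 3, byrow = TRUE))^2))
  # clamped interior projection may miss edge minima; also check the 3 edges
  pmin(d_int, point_segment_dist(p, a, b), point_segment_dist(p, b, c),
       point_segment_dist(p, a, c))
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)
  t <- rowSums((pm - a) * ab) / pmax(rowSums(ab * ab), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  sqrt(rowSums((a + ab * t - pm)^2))
}

#' Convert between face-level and vertex-level annotation
#'
#' `field_to_vertex_array()` returns a binary vector over mesh vertices: 1
#' where the vertex belongs to at least one annotated face. This is the
#' per-vertex projected field array consumed by the transfer matrix (an
#' annotated face sets all 3 of its vertices). `vertex_array_to_faces()`
#' inverts the view: a face is annotated iff all 3 of its vertices are set.
#'
#' @param field a [projected_field].
#' @param mesh the [trimesh] named by `field$mesh_id`.
#' @param check_id error if `field$mesh_id` differs from `mesh_id`.
#' @param mesh_id optional mesh identifier to check against.
#' @return `field_to_vertex_array()`: integer 0/1 vector of length
#'   `nrow(mesh$vertices)`; `vertex_array_to_faces()`: sorted integer vector
#'   of face indices.
#' @export
field_to_vertex_array <- function(field, mesh, check_id = !is.null(mesh_id),
                                  mesh_id = NULL) {
  if (check_id && !identical(field$mesh_id, mesh_id))
    stop("field is for mesh '", field$mesh_id, "', not '", mesh_id, "'")
  validate_field(field, mesh, tol = Inf)  # index bounds only
  arr <- integer(nrow(mesh$vertices))
  arr[as.vector(mesh$faces[field$faces, , drop = FALSE])] <- 1L
  arr
}

#' @rdname field_to_vertex_array
#' @param arr binary vector over mesh vertices.
#' @export
vertex_array_to_faces <- function(arr, mesh) {
  if (length(arr) != nrow(mesh$vertices))
    stop("vertex array length ", length(arr), " != vertex count ",
         nrow(mesh$vertices))
  arr <- as.integer(arr != 0)
  on <- matrix(arr[mesh$faces], ncol = 3)
  which(rowSums(on) == 3L)
}

#' Read / write projected fields as JSON
#'
#' Face indices are stored 0-based in JSON (the convention of the annotation
#' app's mesh format) and converted to this package's 1-based indexing on
#' load. Scale and quality-intensity values are validated to \[0, 1\] and the
#' depth enum to its three values.
#'
#' @param path JSON file path.
#' @param mesh optional [trimesh]: when supplied, hotspots are checked to lie
#'   on the surface and face indices to be in range.
#' @return `load_field()` returns a [projected_field].
#' @export
load_field <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("cannot read field file: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  q <- j$qualities
  if (is.null(q) || length(q) == 0) q <- NULL
  hs <- j$hotspots
  if (!is.null(hs) && length(hs)) {
    if (!is.matrix(hs)) hs <- matrix(unlist(hs), ncol = 3, byrow = TRUE)
  } else hs <- NULL
  field <- projected_field(
    mesh_id = j$mesh_id, faces = as.integer(j$faces) + 1L, hotspots = hs,
    naturalness = j$naturalness, pain = j$pain,
    overall_intensity = j$overall_intensity, qualities = q)
  if (!is.null(mesh)) validate_field(field, mesh)
  field
}

#' @rdname load_field
#' @param field a [projected_field].
#' @export
save_field <- function(field, path) {
  j <- list(mesh_id = field$mesh_id,
            faces = field$faces - 1L,
            hotspots = if (nrow(field$hotspots))
              unname(apply(field$hotspots, 1, identity, simplify = FALSE))
            else list(),
            naturalness = field$naturalness, pain = field$pain,
            overall_intensity = field$overall_intensity,
            qualities = if (nrow(field$qualities))
              lapply(seq_len(nrow(field$qualities)), function(i)
                as.list(field$qualities[i, ])) else list())
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
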