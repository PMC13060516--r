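#' Choose the k-NN size for transfer-matrix construction
#'
#' The neighbourhood size scales with the ratio of source to target face
#' count, with a floor of 30 (the value used at a 1:1 ratio):
#' `k = max(30, ceiling(30 * source / target))`.
#'
#' @param source_face_count,target_face_count positive face counts.
#' @return integer k.
#' @export
choose_k <- function(source_face_count, target_face_count) {
  if (source_face_count < 1 || target_face_count < 1)
    stop("face counts must be positive")
  max(30L, as.integer(ceiling(30 * source_face_count / target_face_count)))
}

#' Rotation taking a unit normal onto +z
#'
#' Rodrigues rotation about `normal x z`; the antiparallel case (normal =
#' -z) rotates 180 degrees about the x axis. Always a proper rotation
#' (det = +1).
#'
#' @param normal unit 3-vector.
#' @return 3 x 3 rotation matrix `R` with `R %*% normal = (0, 0, 1)`.
#' @export
rotation_to_z <- function(normal) {
  normal <- as.numeric(normal)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) stop("normal must be unit length")
  z <- c(0, 0, 1)
  c_ <- sum(normal * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12)
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  v <- c(normal[2] * z[3] - normal[3] * z[2],
         normal[3] * z[1] - normal[1] * z[3],
         normal[1] * z[2] - normal[2] * z[1])  # normal x z
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Area of intersection of two planar triangles
#'
#' Sutherland-Hodgman clip of triangle A against (convex) triangle B followed
#' by the shoelace formula. Degenerate inputs (area below `1e-12`) return 0.
#'
#' @param triA,triB 3 x 2 matrices of triangle vertices.
#' @return nonnegative overlap area.
#' @export
triangle_overlap_area <- function(triA, triB) {
  areaA <- polygon_area(triA); areaB <- polygon_area(triB)
  if (abs(areaA) < 1e-12 || abs(areaB) < 1e-12) return(0)
  if (areaA < 0) triA <- triA[3:1, , drop = FALSE]
  if (areaB < 0) triB <- triB[3:1, , drop = FALSE]
  poly <- triA
  for (i in 1:3) {
    a <- triB[i, ]; b <- triB[if (i == 3) 1 else i + 1, ]
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) == 0) return(0)
  }
  abs(polygon_area(poly))
}

polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# keep the part of polygon `p` on the left of directed edge a->b
clip_halfplane <- function(p, a, b) {
  n <- nrow(p)
  if (n == 0) return(p)
  d <- (p[, 1] - a[1]) * (b[2] - a[2]) - (p[, 2] - a[2]) * (b[1] - a[1])
  d <- -d  # left of a->b  => cross(b-a, p-a) >= 0
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    di <- d[i]; dj <- d[j]
    if (di >= 0) out <- rbind(out, p[i, ])
    if ((di > 0 && dj < 0) || (di < 0 && dj > 0)) {
      t <- di / (di - dj)
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  out
}

#' Build the sparse annotation transfer matrix between two meshes
#'
#' For every target face: the k nearest source faces (Euclidean distance
#' between face centroids, k-d tree search) are gathered; all vertices are
#' re-zeroed by subtracting the target face centroid and rotated so the
#' target normal points along +z; source vertices have their z component
#' zeroed, producing a perspective view of the source faces along the target
#' normal; each source face's overlap area with the projected target face,
#' divided by the target face area, is the proportional coverage, written
#' additively to every (target vertex, source vertex) combination of the two
#' faces. Both meshes must already sit in a common frame (typically the
#' source has been landmark-morphed onto the target).
#'
#' @param source,target [trimesh]es in a common frame.
#' @param k neighbourhood size; `NULL` for [choose_k()] on the face counts.
#'   Values above the source face count are clamped with a warning.
#' @param filter_backfacing drop source faces whose normal opposes the target
#'   face normal (for heavily folded meshes); default keeps them, since
#'   proximity is the paper's only filter.
#' @param source_id,target_id mesh identifiers stored in the metadata.
#' @return object of class `transfer_matrix`: list with `matrix` (a
#'   `dgCMatrix`, target vertices x source vertices), `source_id`,
#'   `target_id`, `k`.
#' @export
build_transfer_matrix <- function(source, target, k = NULL,
                                  filter_backfacing = FALSE,
                                  source_id = "source", target_id = "target") {
  if (nrow(source$faces) == 0 || nrow(target$faces) == 0)
    stop("empty mesh")
  if (is.null(k)) k <- choose_k(nrow(source$faces), nrow(target$faces))
  if (k > nrow(source$faces)) {
    warning("k = ", k, " exceeds source face count; clamped to ",
            nrow(source$faces))
    k <- nrow(source$faces)
  }
  sc <- face_centroids(source)
  tc <- face_centroids(target)
  tn <- face_normals(target)
  sn <- if (filter_backfacing) face_normals(source) else NULL
  ta <- face_areas(target)
  nn <- RANN::nn2(sc, tc, k = k)$nn.idx
  trip <- vector("list", nrow(target$faces))
  for (tf_i in seq_len(nrow(target$faces))) {
    R <- rotation_to_z(tn[tf_i, ])
    ctr <- tc[tf_i, ]
    tv_idx <- target$faces[tf_i, ]
    ttri <- tcrossprod(sweep(target$vertices[tv_idx, , drop = FALSE], 2, ctr),
                       R)[, 1:2, drop = FALSE]
    src_faces <- nn[tf_i, ]
    if (filter_backfacing)
      src_faces <- src_faces[sn[src_faces, , drop = FALSE] %*% tn[tf_i, ] > 0]
    covs <- vapply(src_faces, function(sf_i) {
      stri <- tcrossprod(sweep(source$vertices[source$faces[sf_i, ], ,
                                               drop = FALSE], 2, ctr),
                         R)[, 1:2, drop = FALSE]  # z zeroed by projection
      triangle_overlap_area(stri, ttri) / ta[tf_i]
    }, 0)
    hit <- covs > 0
    if (!any(hit)) next
    sv <- t(source$faces[src_faces[hit], , drop = FALSE])  # 3 x nhit
    trip[[tf_i]] <- list(
      i = rep(rep(tv_idx, each = 3L), times = sum(hit)),
      j = as.vector(sv[rep(1:3, times = 3L), , drop = FALSE]),
      x = rep(covs[hit], each = 9L))
  }
  trip <- trip[!vapply(trip, is.null, TRUE)]
  M <- Matrix::sparseMatrix(i = unlist(lapply(trip, `[[`, "i")),
                            j = unlist(lapply(trip, `[[`, "j")),
                            x = unlist(lapply(trip, `[[`, "x")),
                            dims = c(nrow(target$vertices),
                                     nrow(source$vertices)))
  structure(list(matrix = M, source_id = source_id, target_id = target_id,
                 k = as.integer(k)), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix: ", nrow(x$matrix), " target x ", ncol(x$matrix),
      " source vertices, k = ", x$k, ", ",
      length(x$matrix@x), " stored entries\n", sep = "")
  invisible(x)
}

#' Project an annotation through a transfer matrix
#'
#' Multiplies the source mesh's per-vertex projected field array by the
#' transfer matrix. Target vertices whose accumulated coverage sum reaches
#' the threshold (default 1.5 = 3 vertices per face x 50% coverage,
#' inclusive) are set; target faces with all three vertices set become the
#' projected annotation. Scale ratings and qualities are copied verbatim;
#' hotspots are not transferred.
#'
#' @param field_src [projected_field] on the source mesh.
#' @param T_ a `transfer_matrix` from [build_transfer_matrix()].
#' @param source,target the [trimesh]es the matrix was built from.
#' @param threshold inclusive annotation threshold on the summed coverage.
#' @return a [projected_field] on the target mesh.
#' @export
project_field <- function(field_src, T_, source, target, threshold = 1.5) {
  if (!identical(field_src$mesh_id, T_$source_id))
    stop("field is on mesh '", field_src$mesh_id,
         "' but the matrix was built from '", T_$source_id, "'")
  a <- field_to_vertex_array(field_src, source)
  s <- as.numeric(T_$matrix %*% a)
  b <- as.integer(s >= threshold)
  projected_field(mesh_id = T_$target_id,
                  faces = vertex_array_to_faces(b, target),
                  naturalness = field_src$naturalness, pain = field_src$pain,
                  overall_intensity = field_src$overall_intensity,
                  qualities = field_src$qualities)
}

#' Read / write transfer matrices (Matrix Market + JSON metadata)
#'
#' The sparse matrix goes to `<path>` in Matrix Market coordinate format and
#' the metadata (`source_mesh`, `target_mesh`, `k`) to `<path>.json`.
#'
#' @param path `.mtx` file path.
#' @return `load_transfer_matrix()` returns a `transfer_matrix`.
#' @export
load_transfer_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read matrix file: ", path)
  M <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(matrix = M, source_id = meta$source_mesh,
                 target_id = meta$target_mesh, k = as.integer(meta$k)),
            class = "transfer_matrix")
}

#' @rdname load_transfer_matrix
#' @param T_ a `transfer_matrix`.
#' @export
save_transfer_matrix <- function(T_, path) {
  Matrix::writeMM(T_$matrix, path)
  jsonlite::write_json(list(source_mesh = T_$source_id,
                            target_mesh = T_$target_id, k = T_$k),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
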