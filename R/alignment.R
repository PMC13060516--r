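#' Dependency list over primary landmarks
#'
#' The hand (or any articulated part) is treated as a hierarchy of segments
#' attached at joints. A dependency list is an ordered set of
#' `(parent, child)` primary-landmark pairs rooted at the anchor, in
#' topological order: each pair's parent has already appeared as a child (or
#' is the root) by the time the pair is processed. Each pair defines one
#' segment, identified by its child landmark name.
#'
#' @param root name of the root primary landmark (the wrist base).
#' @param pairs two-column character matrix (or list of length-2 vectors) of
#'   `(parent, child)` names.
#' @return object of class `dependency_list` with `root` and `pairs`.
#' @export
dependency_list <- function(root, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2)
  children <- pairs[, 2]
  if (anyDuplicated(children))
    stop("landmark(s) appear more than once as child: ",
         paste(unique(children[duplicated(children)]), collapse = ", "))
  if (root %in% children) stop("root must not appear as a child")
  seen <- root
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs[i, 1] %in% seen))
      stop("dependency list not in topological order: parent '", pairs[i, 1],
           "' of '", pairs[i, 2], "' not yet defined")
    seen <- c(seen, pairs[i, 2])
  }
  structure(list(root = root, pairs = pairs), class = "dependency_list")
}

#' @export
print.dependency_list <- function(x, ...) {
  cat("dependency_list: root '", x$root, "', ", nrow(x$pairs), " pairs\n",
      sep = "")
  invisible(x)
}

#' Read / write dependency lists as JSON
#'
#' Format: `{"root": "wrist", "pairs": [["wrist","Imcp"], ...]}`.
#' @param path JSON file path.
#' @return `load_dependencies()` returns a [dependency_list].
#' @export
load_dependencies <- function(path) {
  if (!file.exists(path)) stop("cannot read dependency file: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dependency_list(j$root, j$pairs)
}

#' @rdname load_dependencies
#' @param deps a [dependency_list].
#' @export
save_dependencies <- function(deps, path) {
  jsonlite::write_json(list(root = deps$root, pairs = deps$pairs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Whole-model alignment with anchor re-translation
#'
#' First fits an unrestricted similarity Procrustes (reflection permitted)
#' from the full matched landmark complement of the model onto the target
#' (e.g. 2D illustration) landmarks and applies it to the mesh and landmarks;
#' then rigidly translates both so the model's anchor landmark coincides
#' exactly with the target's anchor.
#'
#' @param mesh the model [trimesh].
#' @param lms3d [landmark_set] of the model (same frame as `mesh`).
#' @param lms2d target [landmark_set] (2D sets carry z = 0).
#' @return list with the aligned `mesh` and `landmarks`.
#' @export
initial_align <- function(mesh, lms3d, lms2d) {
  if (!setequal(lms3d$names, lms2d$names))
    stop("landmark names do not match between the two sets")
  if (!identical(lms3d$anchor, lms2d$anchor))
    stop("anchor names differ between the two sets")
  tgt <- landmark_positions(lms2d, lms3d$names)
  tf <- procrustes(lms3d$positions, tgt, allow_reflection = TRUE,
                   allow_scale = TRUE)
  pos <- apply_transform(tf, lms3d$positions)
  verts <- apply_transform(tf, mesh$vertices)
  shift <- landmark_positions(lms2d, lms2d$anchor) -
    pos[match(lms3d$anchor, lms3d$names), , drop = FALSE]
  pos <- sweep(pos, 2, as.vector(shift), `+`)
  verts <- sweep(verts, 2, as.vector(shift), `+`)
  list(mesh = structure(list(vertices = verts, faces = mesh$faces),
                        class = "trimesh"),
       landmarks = with_positions(lms3d, pos))
}

#' Expand primary landmarks into temporary landmarks along each segment
#'
#' Interpolates evenly spaced temporary landmarks along every parent-to-child
#' segment of the dependency list, at most `spacing` apart, each tagged with
#' the child's segment id. The original primary landmarks are retained: each
#' non-root primary is tagged with its own segment (the pair in which it is
#' the child) and the root with the root segment.
#'
#' @param lms a [landmark_set].
#' @param deps a [dependency_list].
#' @param spacing maximum distance between consecutive temporary landmarks
#'   (model units). Default: 5% of the anchor-to-farthest-primary distance,
#'   making assignment resolution scale-free.
#' @return data frame with columns `x`, `y`, `z`, `segment`.
#' @export
expand_landmarks <- function(lms, deps, spacing = NULL) {
  if (is.null(spacing)) spacing <- 0.05 * hand_length(lms)
  if (spacing <= 0) stop("spacing must be positive")
  prim <- lms$names[lms$roles == "primary"]
  segs <- c(deps$root, deps$pairs[, 2])
  out <- list()
  # originals first
  for (nm in intersect(prim, segs)) {
    p <- landmark_positions(lms, nm)
    out[[length(out) + 1L]] <- c(p, match(nm, segs))
  }
  for (i in seq_len(nrow(deps$pairs))) {
    a <- landmark_positions(lms, deps$pairs[i, 1])
    b <- landmark_positions(lms, deps$pairs[i, 2])
    len <- sqrt(sum((b - a)^2))
    n <- ceiling(len / spacing)
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        p <- a + (k / n) * (b - a)
        out[[length(out) + 1L]] <- c(p, match(deps$pairs[i, 2], segs))
      }
    }
  }
  m <- do.call(rbind, out)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
             segment = factor(segs[m[, 4]], levels = segs))
}

#' Characteristic length of a landmark set
#'
#' Anchor-to-farthest-primary distance: a scale-free proxy for hand length,
#' used to express defaults (temporary-landmark spacing) and error metrics
#' relative to model size.
#'
#' @param lms a [landmark_set].
#' @return scalar length in model units.
#' @export
hand_length <- function(lms) {
  a <- landmark_positions(lms, lms$anchor)
  prim <- lms$positions[lms$roles == "primary", , drop = FALSE]
  max(sqrt(rowSums(sweep(prim, 2, as.vector(a))^2)))
}

#' Assign mesh vertices to segments with exponential falloff weights
#'
#' Each vertex's primary segment is that of its nearest temporary landmark
#' (ties broken toward the earliest segment in dependency-list order). Partial
#' influence from dependency-linked segments is modelled with an exponential
#' falloff: the weight of segment s is `exp(-d_s / falloff_scale)` with `d_s`
#' the distance to the nearest temporary landmark of s, evaluated over the
#' primary segment and the segments sharing a dependency edge with it, then
#' normalized to sum to 1.
#'
#' @param mesh a [trimesh].
#' @param temp_lms temporary landmarks from [expand_landmarks()].
#' @param deps the [dependency_list].
#' @param falloff_scale distance constant of the falloff (model units), a
#'   single value or one per segment. Default: 25% of each segment's
#'   parent-to-child primary landmark distance (the root segment inherits the
#'   mean); a vertex's falloff is taken from its primary segment.
#' @param lms the [landmark_set] (needed only to compute the default
#'   `falloff_scale`).
#' @return object of class `segment_assignment`: list with `segments`
#'   (segment ids, dependency order), `primary` (per-vertex segment index)
#'   and `weights` (vertex x segment matrix, rows summing to 1).
#' @export
assign_vertices <- function(mesh, temp_lms, deps, falloff_scale = NULL,
                            lms = NULL) {
  segs <- c(deps$root, deps$pairs[, 2])
  if (is.null(falloff_scale)) {
    if (is.null(lms))
      stop("supply falloff_scale or lms (for the default per-segment scale)")
    seg_len <- vapply(seq_len(nrow(deps$pairs)), function(i) {
      sqrt(sum((landmark_positions(lms, deps$pairs[i, 2]) -
                  landmark_positions(lms, deps$pairs[i, 1]))^2))
    }, 0)
    falloff_scale <- 0.25 * c(mean(seg_len), seg_len)
  }
  falloff_scale <- rep_len(falloff_scale, length(segs))
  if (any(falloff_scale <= 0)) stop("falloff_scale must be positive")
  tp <- as.matrix(temp_lms[, c("x", "y", "z")])
  tseg <- as.integer(factor(temp_lms$segment, levels = segs))
  V <- mesh$vertices
  # distance from every vertex to the nearest temporary landmark per segment
  dmin <- matrix(Inf, nrow(V), length(segs))
  for (s in seq_along(segs)) {
    sel <- tp[tseg == s, , drop = FALSE]
    if (nrow(sel) == 0) next
    nn <- RANN::nn2(sel, V, k = 1)
    dmin[, s] <- nn$nn.dists[, 1]
  }
  primary <- apply(dmin, 1, which.min)  # which.min: earliest index wins ties
  # segment adjacency: linked iff the pairs share a primary landmark
  adj <- matrix(FALSE, length(segs), length(segs))
  for (i in seq_len(nrow(deps$pairs))) {
    p <- match(deps$pairs[i, 1], segs)
    c_ <- match(deps$pairs[i, 2], segs)
    adj[p, c_] <- adj[c_, p] <- TRUE
  }
  W <- matrix(0, nrow(V), length(segs))
  for (s in seq_along(segs)) {
    rows <- which(primary == s)
    if (!length(rows)) next
    involved <- c(s, which(adj[s, ]))
    w <- exp(-dmin[rows, involved, drop = FALSE] / falloff_scale[s])
    W[rows, involved] <- w / rowSums(w)
  }
  structure(list(segments = segs, primary = primary, weights = W),
            class = "segment_assignment")
}

#' Iterative segmented Procrustes morph
#'
#' Walks the dependency list in order. For each `(parent, child)` pair it
#' (1) takes the pair's primary landmarks, (2) adds every accessory landmark
#' whose suffix-stripped base name matches one of them, (3) fits a
#' no-reflection similarity Procrustes from the superset's current positions
#' to their targets, and (4) applies the fit to the superset's landmarks and
#' — weighted by the segment assignment — to the mesh vertices influenced by
#' the pair's child segment. Landmark updates compose sequentially down the
#' tree (each later fit starts from already-moved positions); each vertex's
#' final position is the weight-averaged image of its starting position under
#' the per-segment fits (vertices on the root segment keep their aligned
#' position). With `hard = TRUE` weighting is disabled and every vertex moves
#' rigidly with its primary segment.
#'
#' @param mesh the [trimesh] (typically after [initial_align()]).
#' @param lms_src current [landmark_set] of the mesh.
#' @param lms_tgt target [landmark_set] (matched names).
#' @param deps a [dependency_list].
#' @param assignment a `segment_assignment` from [assign_vertices()].
#' @param hard move each vertex entirely with its primary segment.
#' @return list with morphed `mesh`, `landmarks`, and `fits` (one
#'   `procrustes_transform` per dependency pair, named by child segment).
#' @export
segmented_procrustes <- function(mesh, lms_src, lms_tgt, deps, assignment,
                                 hard = FALSE) {
  if (!setequal(lms_src$names, lms_tgt$names))
    stop("landmark names do not match between source and target sets")
  segs <- assignment$segments
  cur <- lms_src
  fits <- vector("list", nrow(deps$pairs))
  names(fits) <- deps$pairs[, 2]
  V0 <- mesh$vertices
  Vacc <- V0 * 0  # weighted accumulation of per-segment images
  Wsum <- numeric(nrow(V0))
  w_of <- function(seg_name) {
    s <- match(seg_name, segs)
    if (hard) as.numeric(assignment$primary == s) else assignment$weights[, s]
  }
  # root segment: identity (vertices anchored at the wrist stay put)
  w <- w_of(deps$root)
  Vacc <- Vacc + w * V0
  Wsum <- Wsum + w
  for (i in seq_len(nrow(deps$pairs))) {
    pr <- deps$pairs[i, 1]; ch <- deps$pairs[i, 2]
    bases <- c(pr, ch)
    superset <- lms_src$names[lms_src$names %in% bases |
                                (lms_src$roles == "accessory" &
                                   landmark_base(lms_src$names) %in% bases)]
    src <- landmark_positions(cur, superset)
    tgt <- landmark_positions(lms_tgt, superset)
    tf <- procrustes(src, tgt, allow_reflection = FALSE, allow_scale = TRUE)
    fits[[i]] <- tf
    idx <- match(superset, cur$names)
    cur$positions[idx, ] <- apply_transform(tf, src)
    w <- w_of(ch)
    if (any(w > 0)) {
      moved <- apply_transform(tf, V0)
      Vacc <- Vacc + w * moved
      Wsum <- Wsum + w
    }
  }
  if (any(Wsum <= 0)) stop("vertex with zero total segment weight")
  verts <- Vacc / Wsum
  list(mesh = structure(list(vertices = verts, faces = mesh$faces),
                        class = "trimesh"),
       landmarks = cur, fits = fits)
}

#' Full 3D-to-2D (or 3D-to-3D) landmark-driven morph
#'
#' Convenience wrapper chaining [initial_align()], [expand_landmarks()],
#' [assign_vertices()] and [segmented_procrustes()] with their defaults.
#'
#' @inheritParams segmented_procrustes
#' @param lms3d source landmarks.
#' @param lms2d target landmarks.
#' @param spacing,falloff_scale see [expand_landmarks()], [assign_vertices()].
#' @return as [segmented_procrustes()], plus `initial` (the whole-model
#'   alignment result).
#' @export
morph_to_target <- function(mesh, lms3d, lms2d, deps, spacing = NULL,
                            falloff_scale = NULL, hard = FALSE) {
  ini <- initial_align(mesh, lms3d, lms2d)
  tmp <- expand_landmarks(ini$landmarks, deps, spacing)
  asg <- assign_vertices(ini$mesh, tmp, deps, falloff_scale,
                         lms = ini$landmarks)
  res <- segmented_procrustes(ini$mesh, ini$landmarks, lms2d, deps, asg,
                              hard = hard)
  res$initial <- ini
  res
}
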