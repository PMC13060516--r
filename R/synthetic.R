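#' Specification for a synthetic articulated hand
#'
#' Describes a toy right hand built as an extruded silhouette: a palm plate
#' with four fingers on its distal edge and a tilted thumb, each digit a
#' chain of tapered segments with a rounded tip. The silhouette boundary is
#' gently curved everywhere (taper plus a sinusoidal bulge) so its
#' triangulation is well conditioned, and the extrusion yields a closed
#' genus-0 manifold. All lengths are dimensionless model units.
#'
#' @param finger_lengths list of per-digit segment lengths, proximal to
#'   distal; digits in order thumb, index, middle, ring, pinky. The thumb
#'   has two segments (MCP-IP, IP-tip), fingers three.
#' @param radius per-digit half-width at the base.
#' @param palm_width,palm_height,thickness palm plate dimensions.
#' @param resolution boundary subdivisions per segment edge (>= 2; at least
#'   8 faces per segment).
#' @param thumb_angle_deg tilt of the thumb from the finger direction.
#' @param seed integer; generators are pure functions of (spec, seed).
#' @return object of class `hand_spec`.
#' @export
hand_spec <- function(finger_lengths = list(T = c(0.45, 0.40),
                                            I = c(0.50, 0.32, 0.28),
                                            M = c(0.55, 0.36, 0.30),
                                            R = c(0.50, 0.33, 0.28),
                                            P = c(0.38, 0.26, 0.24)),
                      radius = c(T = 0.13, I = 0.10, M = 0.10, R = 0.09,
                                 P = 0.085),
                      palm_width = 1.3, palm_height = 1.0, thickness = 0.25,
                      resolution = 3L, thumb_angle_deg = 35, seed = 1L) {
  if (any(unlist(finger_lengths) <= 0) || any(radius <= 0) ||
      palm_width <= 0 || palm_height <= 0 || thickness <= 0)
    stop("all lengths and radii must be positive")
  if (resolution < 2L)
    stop("resolution too low to place width markers (need >= 2)")
  structure(list(finger_lengths = finger_lengths, radius = radius,
                 palm_width = palm_width, palm_height = palm_height,
                 thickness = thickness, resolution = as.integer(resolution),
                 thumb_angle_deg = thumb_angle_deg, seed = as.integer(seed)),
            class = "hand_spec")
}

# arc-chain helpers: points along a segment with a perpendicular sinusoidal
# bulge, so no three consecutive boundary points are collinear
arc_chain <- function(a, b, n, bulge) {
  t <- seq(0, 1, length.out = n + 1)[-1]  # excludes a, includes b
  d <- b - a
  perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
  sapply(seq_along(t), function(k)
    a + t[k] * d + bulge * sin(pi * t[k]) * perp)
}

#' Generate a synthetic hand mesh with landmarks and dependencies
#'
#' Builds the closed extruded-silhouette mesh, the canonical 54-landmark set
#' (22 primary + 32 accessory, anchor `"wrist"`) and the anatomical
#' dependency list (wrist to MCP to PIP to DIP to tip per digit; palm centers
#' as direct children of the wrist). Digit landmark names are the digit
#' initial (`T I M R P`) plus the joint slot (`mcp`, `pip`, `dip`, `tip`);
#' the thumb's single interphalangeal joint occupies the `dip` slot (`Tdip`)
#' so suffix conventions stay uniform. Width markers `<base>_t` / `<base>_p`
#' sit on the silhouette edge halfway along the segment that ends at
#' `<base>`.
#'
#' @param spec a [hand_spec].
#' @return list with `mesh` ([trimesh]), `landmarks` ([landmark_set]) and
#'   `deps` ([dependency_list]).
#' @export
make_hand <- function(spec = hand_spec()) {
  W <- spec$palm_width; H <- spec$palm_height; th <- spec$thickness
  res <- spec$resolution
  digits <- c("T", "I", "M", "R", "P")
  r <- spec$radius
  # digit base x positions on the distal palm edge (thumb leftmost)
  xb <- setNames(c(0.14, 0.38, 0.57, 0.75, 0.92) * W, digits)
  ang <- c(T = -spec$thumb_angle_deg * pi / 180, I = 0, M = 0, R = 0, P = 0)
  lm_names <- character(); lm_roles <- character(); lm_pos <- list()
  add_lm <- function(name, role, p) {
    lm_names <<- c(lm_names, name); lm_roles <<- c(lm_roles, role)
    lm_pos[[length(lm_pos) + 1L]] <<- if (length(p) == 2) c(p, 0) else p
  }
  # outline built clockwise when viewed from +z, starting at the wrist-thumb
  # junction (0, 0): up the thumb-side palm edge, across the distal edge
  # traversing each digit, down the pinky-side edge, back along the wrist
  # edge; reversed to counter-clockwise at the end. Every chain carries a
  # small perpendicular bulge so no three boundary points are collinear.
  outline <- matrix(c(0, 0), 1, 2)
  add_pts <- function(m) outline <<- rbind(outline, t(m))
  bulge_out <- 0.008 * W
  digit_outline <- function(d) {
    # up the thumb side of the digit, around the rounded tip, down the other
    dir <- c(sin(ang[[d]]), cos(ang[[d]]))
    perp <- c(-dir[2], dir[1])  # left of dir = thumb side for the fingers
    lens <- spec$finger_lengths[[d]]
    cum <- cumsum(lens); L <- sum(lens)
    base <- c(xb[[d]], H)
    taper <- function(s) r[[d]] * (1 - 0.25 * s / L)  # half-width at arclength s
    hb <- r[[d]] / cos(ang[[d]])          # base half-span along the palm edge
    joint <- function(s) base + s * dir
    s0 <- 0
    for (s1 in cum) {   # per segment so joints subdivide the chain
      a <- if (s0 == 0) base - c(hb, 0) else joint(s0) + taper(s0) * perp
      add_pts(arc_chain(a, joint(s1) + taper(s1) * perp, res, bulge_out))
      s0 <- s1
    }
    # rounded tip arc, +perp side around to -perp side
    tipc <- joint(L); rt <- taper(L)
    thetas <- seq(0, pi, length.out = 2 * res + 1)[-1]
    add_pts(sapply(thetas, function(t_)
      tipc + rt * cos(t_) * perp + rt * sin(t_) * dir))
    s0 <- L
    for (s1 in c(rev(cum[-length(cum)]), 0)) {
      b <- if (s1 == 0) base + c(hb, 0) else joint(s1) - taper(s1) * perp
      add_pts(arc_chain(joint(s0) - taper(s0) * perp, b, res, bulge_out))
      s0 <- s1
    }
    # landmarks for this digit
    slots <- if (length(lens) == 2) c("dip", "tip") else c("pip", "dip", "tip")
    add_lm(paste0(d, "mcp"), "primary", joint(0))
    prev <- 0
    for (k in seq_along(cum)) {
      nm <- paste0(d, slots[k])
      add_lm(nm, "primary", joint(cum[k]))
      mid <- (prev + cum[k]) / 2
      add_lm(paste0(nm, "_t"), "accessory", joint(mid) + taper(mid) * perp)
      add_lm(paste0(nm, "_p"), "accessory", joint(mid) - taper(mid) * perp)
      prev <- cum[k]
    }
  }
  gap_n <- max(2L, res %/% 2L)
  first_base <- xb[["T"]] - r[["T"]] / cos(ang[["T"]])
  if (first_base <= 0) stop("thumb overlaps the palm edge; widen the palm")
  add_pts(arc_chain(c(0, 0), c(0, H), res + 1, bulge_out))        # thumb-side edge
  add_pts(arc_chain(c(0, H), c(first_base, H), gap_n, -0.5 * bulge_out))
  for (i in seq_along(digits)) {
    d <- digits[i]
    digit_outline(d)
    here <- xb[[d]] + r[[d]] / cos(ang[[d]])
    to <- if (i < 5) c(xb[[digits[i + 1]]] - r[[digits[i + 1]]], H) else c(W, H)
    if (to[1] <= here) stop("digits overlap on the palm edge; widen the palm")
    add_pts(arc_chain(c(here, H), to, gap_n, -0.5 * bulge_out))
  }
  add_pts(arc_chain(c(W, H), c(W, 0), res + 1, bulge_out))        # pinky-side edge
  add_pts(arc_chain(c(W, 0), c(0, 0), res + 1, bulge_out))        # wrist edge
  outline <- dedupe_ring(outline)
  outline <- outline[rev(seq_len(nrow(outline))), , drop = FALSE]  # to CCW
  tris <- ear_clip(outline)
  mesh <- extrude_polygon(outline, tris, th)
  # non-digit landmarks
  add_lm("wrist", "primary", c(W / 2, 0))
  add_lm("wrist_t", "accessory", c(0, 0))
  add_lm("wrist_p", "accessory", c(W, 0))
  add_lm("palm", "primary", c(W / 2, H / 2, th / 2))
  add_lm("palmd", "primary", c(W / 2, H / 2, -th / 2))
  add_lm("palm_t", "accessory", c(0, H / 2))
  add_lm("palm_p", "accessory", c(W, H / 2))
  lms <- landmark_set(lm_names, lm_roles, do.call(rbind, lm_pos), "wrist")
  pairs <- list(c("wrist", "palm"), c("wrist", "palmd"))
  for (d in digits) {
    chain <- if (d == "T") c("mcp", "dip", "tip") else
      c("mcp", "pip", "dip", "tip")
    prev <- "wrist"
    for (s in chain) {
      pairs[[length(pairs) + 1L]] <- c(prev, paste0(d, s))
      prev <- paste0(d, s)
    }
  }
  list(mesh = mesh, landmarks = lms,
       deps = dependency_list("wrist", pairs))
}

dedupe_ring <- function(p, tol = 1e-9) {
  keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2) > tol^2)
  p <- p[keep, , drop = FALSE]
  if (sum((p[1, ] - p[nrow(p), ])^2) <= tol^2) p <- p[-nrow(p), , drop = FALSE]
  p
}

# O(n^2) ear clipping of a simple CCW polygon; returns index triples
ear_clip <- function(p) {
  if (polygon_area(p) < 0) stop("outline must be counter-clockwise")
  idx <- seq_len(nrow(p))
  tris <- list()
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    found <- FALSE
    for (k in seq_len(n)) {
      i0 <- idx[if (k == 1) n else k - 1]; i1 <- idx[k]
      i2 <- idx[if (k == n) 1 else k + 1]
      a <- p[i0, ]; b <- p[i1, ]; c_ <- p[i2, ]
      cr <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
      if (cr <= 1e-14) next  # reflex or degenerate corner
      others <- idx[!(idx %in% c(i0, i1, i2))]
      if (length(others)) {
        inside <- points_in_triangle(p[others, , drop = FALSE],
                                     rbind(a, b, c_), eps = -1e-14)
        if (any(inside)) next
      }
      tris[[length(tris) + 1L]] <- c(i0, i1, i2)
      idx <- idx[-k]
      found <- TRUE
      break
    }
    if (!found) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear clipping failed; outline may self-intersect")
      # numerical fallback: relax the strictness once
      tris[[length(tris) + 1L]] <- idx[1:3]
      idx <- idx[-2]
    }
  }
  tris[[length(tris) + 1L]] <- idx
  do.call(rbind, tris)
}

# extrude a CCW polygon (with triangulation) into a closed solid of given
# thickness, centered on z = 0
extrude_polygon <- function(outline, tris, thickness) {
  n <- nrow(outline)
  h <- thickness / 2
  verts <- rbind(cbind(outline, h), cbind(outline, -h))  # top then bottom
  top <- tris                                  # CCW from +z: outward
  bottom <- tris[, c(1, 3, 2), drop = FALSE] + n
  sides <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ti <- i; tj <- j; bi <- i + n; bj <- j + n
    sides[[length(sides) + 1L]] <- c(ti, bj, tj)
    sides[[length(sides) + 1L]] <- c(ti, bi, bj)
  }
  trimesh(verts, rbind(top, bottom, do.call(rbind, sides)))
}

#' Build a deformed planar reference landmark set
#'
#' Stands in for the landmark annotations of a palmar/dorsal 2D reference
#' illustration: the landmarks are flattened to z = 0 and each segment is
#' perturbed by a similarity (in-plane rotation about the parent joint plus a
#' scale), applied hierarchically down the dependency tree so distal segments
#' inherit their ancestors' motion. The applied parameters are returned for
#' recovery tests.
#'
#' @param lms a [landmark_set] (3D).
#' @param deps the [dependency_list].
#' @param deformation data frame with columns `segment`, `angle_deg`,
#'   `scale`; `NULL` draws one per digit segment (uniform on +/- 6 degrees,
#'   scale 0.95-1.05; palm and MCP segments are left rigid) from `seed`.
#' @param seed integer seed for the default draw.
#' @param flatten project the landmarks to z = 0 (a 2D illustration target);
#'   `FALSE` keeps the 3D configuration and applies only the per-segment
#'   similarities, giving an exactly consistent articulated 3D target.
#' @return list with `landmarks` (planar [landmark_set], all z = 0 when
#'   `flatten`) and `deformation` (the parameter record).
#' @export
make_2d_reference <- function(lms, deps, deformation = NULL, seed = 1L,
                              flatten = TRUE) {
  segs <- deps$pairs[, 2]
  if (is.null(deformation)) {
    rigid <- segs %in% c("palm", "palmd") | grepl("mcp$", segs)
    set.seed(as.integer(seed))
    deformation <- data.frame(
      segment = segs,
      angle_deg = ifelse(rigid, 0, stats::runif(length(segs), -6, 6)),
      scale = ifelse(rigid, 1, stats::runif(length(segs), 0.95, 1.05)))
  }
  if (!all(is.finite(deformation$angle_deg)) ||
      !all(is.finite(deformation$scale)))
    stop("deformation parameters must be finite")
  pos <- lms$positions
  if (flatten) pos[, 3] <- 0
  # subtree membership: primary landmarks under each segment's child
  children_of <- split(deps$pairs[, 2], deps$pairs[, 1])
  subtree <- function(root) {
    out <- root; queue <- root
    while (length(queue)) {
      nxt <- unlist(children_of[queue], use.names = FALSE)
      out <- c(out, nxt); queue <- nxt
    }
    out
  }
  for (i in seq_len(nrow(deps$pairs))) {
    ch <- deps$pairs[i, 2]
    row <- match(ch, deformation$segment)
    a <- deformation$angle_deg[row] * pi / 180
    s <- deformation$scale[row]
    if (abs(a) < 1e-15 && abs(s - 1) < 1e-15) next
    center <- pos[match(deps$pairs[i, 1], lms$names), 1:2]
    members <- subtree(ch)
    sel <- which(lms$names %in% members |
                   (lms$roles == "accessory" &
                      landmark_base(lms$names) %in% members))
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    rel <- sweep(pos[sel, 1:2, drop = FALSE], 2, center)
    pos[sel, 1:2] <- sweep(s * rel %*% t(R), 2, center, `+`)
  }
  list(landmarks = with_positions(lms, pos), deformation = deformation)
}

#' Paint a connected patch annotation around a face
#'
#' Collects the faces whose breadth-first geodesic approximation (shortest
#' path over the face-adjacency graph, weighted by centroid-to-centroid
#' distance) from the center face is at most `radius`; always includes the
#' center face, and is connected by construction. A hotspot is placed at the
#' center face's centroid. Scale ratings are drawn uniformly from `seed`.
#'
#' @param mesh a [trimesh].
#' @param center_face face index of the patch center.
#' @param radius geodesic radius in model units.
#' @param seed integer seed for the scale ratings.
#' @param mesh_id identifier recorded on the field.
#' @return a [projected_field].
#' @export
make_patch_field <- function(mesh, center_face, radius, seed = 1L,
                             mesh_id = "mesh") {
  nf <- nrow(mesh$faces)
  if (center_face < 1 || center_face > nf) stop("invalid center face")
  if (radius < 0) stop("radius must be nonnegative")
  ctr <- face_centroids(mesh)
  adj <- face_adjacency(mesh)
  dist <- rep(Inf, nf)
  dist[center_face] <- 0
  # Dijkstra over the face graph
  done <- rep(FALSE, nf)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || !is.finite(dist[u]) || dist[u] > radius) break
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (done[v]) next
      w <- dist[u] + sqrt(sum((ctr[v, ] - ctr[u, ])^2))
      if (w < dist[v]) dist[v] <- w
    }
    if (all(done | !is.finite(dist))) break
  }
  faces <- which(dist <= radius)
  set.seed(as.integer(seed))
  projected_field(mesh_id = mesh_id, faces = faces,
                  hotspots = ctr[center_face, , drop = FALSE],
                  naturalness = stats::runif(1), pain = stats::runif(1),
                  overall_intensity = stats::runif(1))
}

# faces sharing an (undirected) edge
face_adjacency <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), 3L)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  by_edge <- split(fid, key)
  adj <- vector("list", nf)
  for (fs in by_edge) {
    if (length(fs) < 2) next
    for (a in fs) adj[[a]] <- c(adj[[a]], setdiff(fs, a))
  }
  lapply(adj, unique)
}
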