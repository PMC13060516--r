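# programmatic fixtures shared across tests

# a unit cube (12 triangles, outward winding), centered at the origin
make_cube <- function(half = 0.5) {
  v <- as.matrix(expand.grid(x = c(-half, half), y = c(-half, half),
                             z = c(-half, half)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  trimesh(v, f)
}

# UV sphere about the z axis
make_uv_sphere <- function(n_theta = 20, n_phi = 40, radius = 1) {
  thetas <- seq(0, pi, length.out = n_theta + 1)
  ring_ids <- list()
  verts <- matrix(numeric(0), 0, 3)
  for (i in seq_along(thetas)) {
    th <- thetas[i]
    if (i == 1 || i == length(thetas)) {
      verts <- rbind(verts, radius * c(0, 0, cos(th)))
      ring_ids[[i]] <- rep(nrow(verts), n_phi + 1)
    } else {
      phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
      ring <- radius * cbind(sin(th) * cos(phis), sin(th) * sin(phis),
                             rep(cos(th), n_phi))
      verts <- rbind(verts, ring)
      ring_ids[[i]] <- c(nrow(verts) - n_phi + seq_len(n_phi),
                         nrow(verts) - n_phi + 1)
    }
  }
  faces <- list()
  for (i in seq_len(n_theta)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    for (j in seq_len(n_phi)) {
      if (a[j] != a[j + 1])
        faces[[length(faces) + 1]] <- c(a[j], b[j], a[j + 1])
      if (b[j] != b[j + 1])
        faces[[length(faces) + 1]] <- c(a[j + 1], b[j], b[j + 1])
    }
  }
  trimesh(verts, do.call(rbind, faces))
}

# open cylinder lateral surface, axis along x, radius 1
make_cylinder <- function(n_x = 50, n_phi = 100, len = 4) {
  xs <- seq(0, len, length.out = n_x + 1)
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- as.matrix(expand.grid(phi = phis, x = xs))
  verts <- cbind(verts[, 2], cos(verts[, 1]), sin(verts[, 1]))
  id <- function(ix, ip) (ix - 1) * n_phi + ((ip - 1) %% n_phi) + 1
  faces <- list()
  for (ix in seq_len(n_x)) for (ip in seq_len(n_phi)) {
    faces[[length(faces) + 1]] <- c(id(ix, ip), id(ix + 1, ip), id(ix, ip + 1))
    faces[[length(faces) + 1]] <- c(id(ix, ip + 1), id(ix + 1, ip),
                                    id(ix + 1, ip + 1))
  }
  trimesh(verts, do.call(rbind, faces))
}

# flat rectangular grid mesh in the z = 0 plane tiling [0,w] x [0,h]
make_grid_mesh <- function(nx = 4, ny = 4, w = 1, h = 1, z = 0) {
  g <- as.matrix(expand.grid(x = seq(0, w, length.out = nx + 1),
                             y = seq(0, h, length.out = ny + 1)))
  verts <- cbind(g, z)
  id <- function(i, j) (j - 1) * (nx + 1) + i
  faces <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
    faces[[length(faces) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  trimesh(verts, do.call(rbind, faces))
}

# midpoint (1-to-4) subdivision, preserving winding
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mids <- new.env()
  midpoint <- function(a, b) {
    k <- edge_key(a, b)
    if (!is.null(mids[[k]])) return(mids[[k]])
    v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
    mids[[k]] <- nrow(v)
    nrow(v)
  }
  out <- list()
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
    out[[length(out) + 1]] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                    c(ca, bc, c_), c(ab, bc, ca))
  }
  trimesh(v, do.call(rbind, out))
}

# random rotation matrix (uniform via QR of gaussian)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# cached default synthetic hand (built once per test run)
default_hand <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_hand()
    cache
  }
})

rms_dist <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
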