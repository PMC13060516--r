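test_that("face partition classifies by normal angle with a 90-degree tie-break", {
  tilt <- function(deg) {
    # one triangle whose normal is `deg` degrees from +z (rotation about y)
    a <- deg * pi / 180
    R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
    trimesh(tcrossprod(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), R),
            rbind(1:3))
  }
  p0 <- partition_faces(tilt(0))
  expect_equal(p0$aspect, "palmar"); expect_false(p0$oblique)
  expect_equal(p0$angle_from_depth, 0, tolerance = 1e-9)
  p75 <- partition_faces(tilt(75))
  expect_equal(p75$aspect, "palmar"); expect_true(p75$oblique)
  p90 <- partition_faces(tilt(90))
  expect_equal(p90$aspect, "dorsal"); expect_true(p90$oblique)  # tie: dorsal
  p180 <- partition_faces(tilt(180))
  expect_equal(p180$aspect, "dorsal"); expect_false(p180$oblique)
  p61 <- partition_faces(tilt(61))
  expect_true(p61$oblique)
  expect_false(partition_faces(tilt(59.9))$oblique)
  expect_error(partition_faces(tilt(0), c(0, 0, 0)), "nonzero")
})

test_that("partition is invariant to rotation about the depth vector", {
  h <- default_hand()$mesh
  p0 <- partition_faces(h)
  for (a in c(0.3, 1.2, 2.5)) {
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    m <- trimesh(tcrossprod(h$vertices, R), h$faces)
    p <- partition_faces(m)
    expect_identical(p$aspect, p0$aspect)
    expect_identical(p$oblique, p0$oblique)
    expect_equal(p$angle_from_depth, p0$angle_from_depth, tolerance = 1e-6)
  }
})

test_that("aspect splitting conserves faces and halves a sphere evenly", {
  sph <- make_uv_sphere(50, 100)  # 10k faces
  part <- partition_faces(sph)
  halves <- split_aspect_meshes(sph, part)
  a_p <- sum(face_areas(halves$palmar$mesh))
  a_d <- sum(face_areas(halves$dorsal$mesh))
  expect_lt(abs(a_p - a_d) / (a_p + a_d), 0.01)
  expect_equal(nrow(halves$palmar$mesh$faces) + nrow(halves$dorsal$mesh$faces),
               nrow(sph$faces))
  # index maps invert to the source mesh
  fm <- halves$palmar$face_map
  expect_equal(face_areas(halves$palmar$mesh), face_areas(sph)[fm])
  # all-palmar mesh: empty dorsal half
  flat <- make_grid_mesh(2, 2)
  sp <- split_aspect_meshes(flat, partition_faces(flat))
  expect_null(sp$dorsal)
  expect_equal(nrow(sp$palmar$mesh$faces), nrow(flat$faces))
})

test_that("flattening zeroes the depth component and is idempotent", {
  h <- default_hand()$mesh
  f1 <- flatten_mesh(h)
  expect_true(all(f1$vertices[, 3] == 0))
  expect_equal(f1$vertices[, 1:2], h$vertices[, 1:2])
  expect_equal(flatten_mesh(f1)$vertices, f1$vertices)
  # in-plane distances of a fronto-parallel face unchanged
  tri <- trimesh(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2)), rbind(1:3))
  ft <- flatten_mesh(tri)
  tv <- tri$vertices; tv[, 3] <- 0
  expect_equal(as.numeric(dist(ft$vertices)), as.numeric(dist(tv)))
})

test_that("rasterization matches an exhaustive pixel-center oracle", {
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  mesh <- trimesh(cbind(rbind(tri, c(10, 10)), 0),
                  rbind(c(1, 2, 3), c(2, 4, 3)))
  grid <- pixel_mask(10, 10, origin = c(0, 0), pixel_size = 1)
  m <- rasterize(mesh, 1L, grid)
  # brute force: half-integer centers inside (or on the edge of) the triangle
  oracle <- 0L
  for (cx in seq(0.5, 9.5)) for (cy in seq(0.5, 9.5)) {
    if (cx + cy <= 10 + 1e-12 && cx >= -1e-12 && cy >= -1e-12)
      oracle <- oracle + 1L
  }
  expect_equal(sum(m$values), oracle)
  # no annotation -> empty; covering triangle -> full
  expect_equal(sum(rasterize(mesh, integer(0), grid)$values), 0L)
  big <- trimesh(cbind(rbind(c(-50, -50), c(100, -50), c(-50, 100)), 0),
                 rbind(1:3))
  expect_equal(sum(rasterize(big, 1L, grid)$values), 100L)
  expect_error(pixel_mask(10, 10, pixel_size = 0), "positive")
})

test_that("rasterized area converges to the projected patch area", {
  # convex quadrilateral patch spanning two faces, ~500 pixels across
  mesh <- trimesh(cbind(rbind(c(0.05, 0.1), c(0.92, 0.07), c(0.9, 0.95),
                              c(0.1, 0.9)), 0),
                  rbind(c(1, 2, 3), c(1, 3, 4)))
  true_area <- sum(face_areas(mesh))
  grid <- pixel_mask(500, 500, origin = c(0, 0), pixel_size = 1 / 500)
  m <- rasterize(mesh, 1:2, grid)
  got <- sum(m$values) * (1 / 500)^2
  expect_lt(abs(got - true_area) / true_area, 0.02)
})

test_that("jaccard satisfies its axioms and the worked pixel-count case", {
  g <- function(vals) pixel_mask(10, 10, values = vals)
  v <- matrix(0L, 10, 10)
  a <- v; a[1:6, 1:10] <- 1L          # |a| = 60
  b <- v; b[4:9, 1:10] <- 1L          # |b| = 60, overlap rows 4:6 = 30
  expect_equal(jaccard(g(a), g(b)), 30 / 90)
  expect_equal(jaccard(g(a), g(a)), 1)
  d <- v; d[7:10, 1:10] <- 1L
  expect_equal(jaccard(g(a), g(d)), 0)
  expect_equal(jaccard(g(a), g(b)), jaccard(g(b), g(a)))
  expect_equal(jaccard(g(v), g(v)), 0)  # empty-vs-empty convention
  # adjacency bound J <= min|.|/max|.|
  set.seed(1)
  for (i in 1:25) {
    x <- matrix(rbinom(100, 1, 0.4), 10, 10)
    y <- matrix(rbinom(100, 1, 0.6), 10, 10)
    expect_lte(jaccard(g(x), g(y)),
               min(sum(x), sum(y)) / max(sum(x), sum(y)) + 1e-12)
  }
  expect_error(jaccard(g(a), pixel_mask(5, 5)), "different grids")
})

test_that("mask PNG round-trip preserves the grid and its mapping", {
  set.seed(2)
  m <- pixel_mask(12, 7, origin = c(-1, 2), pixel_size = 0.25,
                  values = matrix(rbinom(84, 1, 0.5), 7, 12))
  p <- withr::local_tempfile(fileext = ".png")
  save_mask(m, p)
  m2 <- load_mask(p)
  expect_identical(m2$values, m$values)
  expect_equal(m2$origin, m$origin)
  expect_equal(m2$pixel_size, m$pixel_size)
})

test_that("obliqueness equals the oblique fraction of annotated area", {
  # fronto-parallel annotation: 0; steeply tilted plane: 1
  flat <- make_grid_mesh(3, 3)
  part <- partition_faces(flat)
  areas <- face_areas(flat)
  f <- projected_field("m", 1:4)
  expect_equal(obliqueness(f, part, areas), 0)
  a <- 80 * pi / 180
  R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  tilted <- trimesh(tcrossprod(flat$vertices, R), flat$faces)
  expect_equal(obliqueness(f, partition_faces(tilted), face_areas(tilted)), 1)
  expect_error(obliqueness(projected_field("m", integer(0)), part, areas),
               "empty")
  # cylinder lateral surface, axis perpendicular to the depth vector:
  # oblique band is 120 of 360 azimuthal degrees -> 1/3 (n_phi chosen so
  # facet columns do not straddle the 60/120-degree band boundaries)
  cyl <- make_cylinder(n_x = 9, n_phi = 600)   # 10,800 faces
  all_faces <- projected_field("cyl", seq_len(nrow(cyl$faces)))
  obl <- obliqueness(all_faces, partition_faces(cyl), face_areas(cyl))
  expect_lt(abs(obl - 1 / 3), 0.01 / 3)
})

test_that("obliqueness is invariant to uniform refinement", {
  base <- make_cylinder(n_x = 4, n_phi = 16)
  f0 <- projected_field("c", seq_len(nrow(base$faces)))
  o0 <- obliqueness(f0, partition_faces(base), face_areas(base))
  fine <- subdivide_mesh(base)
  f1 <- projected_field("c", seq_len(nrow(fine$faces)))
  o1 <- obliqueness(f1, partition_faces(fine), face_areas(fine))
  expect_equal(o1, o0, tolerance = 1e-9)
})
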