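test_that("procrustes recovers a constructed similarity exactly", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # +90 deg about z
  Y <- sweep(2 * tcrossprod(X, Rz), 2, c(1, 0, 0), `+`)
  tf <- procrustes(X, Y)
  expect_equal(tf$scale, 2, tolerance = 1e-9)
  expect_equal(tf$rotation, Rz, tolerance = 1e-9)
  expect_equal(tf$translation, c(1, 0, 0), tolerance = 1e-9)
  expect_lt(procrustes_rms(tf, X, Y), 1e-9)

  idtf <- procrustes(X, X)
  expect_equal(idtf$scale, 1, tolerance = 1e-12)
  expect_equal(idtf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idtf$translation, rep(0, 3), tolerance = 1e-12)
})

test_that("procrustes rejects degenerate configurations", {
  expect_error(procrustes(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "fewer than 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(procrustes(line, line + 1), "collinear")
})

test_that("reflection handling: excluded fits stay proper rotations", {
  set.seed(7)
  for (i in 1:1000) {
    X <- matrix(rnorm(15), 5, 3)
    Y <- matrix(rnorm(15), 5, 3)
    tf <- procrustes(X, Y, allow_reflection = FALSE)
    expect_gt(det(tf$rotation), 0)
    expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-9)
  }
  # mirrored target: best proper fit has positive residual, reflection
  # allowed recovers it exactly
  X <- matrix(rnorm(30), 10, 3)
  Y <- X %*% diag(c(-1, 1, 1))
  tf_no <- procrustes(X, Y, allow_reflection = FALSE)
  expect_gt(det(tf_no$rotation), 0)
  expect_gt(procrustes_rms(tf_no, X, Y), 1e-6)
  tf_yes <- procrustes(X, Y, allow_reflection = TRUE)
  expect_lt(procrustes_rms(tf_yes, X, Y), 1e-9)
  expect_lt(det(tf_yes$rotation), 0)
})

test_that("procrustes residual is invariant to joint pre-rotation", {
  set.seed(11)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(24), 8, 3)
  r0 <- procrustes_rms(procrustes(X, Y), X, Y)
  for (i in 1:20) {
    Q <- random_rotation()
    XQ <- tcrossprod(X, Q); YQ <- tcrossprod(Y, Q)
    expect_equal(procrustes_rms(procrustes(XQ, YQ), XQ, YQ), r0,
                 tolerance = 1e-9)
  }
})

test_that("initial alignment pins the anchors together and improves fit", {
  h <- default_hand()
  # identical sets: mesh unchanged
  res <- initial_align(h$mesh, h$landmarks, h$landmarks)
  expect_equal(res$mesh$vertices, h$mesh$vertices, tolerance = 1e-9)

  ref <- make_2d_reference(h$landmarks, h$deps, seed = 5)
  res <- initial_align(h$mesh, h$landmarks, ref$landmarks)
  a3 <- landmark_positions(res$landmarks, "wrist")
  a2 <- landmark_positions(ref$landmarks, "wrist")
  expect_lt(sqrt(sum((a3 - a2)^2)), 1e-12)
  tgt <- landmark_positions(ref$landmarks, h$landmarks$names)
  expect_lt(rms_dist(res$landmarks$positions, tgt),
            rms_dist(h$landmarks$positions, tgt))

  bad <- h$landmarks
  bad$names[1] <- "zzz"
  expect_error(initial_align(h$mesh, bad, ref$landmarks), "names")
})

test_that("landmark expansion interpolates at the requested spacing", {
  lms <- landmark_set(c("a", "b", "c"), rep("primary", 3),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(2, 3, 0)), "a")
  deps <- dependency_list("a", list(c("a", "b"), c("b", "c")))
  tmp <- expand_landmarks(lms, deps, spacing = 1)
  added <- tmp[-(1:3), ]  # originals retained first
  expect_equal(nrow(added), (2 - 1) + (3 - 1))  # ceil(len/spacing) - 1 each
  expect_equal(unname(as.matrix(added[added$segment == "b", c("x", "y", "z")])),
               rbind(c(1, 0, 0)))
  # spacing >= segment length: no interior points
  tmp2 <- expand_landmarks(lms, deps, spacing = 10)
  expect_equal(nrow(tmp2), 3L)
  # count oracle over random configurations
  set.seed(3)
  for (i in 1:10) {
    P <- matrix(runif(9, -2, 2), 3, 3)
    lr <- landmark_set(c("a", "b", "c"), rep("primary", 3), P, "a")
    sp <- runif(1, 0.1, 1)
    lens <- c(sqrt(sum((P[2, ] - P[1, ])^2)), sqrt(sum((P[3, ] - P[2, ])^2)))
    tmpR <- expand_landmarks(lr, deps, spacing = sp)
    expect_equal(nrow(tmpR) - 3L, sum(ceiling(lens / sp) - 1))
  }
})

test_that("vertex assignment weights are a normalized exponential falloff", {
  # root r at the origin with two symmetric child segments a (left), b (right)
  lms <- landmark_set(c("r", "a", "b"), rep("primary", 3),
                      rbind(c(0, 0, 0), c(-2, 0, 0), c(2, 0, 0)), "r")
  deps <- dependency_list("r", list(c("r", "a"), c("r", "b")))
  mesh <- make_grid_mesh(8, 1, w = 4, h = 0.2)
  mesh$vertices[, 1] <- mesh$vertices[, 1] - 2  # x in [-2, 2], step 0.5
  tmp <- expand_landmarks(lms, deps, spacing = 1)
  asg <- assign_vertices(mesh, tmp, deps, falloff_scale = 0.15)
  expect_equal(rowSums(asg$weights), rep(1, nrow(mesh$vertices)))
  expect_true(all(asg$weights >= 0))
  # vertex on the root landmark, other segments' landmarks 1 unit away
  # (~ 6.7 falloff scales): weight ~ 1 on the root segment
  i0 <- which(rowSums(abs(sweep(mesh$vertices, 2, c(0, 0, 0)))) < 1e-9)
  expect_gt(asg$weights[i0, 1], 0.99)
  # two-segment toy: vertex exactly equidistant from the two linked
  # segments' nearest temporary landmarks splits 0.5 / 0.5
  lms2 <- landmark_set(c("a", "b"), c("primary", "primary"),
                       rbind(c(0, 0, 0), c(3, 0, 0)), "a")
  deps2 <- dependency_list("a", list(c("a", "b")))
  mesh2 <- make_grid_mesh(6, 1, w = 3, h = 0.2)
  tmp2 <- expand_landmarks(lms2, deps2, spacing = 1)
  asg2 <- assign_vertices(mesh2, tmp2, deps2, falloff_scale = 0.15)
  im <- which(rowSums(abs(sweep(mesh2$vertices, 2, c(0.5, 0, 0)))) < 1e-9)
  expect_equal(asg2$weights[im, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("segmented procrustes is exact on a single-segment toy", {
  # bar mesh with two primary landmarks and width markers; target = similarity
  mesh <- make_grid_mesh(6, 2, w = 3, h = 1)
  lms <- landmark_set(c("a", "b", "b_t", "b_p"),
                      c("primary", "primary", "accessory", "accessory"),
                      rbind(c(0, 0.5, 0), c(3, 0.5, 0),
                            c(1.5, 1, 0), c(1.5, 0, 0)), "a")
  deps <- dependency_list("a", list(c("a", "b")))
  th <- pi / 5
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s <- 1.3; tr <- c(0.4, -0.2, 0.7)
  tgt <- with_positions(lms, sweep(s * tcrossprod(lms$positions, Rz), 2, tr, `+`))
  tmp <- expand_landmarks(lms, deps, spacing = 0.5)
  asg <- assign_vertices(mesh, tmp, deps, falloff_scale = 0.2)
  res <- segmented_procrustes(mesh, lms, tgt, deps, asg, hard = TRUE)
  expect_equal(landmark_positions(res$landmarks, lms$names),
               tgt$positions, tolerance = 1e-9)
  # vertices fully controlled by segment b move by the same similarity
  moved <- which(asg$primary == 2)
  expect_equal(res$mesh$vertices[moved, ],
               sweep(s * tcrossprod(mesh$vertices[moved, ], Rz), 2, tr, `+`),
               tolerance = 1e-9)
  # identity targets leave the mesh unchanged
  res_id <- segmented_procrustes(mesh, lms, lms, deps, asg)
  expect_equal(res_id$mesh$vertices, mesh$vertices, tolerance = 1e-9)
})

test_that("vertices outside every touched segment never move", {
  mesh <- make_grid_mesh(6, 2, w = 3, h = 1)
  lms <- landmark_set(c("a", "b", "b_t", "b_p"),
                      c("primary", "primary", "accessory", "accessory"),
                      rbind(c(0, 0.5, 0), c(3, 0.5, 0),
                            c(1.5, 1, 0), c(1.5, 0, 0)), "a")
  deps <- dependency_list("a", list(c("a", "b")))
  tmp <- expand_landmarks(lms, deps, spacing = 0.3)
  asg <- assign_vertices(mesh, tmp, deps, falloff_scale = 0.1)
  tgt <- with_positions(lms, sweep(lms$positions, 2, c(0, 0, 2), `+`))
  res <- segmented_procrustes(mesh, lms, tgt, deps, asg, hard = TRUE)
  frozen <- which(asg$primary == 1)  # root segment only
  expect_equal(res$mesh$vertices[frozen, ], mesh$vertices[frozen, ])
})

test_that("the full morph improves landmark fit and recovers known deformations", {
  h <- default_hand()
  # planar illustration target: morph must beat the whole-model alignment
  ref <- make_2d_reference(h$landmarks, h$deps, seed = 5)
  res <- morph_to_target(h$mesh, h$landmarks, ref$landmarks, h$deps)
  tgt <- landmark_positions(ref$landmarks, h$landmarks$names)
  rms_ini <- rms_dist(landmark_positions(res$initial$landmarks,
                                         h$landmarks$names), tgt)
  rms_mor <- rms_dist(landmark_positions(res$landmarks, h$landmarks$names),
                      tgt)
  expect_lt(rms_mor, rms_ini)
  # articulated 3D target with recorded per-segment similarities: recovery
  # within 1% of hand length
  for (seed in c(2, 7, 13)) {
    ref3 <- make_2d_reference(h$landmarks, h$deps, seed = seed,
                              flatten = FALSE)
    res3 <- morph_to_target(h$mesh, h$landmarks, ref3$landmarks, h$deps)
    tgt3 <- landmark_positions(ref3$landmarks, h$landmarks$names)
    got <- landmark_positions(res3$landmarks, h$landmarks$names)
    expect_lt(rms_dist(got, tgt3), 0.01 * hand_length(ref3$landmarks))
  }
})

test_that("dependency lists enforce tree structure and topological order", {
  expect_error(dependency_list("r", list(c("r", "a"), c("r", "a"))),
               "more than once")
  expect_error(dependency_list("r", list(c("a", "b"), c("r", "a"))),
               "topological")
  expect_error(dependency_list("r", list(c("r", "a"), c("b", "r"))), "root")
  d <- dependency_list("r", list(c("r", "a"), c("a", "b")))
  p <- withr::local_tempfile(fileext = ".json")
  save_dependencies(d, p)
  d2 <- load_dependencies(p)
  expect_identical(d2$root, d$root)
  expect_identical(d2$pairs, d$pairs)
})
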