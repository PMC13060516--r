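#' Similarity Procrustes superimposition of matched point sets
#'
#' Least-squares fit of `target ~ scale * R %*% source + translation` over
#' matched point rows, by the standard SVD solution. With
#' `allow_reflection = FALSE` the rotation is constrained to det(R) = +1 by
#' flipping the sign of the smallest singular-value axis; otherwise an
#' improper orthogonal matrix (reflection) is permitted, as in the
#' unrestricted whole-model alignment. With `allow_scale = FALSE` the scale
#' is fixed at 1 (rigid fit).
#'
#' @param source_pts,target_pts N x 3 matrices of matched points (N >= 3,
#'   not all collinear).
#' @param allow_reflection permit det(R) = -1.
#' @param allow_scale fit a uniform scale factor.
#' @return object of class `procrustes_transform`: list with `scale`,
#'   `rotation` (3 x 3), `translation` (length 3), `reflection_allowed`.
#' @export
procrustes <- function(source_pts, target_pts, allow_reflection = FALSE,
                       allow_scale = TRUE) {
  X <- as_coord_matrix(source_pts, "source_pts")
  Y <- as_coord_matrix(target_pts, "target_pts")
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3L) stop("degenerate configuration: fewer than 3 points")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- crossprod(Xc, Yc)  # 3x3 covariance
  sv <- svd(H)
  # rank check on the source configuration (collinear points leave the
  # rotation about the line undetermined)
  sx <- svd(Xc, nu = 0, nv = 0)$d
  if (sx[2] < 1e-9 * max(sx[1], 1e-300))
    stop("degenerate configuration: points are collinear")
  D <- diag(3)
  if (!allow_reflection && det(sv$v %*% t(sv$u)) < 0)
    D[3, 3] <- -1
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * diag(D)) / sum(Xc^2) else 1
  if (s <= 0) stop("non-positive fitted scale")
  t <- my - s * as.vector(R %*% mx)
  structure(list(scale = s, rotation = R, translation = t,
                 reflection_allowed = allow_reflection),
            class = "procrustes_transform")
}

#' @export
print.procrustes_transform <- function(x, ...) {
  cat("procrustes_transform: scale", format(x$scale), "det(R)",
      format(det(x$rotation)), "\n")
  invisible(x)
}

#' Apply a Procrustes transform to points
#'
#' @param tf a `procrustes_transform`.
#' @param pts N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(tf, pts) {
  pts <- as_coord_matrix(pts, "pts")
  sweep(tcrossprod(pts, tf$rotation) * tf$scale, 2, tf$translation, `+`)
}

#' Residual root-mean-square of a fit
#'
#' @inheritParams apply_transform
#' @param target_pts the matched targets.
#' @return scalar RMS distance after transformation.
#' @export
procrustes_rms <- function(tf, pts, target_pts) {
  sqrt(mean(rowSums((apply_transform(tf, pts) - target_pts)^2)))
}
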