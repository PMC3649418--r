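#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation, mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param axis "x", "y", "z" or a length-3 vector.
#' @param angleDeg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  if (is.character(axis)) {
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be 'x', 'y', 'z' or a 3-vector"))
  }
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Rotation angle of a rotation matrix (degrees)
#' @param R 3x3 rotation matrix.
#' @export
rotationAngle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points N x 3 matrix or \linkS4class{PointCloud}.
#' @return object of the same kind with transformed coordinates (normals are
#'   rotated for point clouds).
#' @export
applyTransform <- function(transform, points) {
  if (is(points, "PointCloud")) {
    out <- points
    out@positions <- applyTransform(transform, points@positions)
    if (!is.null(points@normals))
      out@normals <- points@normals %*% t(transform@rotation)
    return(out)
  }
  if (is(points, "TriangleMesh")) {
    out <- points
    out@vertices <- applyTransform(transform, points@vertices)
    return(out)
  }
  sweep(points %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Compose rigid transforms (apply \code{b} first, then \code{a})
#' @param a,b \linkS4class{RigidTransform} objects.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' Best-fit rigid transform between paired point sets (Kabsch/SVD)
#'
#' Least-squares rotation + translation mapping \code{source} onto
#' \code{target}; a reflection in the SVD solution is corrected by flipping
#' the sign of the smallest singular vector.
#'
#' @param source,target N x 3 matrices of corresponding points (N >= 3).
#' @return A \linkS4class{RigidTransform}.
#' @export
fitRigidTransform <- function(source, target) {
  if (nrow(source) < 3L || nrow(target) != nrow(source))
    stop("need >= 3 point pairs")
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  rigidTransform(R, ct - as.numeric(R %*% cs))
}
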