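#' Centroid of a point set
#'
#' Arithmetic mean of an N x 3 coordinate matrix (Angstrom).
#'
#' @param points numeric matrix with 3 columns (x, y, z), N >= 1 rows.
#' @return numeric vector of length 3.
#' @export
centroid <- function(points) {
  points <- as_xyz_matrix(points)
  if (nrow(points) < 1L) stop("centroid: empty point set")
  colMeans(points)
}

#' Least-squares rigid superposition (proper rotations only)
#'
#' Finds the rotation + translation minimizing the RMSD of `moving` onto
#' `reference` over points in 1:1 correspondence (closed-form SVD solution,
#' reflection excluded so chirality is preserved).
#'
#' @param reference,moving N x 3 coordinate matrices, N >= 3, rows in
#'   correspondence.
#' @return a `RigidTransform`: list with `rotation` (3 x 3 proper orthogonal
#'   matrix), `translation` (length-3 vector) and `rmsd` (Angstrom).  The
#'   fitted coordinates are `moving %*% t(rotation) + translation` (row-wise).
#' @export
superpose <- function(reference, moving) {
  reference <- as_xyz_matrix(reference)
  moving <- as_xyz_matrix(moving)
  n <- nrow(reference)
  if (nrow(moving) != n)
    stop("superpose: point sets differ in length")
  if (n < 3L)
    stop("superpose: need at least 3 points")
  cr <- colMeans(reference)
  cm <- colMeans(moving)
  rc <- sweep(reference, 2L, cr)
  mc <- sweep(moving, 2L, cm)
  # degenerate (collinear) sets leave the rotation about the line undetermined
  if (qr(rc)$rank < 2L || qr(mc)$rank < 2L)
    stop("superpose: degenerate (collinear) point set")
  h <- crossprod(mc, rc)            # sum over i of m_i r_i^T
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  tr <- as.numeric(cr - rot %*% cm)
  structure(list(rotation = rot, translation = tr, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `RigidTransform` from [superpose()].
#' @param points N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as_xyz_matrix(points)
  sweep(points %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Signed dihedral (torsion) angle
#'
#' Standard biomolecular torsion convention: looking along the p2 -> p3 bond,
#' a positive angle is a clockwise rotation carrying the p1 half-plane onto
#' the p4 half-plane (equivalently, the sign of the scalar triple product of
#' b1 x b2, b2 x b3 and b2).
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) < 1e-20) stop("dihedral_angle: p2 and p3 coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("dihedral_angle: collinear points around the central bond")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Wrap angles into (-180, 180]
#'
#' @param theta numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  ifelse(w > 180, w - 360, w)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_xyz_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) %% 3 != 0)
      stop("coordinates must be an N x 3 matrix")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an N x 3 matrix")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  storage.mode(x) <- "double"
  x
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat("RigidTransform: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}
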