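#' Elementary rotation matrices
#'
#' Right-handed rotations about the global x, y and z axes. Columns of the
#' returned matrix are the rotated basis vectors, i.e. the matrix maps
#' body-frame coordinates to global coordinates.
#'
#' @param theta rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Test whether a matrix is a proper rotation
#'
#' Checks orthonormality (`t(m) %*% m == I`) and `det(m) == +1` within a
#' tolerance.
#'
#' @param m matrix to test.
#' @param tol numeric tolerance (default `1e-9`).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
    return(FALSE)
  max(abs(crossprod(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

stopifnot_rotation <- function(m, what = "rotation matrix", tol = 1e-6) {
  if (!is_rotation_matrix(m, tol = tol))
    stop(sprintf("%s is not a proper rotation matrix (orthonormal, det +1)", what),
         call. = FALSE)
  invisible(m)
}

#' Project a matrix onto the rotation group
#'
#' Nearest rotation in the Frobenius norm, by the polar decomposition computed
#' from the SVD (with a determinant sign fix so the result is proper).
#'
#' @param m a 3x3 matrix.
#' @param tol smallest admissible singular value; below it the projection is
#'   considered degenerate.
#' @return A 3x3 rotation matrix.
#' @export
project_rotation <- function(m, tol = 1e-8) {
  s <- svd(m)
  if (min(s$d) < tol)
    stop("dispersed orientations: projection onto the rotation group is degenerate",
         call. = FALSE)
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  r
}

#' Chordal mean of a set of rotations
#'
#' The rotation closest in Frobenius norm to the elementwise average of the
#' inputs: the elementwise mean is projected back onto the rotation group by
#' polar decomposition. Order-independent and exact for coaxial rotations
#' (it returns the rotation by the circular mean angle).
#'
#' @param rotations non-empty list of 3x3 rotation matrices, or a 3x3xn array.
#' @return A 3x3 rotation matrix.
#' @export
mean_rotation <- function(rotations) {
  if (is.array(rotations) && length(dim(rotations)) == 3L)
    rotations <- lapply(seq_len(dim(rotations)[3]), function(i) rotations[, , i])
  if (!is.list(rotations) || length(rotations) == 0L)
    stop("'rotations' must be a non-empty list of rotation matrices", call. = FALSE)
  for (r in rotations) stopifnot_rotation(r)
  m <- Reduce(`+`, rotations) / length(rotations)
  project_rotation(m)
}

#' Axis and angle of a rotation
#'
#' @param r a 3x3 rotation matrix.
#' @return List with `axis` (unit 3-vector) and `angle` (radians, in
#'   `[0, pi]`). For the identity the angle is 0 and the axis is undefined
#'   (`c(0, 0, 1)` is returned by convention).
#' @export
rotation_axis_angle <- function(r) {
  stopifnot_rotation(r)
  angle <- acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
  if (angle < 1e-12)
    return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - angle < 1e-6) {
    # near 180 deg the antisymmetric part vanishes; use the symmetric part
    b <- (r + diag(3)) / 2
    axis <- sqrt(pmax(diag(b), 0))
    # fix relative signs from the off-diagonal entries
    k <- which.max(axis)
    sgn <- sign(b[, k]); sgn[sgn == 0] <- 1
    axis <- abs(axis) * sgn * sign(axis[k] * sgn[k])
    axis <- axis / sqrt(sum(axis^2))
    return(list(axis = axis, angle = angle))
  }
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  axis <- v / (2 * sin(angle))
  list(axis = axis / sqrt(sum(axis^2)), angle = angle)
}

#' Angle between two rotations
#'
#' Geodesic distance on the rotation group, in radians.
#'
#' @param a,b 3x3 rotation matrices.
#' @return Angle in radians in `[0, pi]`.
#' @export
rotation_distance <- function(a, b) {
  rotation_axis_angle(t(a) %*% b)$angle
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}
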