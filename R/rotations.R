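#' @title Rotation algebra for body-worn orientation sensors
#'
#' @description
#' All orientations in the package are 3x3 orthonormal rotation matrices with
#' determinant +1.  Quaternions arriving from IMU sensor fusion are converted
#' once at ingestion.  The fixed world frame is: X mediolateral (subject's
#' right positive), Y vertical (up), Z anteroposterior (direction of
#' progression positive).  With that frame the X component of an rxzy Euler
#' decomposition of a joint rotation is the flexion-extension plane, Z the
#' ab/adduction (tilt) plane and Y axial rotation.  Angles are degrees
#' everywhere, lengths centimetres, time seconds.
#'
#' @name rotations
NULL

DEG <- 180 / pi

#' Validate a rotation matrix
#'
#' Checks that `r` is a 3x3 matrix with orthonormal columns and determinant +1
#' (both within `tol`).
#'
#' @param r matrix to check.
#' @param tol numeric tolerance on orthonormality and determinant.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_rotation <- function(r, tol = 1e-9) {
  if (!is.matrix(r) || !all(dim(r) == c(3L, 3L)) || !all(is.finite(r))) {
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(r) - diag(3))) > tol) {
    stop("rotation columns are not orthonormal (tol ", tol, ")", call. = FALSE)
  }
  if (abs(det(r) - 1) > tol) {
    stop("rotation determinant is not +1 (tol ", tol, ")", call. = FALSE)
  }
  invisible(TRUE)
}

is_rotation <- function(r, tol = 1e-6) {
  is.matrix(r) && all(dim(r) == c(3L, 3L)) && all(is.finite(r)) &&
    max(abs(crossprod(r) - diag(3))) <= tol && abs(det(r) - 1) <= tol
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternions are `(w, x, y, z)` scalar-first.  Inputs within 1e-3 of unit
#' norm are renormalised; anything farther off (or non-finite / near zero
#' norm) is rejected.  `q` and `-q` map to the same rotation.
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  if (length(q) != 4L || !all(is.finite(q))) {
    stop("quaternion must be 4 finite numbers (w, x, y, z)", call. = FALSE)
  }
  n <- sqrt(sum(q^2))
  if (n < 1e-6) stop("quaternion norm is near zero", call. = FALSE)
  if (abs(n - 1) > 1e-3) {
    stop("quaternion norm ", format(n), " is too far from 1", call. = FALSE)
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Scalar-first `(w, x, y, z)` with `w >= 0` (sign convention for a unique
#' representative of the double cover).
#'
#' @param r 3x3 rotation matrix.
#' @return numeric length-4 quaternion.
#' @export
rotation_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1L] < 0) q <- -q
  q
}

rot_x <- function(deg) {
  a <- deg / DEG; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3L, byrow = TRUE)
}

rot_y <- function(deg) {
  a <- deg / DEG; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3L, byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg / DEG; c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3L, byrow = TRUE)
}

#' Compose a rotation from rxzy intrinsic Euler angles
#'
#' The joint-angle convention is intrinsic rotations about the rotating
#' frame's X, then Z, then Y axes ("rxzy"): `R = Rx(x) %*% Rz(z) %*% Ry(y)`.
#' In the package's world frame the X angle is the flexion-extension
#' component, Z the ab/adduction component and Y the axial-rotation
#' component of a joint rotation.
#'
#' @param x,z,y angles in degrees.
#' @return 3x3 rotation matrix.
#' @seealso [euler_rxzy()]
#' @export
matrix_from_euler_rxzy <- function(x, z, y) {
  if (!all(is.finite(c(x, z, y)))) stop("angles must be finite", call. = FALSE)
  rot_x(x) %*% rot_z(z) %*% rot_y(y)
}

#' Decompose a rotation into rxzy intrinsic Euler angles
#'
#' Inverse of [matrix_from_euler_rxzy()] on the principal range
#' `x, y in (-180, 180]`, `z in [-90, 90]`.  Near the gimbal singularity
#' (`|z| > 89.99` degrees) x and y are not separable; the tie is broken by
#' setting `y = 0` and the result carries `attr(, "gimbal") = TRUE`.
#'
#' @param r 3x3 rotation matrix.
#' @return numeric `c(x, z, y)` in degrees, with a `gimbal` attribute.
#' @export
euler_rxzy <- function(r) {
  check_rotation(r, tol = 1e-6)
  sz <- -r[1, 2]
  sz <- min(1, max(-1, sz))
  z <- asin(sz) * DEG
  gimbal <- abs(z) > 89.99
  if (gimbal) {
    # cos(z) ~ 0: only x +/- y observable; convention y = 0
    y <- 0
    x <- atan2(-r[2, 3], r[3, 3]) * DEG
  } else {
    x <- atan2(r[3, 2], r[2, 2]) * DEG
    y <- atan2(r[1, 3], r[1, 1]) * DEG
  }
  out <- c(x = x, z = z, y = y)
  attr(out, "gimbal") <- gimbal
  out
}

#' Project a 3-vector onto the ground plane
#'
#' Removes the vertical (Y) component and returns normalised ground-plane
#' coordinates `(x, z)`.  Vectors within `min_angle_deg` of the vertical have
#' no usable ground direction and raise an error.
#'
#' @param v numeric length-3 world vector.
#' @param min_angle_deg minimum angle from the vertical axis (default 1).
#' @return unit length-2 vector `(x, z)`.
#' @export
project_to_ground <- function(v, min_angle_deg = 1) {
  if (length(v) != 3L || !all(is.finite(v))) {
    stop("v must be a finite 3-vector", call. = FALSE)
  }
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot project a zero vector", call. = FALSE)
  g <- c(v[1L], v[3L])
  gn <- sqrt(sum(g^2))
  if (asin(min(1, gn / n)) * DEG < min_angle_deg) {
    stop("vector is within ", min_angle_deg,
         " degrees of vertical: degenerate ground projection", call. = FALSE)
  }
  g / gn
}

#' Signed angle between two ground-plane directions
#'
#' Angle from `a` to `b` on the ground plane, in degrees in `(-180, 180]`:
#' the angle `alpha` such that [heading_rotation()]`(alpha)` turns `a` onto
#' `b`'s direction.  Bearings are measured from +Z (anteroposterior) toward
#' +X (mediolateral right), the direction in which a heading rotation
#' advances a vector.
#'
#' @param a,b length-2 ground-plane vectors `(x, z)` (need not be unit).
#' @return signed angle in degrees.
#' @export
angle_between_projections <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L ||
      !all(is.finite(c(a, b))) || sum(a^2) == 0 || sum(b^2) == 0) {
    stop("a and b must be finite non-zero 2-vectors", call. = FALSE)
  }
  ang <- (atan2(b[1L], b[2L]) - atan2(a[1L], a[2L])) * DEG
  wrap_angle(ang)
}

#' Wrap an angle to the principal range (-180, 180]
#' @param deg angle in degrees.
#' @return wrapped angle.
#' @export
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
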