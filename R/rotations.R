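# Rotation utilities shared by the sampling and evaluation layers.
# All rotations are 3x3 proper orthonormal matrices acting on column vectors.

vec_norm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the (normalized) `axis`.
#'
#' @param axis numeric 3-vector, need not be unit length.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis <- function(axis, angle) {
  a <- unitize(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Rotation about the z axis
#' @param psi angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(psi) {
  c1 <- cos(psi); s1 <- sin(psi)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Minimal-arc rotation taking the north pole onto a point
#'
#' Returns the rotation with smallest angle that maps (0,0,1) to the unit
#' vector `p`. For `p = (0,0,1)` the identity is returned; for the antipode
#' `p = (0,0,-1)` the tie is broken as a rotation by pi about the x axis,
#' i.e. `diag(c(1,-1,-1))`, so the enumeration of poses is reproducible.
#'
#' @param p unit 3-vector (norm within 1e-6 of 1).
#' @return 3x3 rotation matrix `R` with `R %*% c(0,0,1) == p`.
#' @export
rotation_to_point <- function(p) {
  if (abs(vec_norm(p) - 1) > 1e-6) stop("rotation_to_point: p is not a unit vector")
  z <- c(0, 0, 1)
  if (p[3] >= 1 - 1e-12) return(diag(3))
  if (p[3] <= -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(-p[2], p[1], 0)            # z cross p
  rot_axis(axis, acos(max(-1, min(1, p[3]))))
}

# Minimal-arc rotation taking unit vector a onto unit vector b.
# Antipodal tie-break: rotate by pi about the deterministic in-plane axis
# orthobasis(a)$v_a.
arc_rotation <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  d <- sum(a * b)
  if (d >= 1 - 1e-12) return(diag(3))
  if (d <= -1 + 1e-12) return(rot_axis(orthobasis(a)$v_a, pi))
  rot_axis(pracma_cross(a, b), acos(max(-1, min(1, d))))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# Canonical scalar-first unit quaternion (w >= 0) from a rotation matrix.
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

matrix_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# One rotation drawn uniformly (Haar) from SO(3), using the current RNG state.
random_rotation <- function() {
  q <- stats::rnorm(4)
  matrix_from_quat(q / sqrt(sum(q^2)))
}
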