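# Unit-quaternion helpers for rigid-body orientation. Quaternions are stored
# as c(w, x, y, z) with |q| = 1; they act on body-frame coordinates as
# lab = R(q) %*% body.

quat_normalize <- function(q) {
  q / sqrt(sum(q^2))
}

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rotation matrix from a unit quaternion
#' @param q Numeric length-4 quaternion c(w, x, y, z).
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Unit quaternion from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return Length-4 quaternion c(w, x, y, z).
#' @export
matrix_to_quat <- function(R) {
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
  quat_normalize(q)
}

# Quaternion for rotation by |v| radians about axis v/|v| (rotation vector).
quat_from_rotvec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) {
    return(quat_normalize(c(1, v / 2)))
  }
  c(cos(theta / 2), sin(theta / 2) * v / theta)
}

#' Uniform random orientation on the rotation group
#'
#' Draws unit quaternions uniformly on SO(3) (Shoemake's method via
#' normalized 4D Gaussians), used to initialise encounter simulations with
#' unbiased starting orientations.
#'
#' @param n Number of orientations.
#' @return n x 4 matrix of unit quaternions.
#' @export
random_quaternion <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}
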