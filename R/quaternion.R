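#' Quaternion utilities
#'
#' Quaternions are length-4 numeric vectors in scalar-first Hamilton
#' convention `(q0, q1, q2, q3)`, right-handed. Sequences of quaternions are
#' N x 4 matrices, one quaternion per row. `quat_rotate()` implements the
#' sandwich product `q (0, v) q^-1`, i.e. it rotates a body-frame vector into
#' the world frame when `q` is the body-to-world attitude.
#'
#' @name quaternion
NULL

#' Quaternion product
#'
#' Hamilton product `p %*% q` (non-commutative).
#'
#' @param p,q Length-4 numeric quaternions, scalar first.
#' @return Length-4 numeric quaternion.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Quaternion conjugate
#' @param q Length-4 quaternion.
#' @return Conjugate quaternion (vector part negated).
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit norm
#' @param q Length-4 quaternion.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion exponential
#'
#' `exp(q) = exp(q0) * (cos(|v|), v/|v| * sin(|v|))` where `v` is the vector
#' part. The `|v| -> 0` limit is handled analytically via the series
#' `sin(x)/x -> 1`.
#'
#' @param q Length-4 quaternion (need not be unit norm).
#' @return Length-4 quaternion.
#' @export
quat_exp <- function(q) {
  vn <- sqrt(q[2]^2 + q[3]^2 + q[4]^2)
  s <- exp(q[1])
  if (vn < 1e-12) {
    # sin(x)/x ~ 1 - x^2/6; below 1e-12 the correction is < 1e-24
    sinc <- 1
  } else {
    sinc <- sin(vn) / vn
  }
  s * c(cos(vn), sinc * q[2], sinc * q[3], sinc * q[4])
}

#' Unit quaternion from axis-angle
#' @param axis Length-3 axis (normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion
#'
#' Returns the 3x3 matrix `R` with `R v = q (0, v) q^-1` (body-to-world for
#' an attitude quaternion).
#'
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)),
    nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return Unit quaternion, scalar part non-negative.
#' @export
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
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate a vector by a unit quaternion
#'
#' Computes `q (0, v) q^-1`: rotates `v` from the body frame into the world
#' frame when `q` is the body-to-world attitude. Under this sense a static,
#' flat-foot accelerometer reading rotated by the integrated attitude yields
#' pure gravity in the global frame.
#'
#' @param q Unit quaternion.
#' @param v Length-3 vector, or N x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

#' Convert a unit quaternion to ZYX Euler angles
#'
#' Intrinsic yaw-pitch-roll (ZYX) convention: the rotation factors as
#' `R = Rz(yaw) Ry(pitch) Rx(roll)`. With the shoe frame used throughout the
#' package (x medial/lateral, y anterior/posterior, z superior), roll is the
#' sagittal-plane angle and pitch the frontal-plane angle. The asin argument
#' is clamped to `[-1, 1]`; at gimbal lock (`|pitch| = pi/2`) roll is set to
#' zero and yaw absorbs the remaining rotation.
#'
#' @param q Unit quaternion or N x 4 matrix of unit quaternions.
#' @return Named numeric `(roll, pitch, yaw)` in radians, or an N x 3 matrix.
#' @export
quat_to_euler <- function(q) {
  if (is.matrix(q)) {
    out <- t(apply(q, 1, quat_to_euler))
    colnames(out) <- c("roll", "pitch", "yaw")
    return(out)
  }
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  sp <- 2 * (q0 * q2 - q3 * q1)
  sp <- max(-1, min(1, sp))
  pitch <- asin(sp)
  if (abs(sp) > 1 - 1e-12) {
    # gimbal lock: roll and yaw are degenerate; put everything into yaw
    roll <- 0
    yaw <- atan2(2 * (q1 * q2 - q0 * q3), 2 * (q0 * q2 + q1 * q3)) *
      sign(sp) * -1
  } else {
    roll <- atan2(2 * (q0 * q1 + q2 * q3), 1 - 2 * (q1^2 + q2^2))
    yaw <- atan2(2 * (q0 * q3 + q1 * q2), 1 - 2 * (q2^2 + q3^2))
  }
  c(roll = roll, pitch = pitch, yaw = yaw)
}

#' Unit quaternion from ZYX Euler angles
#' @param roll,pitch,yaw Angles in radians (rotation about x, y, z).
#' @return Unit quaternion.
#' @export
quat_from_euler <- function(roll, pitch, yaw) {
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch)
  qx <- quat_from_axis_angle(c(1, 0, 0), roll)
  quat_multiply(quat_multiply(qz, qy), qx)
}

#' Geodesic distance between two unit quaternions
#'
#' Computed from the chordal distance `min(|p - q|, |p + q|)` via
#' `2 asin(d / 2)`, which stays accurate down to machine precision for
#' nearly identical attitudes (a dot-product/acos formulation loses half
#' the significant digits there).
#'
#' @param p,q Unit quaternions.
#' @return Rotation angle in radians in `[0, pi]` between the two attitudes.
#' @export
quat_angle_between <- function(p, q) {
  d <- min(sqrt(sum((p - q)^2)), sqrt(sum((p + q)^2)))
  2 * asin(min(1, d / 2))
}
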