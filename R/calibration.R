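#' Functional sensor-to-shoe calibration
#'
#' Each IMU is mounted in an arbitrary orientation relative to the shoe. Two
#' functional recordings fix the alignment: a quiet stance (the accelerometer
#' measures gravity, which corresponds to the shoe superior axis z) and a
#' balance-board rotation confined to the sagittal plane (the dominant
#' gyroscope axis corresponds to the shoe medial/lateral axis x). Each
#' recording yields one vector pair (sensor-frame direction, shoe-frame
#' direction); the rotation best mapping sensor directions onto shoe
#' directions is the solution of the Wahba problem.
#'
#' @name calibration
NULL

#' Vector pair for the Wahba alignment problem
#'
#' @param v_sensor Unit 3-vector in the sensor frame.
#' @param v_shoe Unit 3-vector in the shoe frame.
#' @param weight Positive weight (default 1).
#' @return An object of class `vector_pair`.
#' @export
vector_pair <- function(v_sensor, v_shoe, weight = 1) {
  v_sensor <- as.numeric(v_sensor); v_shoe <- as.numeric(v_shoe)
  stopifnot(length(v_sensor) == 3, length(v_shoe) == 3, weight > 0)
  if (abs(sqrt(sum(v_sensor^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(v_shoe^2)) - 1) > 1e-9)
    stop("vector_pair requires unit-norm vectors")
  structure(list(v_sensor = v_sensor, v_shoe = v_shoe, weight = weight),
            class = "vector_pair")
}

#' Gravity vector pair from a quiet-stance recording
#'
#' The subject stands still with the foot flat on the ground; the mean
#' accelerometer vector points along gravity in the sensor frame and maps to
#' the shoe superior axis `(0, 0, 1)`.
#'
#' @param static_stream An `imu_stream` captured during quiet stance.
#' @param gyr_rms_warn Warn if the gyroscope RMS exceeds this (rad/s).
#' @return A `vector_pair`.
#' @export
gravity_pair <- function(static_stream, gyr_rms_warn = 0.2) {
  m <- colMeans(static_stream$acc)
  nm <- sqrt(sum(m^2))
  g <- 9.81
  if (nm < g * 0.85 || nm > g * 1.15)
    stop(sprintf(
      "not static: mean acceleration norm %.2f m/s^2 outside [%.2f, %.2f]",
      nm, g * 0.85, g * 1.15))
  gyr_rms <- sqrt(mean(static_stream$gyr^2))
  if (gyr_rms > gyr_rms_warn)
    warning(sprintf("gyroscope RMS %.3f rad/s during static recording", gyr_rms))
  vector_pair(m / nm, c(0, 0, 1))
}

#' Medial/lateral vector pair from a balance-board recording
#'
#' The foot rocks on a balance board that only permits sagittal-plane
#' rotation, so the angular rate lies along the shoe medial/lateral axis.
#' The sensor-frame direction is the first principal axis of the 3 x N
#' angular-rate sample matrix; its sign is chosen so that the projection of
#' the dominant rotation sample (largest magnitude) is positive.
#'
#' @param rotation_stream An `imu_stream` of the board rocking motion.
#' @param min_axis_ratio Minimum ratio of first to second singular value of
#'   the rate matrix below which the motion is rejected as not planar.
#' @return A `vector_pair` mapping the principal axis to `(1, 0, 0)`.
#' @export
board_axis_pair <- function(rotation_stream, min_axis_ratio = 3) {
  W <- rotation_stream$gyr
  sv <- svd(W, nu = 0, nv = 3)
  if (sv$d[1] < 1e-12 || sv$d[1] / max(sv$d[2], 1e-300) < min_axis_ratio)
    stop(sprintf(
      "rotation not planar: singular value ratio %.2f below %.2f",
      if (sv$d[2] > 0) sv$d[1] / sv$d[2] else Inf, min_axis_ratio))
  axis <- sv$v[, 1]
  proj <- W %*% axis
  if (proj[which.max(abs(proj))] < 0) axis <- -axis
  vector_pair(axis, c(1, 0, 0))
}

#' Solve the Wahba problem for the sensor-to-shoe rotation
#'
#' Finds the proper rotation `R` minimizing
#' `sum_i w_i || v_shoe_i - R v_sensor_i ||^2` via singular value
#' decomposition of the weighted attitude-profile matrix
#' `B = sum_i w_i v_shoe_i v_sensor_i^T`, with the determinant sign
#' correction `R = U diag(1, 1, det(U V^T)) V^T`. Two non-collinear pairs
#' (the functional-calibration setting) determine `R` uniquely; the third
#' axis is implied by orthogonality.
#'
#' @param pairs List of at least two `vector_pair` objects whose shoe-frame
#'   directions span at least two dimensions.
#' @return 3x3 rotation matrix rotating sensor-frame vectors into the shoe
#'   frame.
#' @export
solve_wahba <- function(pairs) {
  stopifnot(length(pairs) >= 2)
  B <- matrix(0, 3, 3)
  for (p in pairs) {
    stopifnot(inherits(p, "vector_pair"))
    B <- B + p$weight * (p$v_shoe %o% p$v_sensor)
  }
  sv <- svd(B)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("rank-deficient alignment problem: reference vectors are collinear")
  d <- det(sv$u %*% t(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  stopifnot(max(abs(R %*% t(R) - diag(3))) < 1e-9, abs(det(R) - 1) < 1e-9)
  R
}

#' Rotate an imu_stream from the sensor frame into the shoe frame
#'
#' @param stream An `imu_stream` with `frame == "sensor"`.
#' @param R 3x3 sensor-to-shoe rotation matrix (e.g. from [solve_wahba()]).
#' @return An `imu_stream` in the shoe frame.
#' @export
align_stream <- function(stream, R) {
  if (stream$frame != "sensor")
    stop(sprintf("align_stream expects a sensor-frame stream, got '%s'",
                 stream$frame))
  imu_stream(acc = stream$acc %*% t(R), gyr = stream$gyr %*% t(R),
             fs = stream$fs, t = stream$t, frame = "shoe",
             position_label = stream$position_label)
}

#' Full functional calibration from static and board recordings
#'
#' Convenience wrapper: builds the gravity and board-axis vector pairs and
#' solves for the sensor-to-shoe rotation.
#'
#' @param static_stream Quiet-stance `imu_stream`.
#' @param board_stream Balance-board `imu_stream`.
#' @param mirror If `TRUE`, flip the medial/lateral reference axis to
#'   `(-1, 0, 0)` (opposite shoe handedness).
#' @param weights Length-2 positive weights for the gravity and board pairs.
#' @return 3x3 sensor-to-shoe rotation matrix.
#' @export
calibrate_alignment <- function(static_stream, board_stream, mirror = FALSE,
                                weights = c(1, 1)) {
  gp <- gravity_pair(static_stream)
  bp <- board_axis_pair(board_stream)
  if (mirror) bp <- vector_pair(bp$v_sensor, c(-1, 0, 0), bp$weight)
  gp$weight <- weights[1]; bp$weight <- weights[2]
  solve_wahba(list(gp, bp))
}

#' Write an alignment rotation to JSON
#' @param R 3x3 rotation matrix.
#' @param path Output path.
#' @param position_label,fs Metadata stored alongside the row-major matrix.
#' @return `path`, invisibly.
#' @export
write_alignment_json <- function(R, path, position_label = "unknown", fs = NA) {
  jsonlite::write_json(
    list(rotation_row_major = as.numeric(t(R)),
         position_label = position_label, fs = fs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an alignment rotation written by [write_alignment_json()]
#' @param path JSON path.
#' @return 3x3 rotation matrix with metadata attributes.
#' @export
read_alignment_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- matrix(x$rotation_row_major, 3, 3, byrow = TRUE)
  attr(R, "position_label") <- x$position_label
  attr(R, "fs") <- x$fs
  R
}
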