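#' IMU stream container
#'
#' An `imu_stream` bundles a time base, tri-axial accelerometer and gyroscope
#' samples, the sampling rate, the coordinate frame the samples are expressed
#' in, and a free-text sensor position label. Angular rate is stored in rad/s
#' internally; degrees are accepted only at the I/O boundary
#' (see [read_imu_csv()]).
#'
#' @param t Numeric vector of timestamps in seconds, uniform at `fs`.
#'   If `NULL`, regenerated as `(0:(n-1))/fs`.
#' @param acc N x 3 matrix of accelerations in m/s^2 (columns x, y, z).
#' @param gyr N x 3 matrix of angular rates in rad/s (columns x, y, z).
#' @param fs Sampling rate in Hz.
#' @param frame One of `"sensor"`, `"shoe"`, `"global"`.
#' @param position_label Free string naming the mounting position
#'   (e.g. `"cavity"`, `"heel"`, `"instep"`, `"lateral"`).
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(acc, gyr, fs, t = NULL,
                       frame = c("sensor", "shoe", "global"),
                       position_label = "unknown") {
  frame <- match.arg(frame)
  acc <- as_xyz_matrix(acc, "acc")
  gyr <- as_xyz_matrix(gyr, "gyr")
  n <- nrow(acc)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  x <- structure(
    list(t = as.numeric(t), acc = acc, gyr = gyr, fs = fs,
         frame = frame, position_label = position_label),
    class = "imu_stream")
  validate_imu_stream(x)
}

as_xyz_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3) stop(sprintf("'%s' must have 3 columns", what))
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

#' Validate an imu_stream against its invariants
#'
#' Checks equal lengths, positive sampling rate, uniform timestamps and
#' absence of non-finite samples. The first offending row is named in the
#' error message.
#'
#' @param x An `imu_stream`.
#' @param t_tol Tolerance on the deviation of timestamp increments from
#'   `1/fs`, in seconds.
#' @return `x`, invisibly validated (returned unchanged).
#' @export
validate_imu_stream <- function(x, t_tol = 1e-9) {
  stopifnot(inherits(x, "imu_stream"))
  if (!is.numeric(x$fs) || length(x$fs) != 1 || x$fs <= 0)
    stop("fs must be a single positive number")
  n <- length(x$t)
  if (nrow(x$acc) != n || nrow(x$gyr) != n)
    stop(sprintf("length mismatch: %d timestamps, %d acc rows, %d gyr rows",
                 n, nrow(x$acc), nrow(x$gyr)))
  if (n == 0) stop("empty stream")
  if (!x$frame %in% c("sensor", "shoe", "global"))
    stop("frame must be one of 'sensor', 'shoe', 'global'")
  bad <- which(!is.finite(x$t) | !apply(is.finite(x$acc), 1, all) |
                 !apply(is.finite(x$gyr), 1, all))
  if (length(bad) > 0)
    stop(sprintf("non-finite sample at row %d", bad[1]))
  if (n > 1) {
    dt <- diff(x$t)
    off <- which(abs(dt - 1 / x$fs) > t_tol)
    if (length(off) > 0)
      stop(sprintf(
        "non-uniform timestamps: gap of %.6g s between rows %d and %d (expected %.6g s)",
        dt[off[1]], off[1], off[1] + 1, 1 / x$fs))
  }
  x
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples @ %g Hz (%.2f s), frame=%s, position=%s\n",
              length(x$t), x$fs, length(x$t) / x$fs, x$frame, x$position_label))
  invisible(x)
}

#' Number of samples in an imu_stream
#' @param x An `imu_stream`.
#' @export
length.imu_stream <- function(x) length(x$t)

#' Extract a contiguous sample range of an imu_stream
#' @param x An `imu_stream`.
#' @param from,to 1-based sample indices (inclusive).
#' @return A new `imu_stream` covering the range; timestamps are rebased to 0.
#' @export
imu_window <- function(x, from, to) {
  stopifnot(from >= 1, to <= length(x$t), from <= to)
  imu_stream(acc = x$acc[from:to, , drop = FALSE],
             gyr = x$gyr[from:to, , drop = FALSE],
             fs = x$fs, frame = x$frame, position_label = x$position_label)
}

#' Read an IMU recording from CSV
#'
#' Expects a header row with a time column and six signal columns. Column
#' names and the gyroscope unit are configurable; angular rate given in
#' degrees per second is converted to rad/s on read.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping the canonical names
#'   `t, ax, ay, az, gx, gy, gz` to the column names in the file.
#' @param gyr_unit `"rad/s"` (default) or `"deg/s"`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred from the median
#'   timestamp increment.
#' @param frame Frame the data is expressed in (default `"sensor"`).
#' @param position_label Sensor position label.
#' @return An `imu_stream`.
#' @export
read_imu_csv <- function(path,
                         columns = c(t = "t", ax = "ax", ay = "ay", az = "az",
                                     gx = "gx", gy = "gy", gz = "gz"),
                         gyr_unit = c("rad/s", "deg/s"),
                         fs = NULL,
                         frame = "sensor",
                         position_label = "unknown") {
  gyr_unit <- match.arg(gyr_unit)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(columns))
  if (length(miss) > 0)
    stop("column mapping incomplete, missing: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(columns[need]), names(df))
  if (length(absent) > 0)
    stop(sprintf("missing column '%s' in %s", absent[1], path))
  t <- df[[columns[["t"]]]]
  acc <- cbind(df[[columns[["ax"]]]], df[[columns[["ay"]]]], df[[columns[["az"]]]])
  gyr <- cbind(df[[columns[["gx"]]]], df[[columns[["gy"]]]], df[[columns[["gz"]]]])
  if (gyr_unit == "deg/s") gyr <- gyr * pi / 180
  if (is.null(fs)) {
    if (length(t) < 2) stop("cannot infer fs from fewer than 2 samples")
    fs <- 1 / stats::median(diff(t))
  }
  imu_stream(acc = acc, gyr = gyr, fs = fs, t = t, frame = frame,
             position_label = position_label)
}

#' Write an imu_stream to CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz`; angular rate written in rad/s.
#'
#' @param stream An `imu_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  df <- data.frame(t = stream$t,
                   ax = stream$acc[, 1], ay = stream$acc[, 2], az = stream$acc[, 3],
                   gx = stream$gyr[, 1], gy = stream$gyr[, 2], gz = stream$gyr[, 3])
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-stride parameter table to CSV
#'
#' Fixed column order with units encoded in the header:
#' `stride_id, t_stride_s, t_gc_s, d_stride_m, v_stride_mps,
#' sole_angle_deg, rom_deg`.
#'
#' @param params Data frame with (at least) those seven columns, one row per
#'   stride; extra columns are dropped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path) {
  cols <- c("stride_id", "t_stride_s", "t_gc_s", "d_stride_m",
            "v_stride_mps", "sole_angle_deg", "rom_deg")
  if (!is.data.frame(params) || nrow(params) == 0)
    stop("'params' must be a non-empty data frame")
  miss <- setdiff(cols, names(params))
  if (length(miss) > 0)
    stop("missing parameter columns: ", paste(miss, collapse = ", "))
  out <- params[, cols]
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-stride parameter table written by [write_parameters_csv()]
#' @param path CSV path.
#' @return Data frame with the seven canonical columns.
#' @export
read_parameters_csv <- function(path) {
  utils::read.csv(path)
}
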