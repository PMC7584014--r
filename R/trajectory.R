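#' Zero-velocity-update strapdown integration
#'
#' Per stride, the foot attitude is obtained by quaternion integration of the
#' gyroscope between two consecutive midstance instants (where the foot is
#' assumed flat and stationary, so the shoe and global frames coincide and
#' orientation and velocity can be reset to zero). The acceleration is
#' rotated into the global frame, gravity is subtracted, and velocity and
#' position follow from rectangular cumulative integration with a linear
#' dedrifting that forces zero velocity at both midstance endpoints.
#'
#' @name trajectory
NULL

#' Forward quaternion integration of angular rate
#'
#' Starting from the identity at the first sample, each step right-multiplies
#' by the differential rotation `exp(W[n] / (2 fs))` where `W[n]` is the pure
#' quaternion of the angular rate sample. The quaternion is renormalized
#' every step. The result row `k` is the attitude of sample `k` relative to
#' the starting sample: with the zero-velocity initialization it rotates
#' shoe-frame vectors into the global frame.
#'
#' @param gyr N x 3 angular rate matrix (rad/s), shoe frame.
#' @param fs Sampling rate (Hz).
#' @return N x 4 matrix of unit quaternions; row 1 is the identity. The rate
#'   sample of row `k` advances the attitude from row `k` to row `k + 1`
#'   (the last rate sample is unused).
#' @export
integrate_forward <- function(gyr, fs) {
  gyr <- as_xyz_matrix(gyr, "gyr")
  n <- nrow(gyr)
  q <- matrix(0, n, 4)
  q[1, ] <- c(1, 0, 0, 0)
  if (n > 1) {
    h <- 1 / (2 * fs)
    for (k in seq_len(n - 1)) {
      dq <- quat_exp(c(0, gyr[k, ] * h))
      q[k + 1, ] <- quat_normalize(quat_multiply(q[k, ], dq))
    }
  }
  q
}

#' Backward quaternion integration of angular rate
#'
#' Integrates from the last sample (midstance, identity attitude) backwards
#' to the first, using the negated angular rates, so that row `k` is the
#' attitude of sample `k` relative to midstance. Forward-integrating the
#' same interval from the backward result's first attitude returns to the
#' identity.
#'
#' @param gyr N x 3 angular rate matrix (rad/s) spanning `[n_ic, n_ms]`.
#' @param fs Sampling rate (Hz).
#' @return N x 4 matrix of unit quaternions; the last row is the identity.
#' @export
integrate_backward <- function(gyr, fs) {
  gyr <- as_xyz_matrix(gyr, "gyr")
  n <- nrow(gyr)
  q <- matrix(0, n, 4)
  q[n, ] <- c(1, 0, 0, 0)
  if (n > 1) {
    h <- 1 / (2 * fs)
    for (k in seq(n - 1, 1)) {
      dq <- quat_exp(c(0, -gyr[k, ] * h))
      q[k, ] <- quat_normalize(quat_multiply(q[k + 1, ], dq))
    }
  }
  q
}

#' Rotate acceleration into the global frame and remove gravity
#'
#' Each acceleration sample is rotated by the corresponding attitude
#' quaternion (shoe to global; the two frames coincide at midstance) and the
#' gravity vector `(0, 0, g)` is subtracted. A static flat-foot stream maps
#' to zero.
#'
#' @param acc N x 3 shoe-frame specific force (m/s^2).
#' @param quat N x 4 attitude quaternions from [integrate_forward()].
#' @param g Gravity magnitude (m/s^2), default 9.81.
#' @return N x 3 gravity-corrected global-frame acceleration.
#' @export
remove_gravity <- function(acc, quat, g = 9.81) {
  acc <- as_xyz_matrix(acc, "acc")
  if (nrow(acc) != nrow(quat))
    stop(sprintf("length mismatch: %d acceleration rows vs %d quaternions",
                 nrow(acc), nrow(quat)))
  out <- matrix(0, nrow(acc), 3)
  for (k in seq_len(nrow(acc))) {
    out[k, ] <- quat_rotate(quat[k, ], acc[k, ])
  }
  out[, 3] <- out[, 3] - g
  colnames(out) <- c("x", "y", "z")
  out
}

#' Dedrifted double integration of gravity-corrected acceleration
#'
#' Velocity is the rectangular cumulative integral of acceleration with
#' `v = 0` at the first sample (midstance). The accumulated drift is removed
#' by subtracting the linear ramp that matches the terminal velocity, which
#' forces the dedrifted velocity to zero at both midstance endpoints by
#' construction. Position is the rectangular cumulative integral of the
#' dedrifted velocity with `pos = 0` at the first sample.
#'
#' @param acc_gc N x 3 gravity-corrected global-frame acceleration spanning
#'   one stride (midstance to next midstance), N >= 2.
#' @param fs Sampling rate (Hz).
#' @return List with `vel` (raw velocity), `vel_dedrifted` and `pos`, each
#'   N x 3.
#' @export
dedrift_integrate <- function(acc_gc, fs) {
  acc_gc <- as_xyz_matrix(acc_gc, "acc_gc")
  n <- nrow(acc_gc)
  if (n < 2) stop("stride span must contain at least 2 samples")
  v <- apply(acc_gc, 2, function(a) c(0, cumsum(a[-n])) / fs)
  ramp <- (seq_len(n) - 1) / (n - 1)
  delta <- outer(ramp, v[n, ])
  vd <- v - delta
  pos <- apply(vd, 2, function(u) c(0, cumsum(u[-n])) / fs)
  colnames(v) <- colnames(vd) <- colnames(pos) <- c("x", "y", "z")
  list(vel = v, vel_dedrifted = vd, pos = pos)
}

#' Compute the full per-stride trajectory
#'
#' Composition of the strapdown steps for one stride: forward quaternion
#' integration on `[n_ms, n_ms_next]`, backward integration on
#' `[n_ic, n_ms]` (so the orientation at initial contact is expressed
#' relative to the flat-foot midstance attitude), Euler conversion with the
#' backward segment concatenated before the forward one, gravity removal and
#' dedrifted double integration.
#'
#' @param stream Shoe-frame `imu_stream`.
#' @param events One stride's events: named list or single-row data frame
#'   with `n_ic, n_ms, n_to, n_ms_next`.
#' @param g Gravity magnitude (m/s^2).
#' @return Object of class `stride_trajectory`: list with `quat`
#'   (over `[n_ms, n_ms_next]`), `euler` (radians, over `[n_ic, n_ms_next]`),
#'   `vel_dedrifted`, `pos` (over `[n_ms, n_ms_next]`), `n_start` (= n_ic,
#'   global index of the first euler row), `events`, `fs`.
#' @export
compute_stride_trajectory <- function(stream, events, g = 9.81) {
  if (stream$frame != "shoe")
    stop("compute_stride_trajectory expects a shoe-frame stream")
  ev <- as.list(events)
  n_ic <- ev$n_ic; n_ms <- ev$n_ms; n_ms_next <- ev$n_ms_next
  stopifnot(n_ic <= n_ms, n_ms < n_ms_next, n_ms_next <= length(stream$t))
  fwd_idx <- n_ms:n_ms_next
  qf <- integrate_forward(stream$gyr[fwd_idx, , drop = FALSE], stream$fs)
  if (n_ic < n_ms) {
    qb <- integrate_backward(stream$gyr[n_ic:n_ms, , drop = FALSE], stream$fs)
    eb <- quat_to_euler(qb[-nrow(qb), , drop = FALSE])
  } else {
    eb <- matrix(numeric(0), 0, 3)
  }
  ef <- quat_to_euler(qf)
  euler <- rbind(eb, ef)
  colnames(euler) <- c("roll", "pitch", "yaw")
  acc_gc <- remove_gravity(stream$acc[fwd_idx, , drop = FALSE], qf, g)
  integ <- dedrift_integrate(acc_gc, stream$fs)
  structure(list(quat = qf, euler = euler,
                 vel_dedrifted = integ$vel_dedrifted, pos = integ$pos,
                 n_start = n_ic, events = ev, fs = stream$fs),
            class = "stride_trajectory")
}

#' @export
print.stride_trajectory <- function(x, ...) {
  cat(sprintf("<stride_trajectory> %d samples @ %g Hz, |pos end| = %.3f m\n",
              nrow(x$quat), x$fs, sqrt(sum(x$pos[nrow(x$pos), ]^2))))
  invisible(x)
}
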