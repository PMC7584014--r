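#' Rigid-body foot-IMU simulator
#'
#' Generates physically consistent multi-position IMU recordings of running
#' with known ground truth. The foot is modelled as a rigid body whose pose
#' (position + orientation) is a piecewise-polynomial function of time with
#' an exactly stationary, exactly flat midstance dwell in every stride --
#' the premise of the zero-velocity update holds by construction, so
#' parameter-recovery error isolates algorithmic error. Sensors are rigidly
#' offset from the foot reference point by a lever arm and an arbitrary
#' mounting rotation; their accelerometer signals include the lever-arm
#' angular and centripetal terms, while their angular-rate signals are
#' position-independent (rigid-body property). Attachment artifacts
#' (impact-excited damped oscillations, white noise, gyro bias) are applied
#' on top, deterministically for a given seed.
#'
#' @name simulate
NULL

# ---- gait model ------------------------------------------------------------

#' Gait model: the per-stride ground-truth description
#'
#' @param t_stride Stride time in seconds (IC to IC).
#' @param duty Ground-contact fraction `t_gc / t_stride` in (0, 1).
#' @param d_stride Stride length in metres.
#' @param sole_angle_deg Sagittal sole angle at IC in degrees (negative =
#'   rearfoot strike).
#' @param rom_deg Frontal-plane range of motion during ground contact,
#'   degrees (> 0).
#' @param ms_dwell Duration in seconds of the exactly stationary flat-foot
#'   midstance segment.
#' @return Object of class `gait_model`. The implied average velocity
#'   `d_stride / t_stride` must lie in the supported 2-6 m/s range.
#' @export
gait_model <- function(t_stride = 0.75, duty = 0.36, d_stride = 2.25,
                       sole_angle_deg = -10, rom_deg = 9, ms_dwell = 0.05) {
  stopifnot(t_stride > 0, duty > 0, duty < 1, d_stride >= 0, rom_deg >= 0,
            ms_dwell > 0)
  v <- d_stride / t_stride
  if (v < 1.5 || v > 6.5)
    stop(sprintf("implied velocity %.2f m/s outside the supported range", v))
  if (duty * t_stride <= ms_dwell)
    stop("midstance dwell must be shorter than the ground contact phase")
  structure(list(t_stride = t_stride, duty = duty, d_stride = d_stride,
                 sole_angle_deg = sole_angle_deg, rom_deg = rom_deg,
                 ms_dwell = ms_dwell),
            class = "gait_model")
}

# ---- piecewise polynomial helpers -----------------------------------------

# cubic Hermite coefficients on [0, dt] from endpoint values/derivatives
hermite3 <- function(f0, d0, f1, d1, dt) {
  c(f0, d0,
    3 * (f1 - f0) / dt^2 - (2 * d0 + d1) / dt,
    2 * (f0 - f1) / dt^3 + (d0 + d1) / dt^2)
}

# exact integral of a cubic Hermite segment (used to solve the waveform)
hermite3_area <- function(f0, d0, f1, d1, dt) {
  dt * (f0 + f1) / 2 + dt^2 * (d0 - d1) / 12
}

# quintic Hermite coefficients on [0, dt] from values/1st/2nd derivatives
hermite5 <- function(f0, d0, s0, f1, d1, s1, dt) {
  A <- rbind(c(1, 0, 0, 0, 0, 0),
             c(0, 1, 0, 0, 0, 0),
             c(0, 0, 2, 0, 0, 0),
             dt^(0:5),
             c(0, 1, 2 * dt, 3 * dt^2, 4 * dt^3, 5 * dt^4),
             c(0, 0, 2, 6 * dt, 12 * dt^2, 20 * dt^3))
  as.numeric(solve(A, c(f0, d0, s0, f1, d1, s1)))
}

# evaluate a piecewise polynomial: knots (length m+1), coef list (m entries,
# power-basis in local time), plus per-segment integral offsets for the
# antiderivative channel if requested. Returns value/1st/2nd derivative.
piecewise_eval <- function(tt, knots, coefs) {
  seg <- findInterval(tt, knots, rightmost.closed = TRUE)
  seg[seg < 1] <- 1
  seg[seg > length(coefs)] <- length(coefs)
  f <- d1 <- d2 <- numeric(length(tt))
  for (s in unique(seg)) {
    i <- which(seg == s)
    tau <- tt[i] - knots[s]
    cf <- coefs[[s]]
    pw <- outer(tau, seq_along(cf) - 1, `^`)
    f[i] <- pw %*% cf
    dcf <- cf[-1] * seq_len(length(cf) - 1)
    d1[i] <- outer(tau, seq_along(dcf) - 1, `^`) %*% dcf
    if (length(dcf) > 1) {
      scf <- dcf[-1] * seq_len(length(dcf) - 1)
      d2[i] <- outer(tau, seq_along(scf) - 1, `^`) %*% scf
    }
  }
  list(f = f, d1 = d1, d2 = d2)
}

# antiderivative of a piecewise polynomial with given starting value
piecewise_antideriv <- function(knots, coefs, f0 = 0) {
  out <- vector("list", length(coefs))
  acc <- f0
  for (s in seq_along(coefs)) {
    cf <- coefs[[s]]
    icf <- c(acc, cf / seq_along(cf))
    out[[s]] <- icf
    dt <- knots[s + 1] - knots[s]
    acc <- sum(icf * dt^(seq_along(icf) - 1))
  }
  out
}

snap <- function(x, fs) round(x * fs) / fs

# ---- one-cycle waveform design --------------------------------------------

# Designs the within-cycle (midstance to midstance) angle and position
# profiles. The sagittal angle is specified through its rate so that the
# gyroscope extrema fall at fixed offsets from the true events: the IC peak
# 10 ms after true IC and the TO peak 24 ms after true TO, emulating the
# documented biases of these fiducials. Peak amplitudes are solved from the
# sole-angle and periodicity constraints.
design_cycle <- function(model, fs,
                         t_ic_ms = 0.12,       # IC to flat foot
                         ic_peak_offset = 0.010,
                         to_peak_offset = 0.024,
                         omega_ic_peak = 3.0,  # rad/s at the IC gyro peak
                         swing_frac = 0.65,    # swing-minimum placement
                         z_lift = 0.12) {      # swing foot lift, m
  T <- snap(model$t_stride, fs)
  t_gc <- snap(model$duty * model$t_stride, fs)
  d <- snap(model$ms_dwell, fs)
  t_icms <- snap(t_ic_ms, fs)
  v <- model$d_stride / model$t_stride
  d_stride <- v * T                       # keep velocity exact after snapping
  theta_ic <- model$sole_angle_deg * pi / 180
  rom <- model$rom_deg * pi / 180

  t_to <- t_gc - t_icms                   # TO of the previous contact
  t_ic <- T - t_icms                      # next IC
  if (t_to <= d + 2 / fs)
    stop("infeasible gait model: midstance dwell reaches into toe off")
  if (t_ic <= t_to + 0.1)
    stop("infeasible gait model: no swing phase left")
  t_topk <- t_to + to_peak_offset
  t_icpk <- t_ic + ic_peak_offset
  t_sp <- snap(t_topk + swing_frac * (t_ic - t_topk), fs)
  t_mid2 <- t_icpk + 0.5 * (T - t_icpk)

  dd <- t_icpk - t_ic
  de1 <- t_mid2 - t_icpk
  de2 <- T - t_mid2
  w3 <- 5 + 0.8 * v                       # swing-dip depth, rad/s
  # Landing waveform: rate rises through IC to a peak 10 ms later (w1),
  # then decays via w_d to zero at the dwell. The integral from IC to
  # midstance must equal -theta_ic. With w_ic = 0.7 w1 and
  # s_ic = 0.36 w1 / dd the landing-side area is linear in (w1, w_d).
  # Steep landings scale the peak (w_d = 0.3 w1); shallow or forefoot
  # landings keep the default peak and absorb the area in w_d.
  k_land <- 0.88 * dd + 0.65 * de1 + 0.15 * de2
  if (-theta_ic / k_land >= omega_ic_peak) {
    w1 <- -theta_ic / k_land
    w_d <- 0.3 * w1
  } else {
    w1 <- omega_ic_peak
    A4 <- 0.88 * dd * w1
    w_d <- (-theta_ic - A4 - de1 * w1 / 2) / ((de1 + de2) / 2)
  }
  w_ic <- 0.7 * w1
  s_ic <- 0.36 * w1 / dd
  A4 <- hermite3_area(w_ic, s_ic, w1, 0, dd)
  if (w_d >= 0.85 * w1 || w_d <= -0.8 * w3)
    stop("infeasible gait model: sole angle too large for the landing waveform")
  dc <- t_ic - t_sp
  A3 <- hermite3_area(-w3, 0, w_ic, s_ic, dc)
  da <- t_topk - d
  db <- t_sp - t_topk
  w2 <- (theta_ic - A3 + db * w3 / 2) / ((da + db) / 2)
  if (w2 <= 0.5)
    stop("infeasible gait model: propulsion peak would vanish")

  wk <- c(0, d, t_topk, t_sp, t_ic, t_icpk, t_mid2, T)
  wv <- c(0, 0, w2, -w3, w_ic, w1, w_d, 0)
  ws <- c(0, 0, 0, 0, s_ic, 0, 0, 0)
  om_coefs <- lapply(seq_len(length(wk) - 1), function(i)
    hermite3(wv[i], ws[i], wv[i + 1], ws[i + 1], wk[i + 1] - wk[i]))
  th_coefs <- piecewise_antideriv(wk, om_coefs, 0)

  # frontal angle: quintic knots; max phi_a at IC, min -phi_b mid-stance
  phi_a <- 0.6 * rom
  phi_b <- 0.4 * rom
  phi_sw <- 0.25 * rom
  t_dip <- snap((d + t_to) / 2, fs)
  t_sw <- snap(t_topk + 0.5 * (t_ic - t_topk), fs)
  dphi_ic <- -1.2 * phi_a / (T - t_ic)
  pk <- c(0, d, t_dip, t_sw, t_ic, T)
  pv <- c(0, 0, -phi_b, phi_sw, phi_a, 0)
  pd <- c(0, 0, 0, 0, dphi_ic, 0)
  phi_coefs <- lapply(seq_len(length(pk) - 1), function(i)
    hermite5(pv[i], pd[i], 0, pv[i + 1], pd[i + 1], 0, pk[i + 1] - pk[i]))

  list(T = T, fs = fs, t_gc = t_gc, dwell = d, t_icms = t_icms,
       t_to = t_to, t_ic = t_ic, t_topk = t_topk, t_icpk = t_icpk,
       t_sp = t_sp, t_dip = t_dip, d_stride = d_stride, v = v,
       theta_ic = theta_ic, rom = rom, phi_a = phi_a, phi_b = phi_b,
       z_lift = z_lift,
       omega_knots = wk, omega_coefs = om_coefs, theta_coefs = th_coefs,
       phi_knots = pk, phi_coefs = phi_coefs)
}

# evaluate all cycle channels at within-cycle times tau (vectorized)
cycle_channels <- function(cy, tau) {
  om <- piecewise_eval(tau, cy$omega_knots, cy$omega_coefs)
  th <- piecewise_eval(tau, cy$omega_knots, cy$theta_coefs)
  ph <- piecewise_eval(tau, cy$phi_knots, cy$phi_coefs)
  # forward advance: quintic smoothstep on [dwell, T]
  y <- dy <- ddy <- numeric(length(tau))
  L <- cy$T - cy$dwell
  u <- (tau - cy$dwell) / L
  i <- which(u > 0 & u < 1)
  ui <- u[i]
  y[u >= 1] <- cy$d_stride
  y[i] <- cy$d_stride * (10 * ui^3 - 15 * ui^4 + 6 * ui^5)
  dy[i] <- cy$d_stride * (30 * ui^2 - 60 * ui^3 + 30 * ui^4) / L
  ddy[i] <- cy$d_stride * (60 * ui - 180 * ui^2 + 120 * ui^3) / L^2
  # swing lift: C2 bump on [t_to, t_ic]
  z <- dz <- ddz <- numeric(length(tau))
  Lz <- cy$t_ic - cy$t_to
  w <- (tau - cy$t_to) / Lz
  j <- which(w > 0 & w < 1)
  wj <- w[j]
  b <- wj * (1 - wj)
  z[j] <- cy$z_lift * 64 * b^3
  dz[j] <- cy$z_lift * 64 * 3 * b^2 * (1 - 2 * wj) / Lz
  ddz[j] <- cy$z_lift * 64 * (6 * b * (1 - 2 * wj)^2 - 6 * b^2) / Lz^2
  list(theta = th$f, dtheta = om$f, ddtheta = om$d1,
       phi = ph$f, dphi = ph$d1, ddphi = ph$d2,
       y = y, dy = dy, ddy = ddy, z = z, dz = dz, ddz = ddz)
}

# pose and derivatives at absolute times (handles the cycle wrap)
pose_at <- function(cy, t_abs) {
  cyc <- floor(t_abs / cy$T + 1e-12)
  tau <- t_abs - cyc * cy$T
  # samples that fall on the grid are snapped onto it exactly, so that knot
  # boundaries (dwell edges in particular) evaluate to their exact values
  kk <- tau * cy$fs
  on_grid <- abs(kk - round(kk)) < 1e-6
  tau[on_grid] <- round(kk[on_grid]) / cy$fs
  ch <- cycle_channels(cy, tau)
  n <- length(t_abs)
  pos <- cbind(x = numeric(n), y = cyc * cy$d_stride + ch$y, z = ch$z)
  vel <- cbind(0, ch$dy, ch$dz)
  acc <- cbind(0, ch$ddy, ch$ddz)
  # orientation R = Ry(phi) Rx(theta): ZYX Euler (roll = theta, pitch = phi)
  ct <- cos(ch$theta); st <- sin(ch$theta)
  c2 <- cos(ch$theta / 2); s2 <- sin(ch$theta / 2)
  cp2 <- cos(ch$phi / 2); sp2 <- sin(ch$phi / 2)
  quat <- cbind(cp2 * c2, cp2 * s2, sp2 * c2, -sp2 * s2)
  omega <- cbind(ch$dtheta, ch$dphi * ct, -ch$dphi * st)
  omega_dot <- cbind(ch$ddtheta,
                     ch$ddphi * ct - ch$dphi * ch$dtheta * st,
                     -ch$ddphi * st - ch$dphi * ch$dtheta * ct)
  list(pos = pos, vel = vel, acc = acc, quat = quat,
       omega = omega, omega_dot = omega_dot,
       theta = ch$theta, phi = ch$phi)
}

#' Generate the ground-truth foot trajectory of a stride train
#'
#' Produces the rigid-body pose sequence (position, attitude quaternion,
#' body angular rate and its derivative, world-frame acceleration) for
#' `n_strides` annotated strides, plus lead-in and lead-out cycles so that
#' segmentation has context at both ends. Every stride contains an exactly
#' stationary flat-foot dwell; the sagittal angle at the annotated IC equals
#' the model's sole angle; the frontal-plane excursion over ground contact
#' equals the model's range of motion; the planar displacement per cycle
#' equals the stride length. All knot times are snapped to the sample grid.
#'
#' @param model A [gait_model()].
#' @param n_strides Number of annotated strides (>= 1).
#' @param fs Sampling rate (Hz), >= 100.
#' @return Object of class `foot_trajectory`: list with `t`, `pos`, `quat`,
#'   `omega`, `omega_dot`, `acc_world` (all per sample), `fs`, `cycle`
#'   (design constants), `annotations` (per-stride truth: event times and
#'   sample indices, the six parameters, speed bin) and `pose_fun(t)` for
#'   continuous evaluation.
#' @export
generate_foot_trajectory <- function(model, n_strides, fs = 200) {
  stopifnot(inherits(model, "gait_model"), n_strides >= 1, fs >= 100)
  cy <- design_cycle(model, fs)
  n_cycles <- n_strides + 2
  N <- round(cy$T * fs)
  n <- n_cycles * N
  t <- (seq_len(n) - 1) / fs
  po <- pose_at(cy, t)
  idx <- function(time) round(time * fs) + 1L
  k <- seq_len(n_strides)
  ann <- data.frame(
    stride_id = k,
    t_sp = (k - 1) * cy$T + cy$t_sp,
    t_ic = (k - 1) * cy$T + cy$t_ic,
    t_ms = k * cy$T,
    t_to = k * cy$T + cy$t_to,
    t_ms_next = (k + 1) * cy$T)
  ann$n_sp <- idx(ann$t_sp); ann$n_ic <- idx(ann$t_ic)
  ann$n_ms <- idx(ann$t_ms); ann$n_to <- idx(ann$t_to)
  ann$n_ms_next <- idx(ann$t_ms_next)
  ann$t_stride <- cy$T
  ann$t_gc <- cy$t_gc
  ann$d_stride <- cy$d_stride
  ann$v_stride <- cy$v
  ann$sole_angle_deg <- cy$theta_ic * 180 / pi
  ann$rom_deg <- (cy$phi_a + cy$phi_b) * 180 / pi
  ann$speed_bin <- speed_bin(ann$v_stride)
  structure(list(t = t, pos = po$pos, quat = po$quat, omega = po$omega,
                 omega_dot = po$omega_dot, acc_world = po$acc, fs = fs,
                 cycle = cy, annotations = ann,
                 pose_fun = function(tt) pose_at(cy, tt)),
            class = "foot_trajectory")
}

# ---- sensors ---------------------------------------------------------------

#' Sensor mounting description
#'
#' @param lever_arm Length-3 offset (m) of the sensor from the foot
#'   reference point, in the shoe frame; norm < 0.3 m.
#' @param mount_rotation Unit quaternion rotating sensor-frame vectors into
#'   the shoe frame (the misalignment the functional calibration recovers).
#' @param artifact An [artifact_model()].
#' @return Object of class `sensor_mount`.
#' @export
sensor_mount <- function(lever_arm = c(0, 0, 0),
                         mount_rotation = c(1, 0, 0, 0),
                         artifact = artifact_model()) {
  lever_arm <- as.numeric(lever_arm)
  stopifnot(length(lever_arm) == 3, sqrt(sum(lever_arm^2)) < 0.3,
            length(mount_rotation) == 4)
  mount_rotation <- quat_normalize(mount_rotation)
  structure(list(lever_arm = lever_arm, mount_rotation = mount_rotation,
                 artifact = artifact),
            class = "sensor_mount")
}

#' Attachment artifact description
#'
#' Mechanisms: a damped oscillation excited by the landing impact at each
#' IC (shoe-upper vibration), white measurement noise on both modalities,
#' and a constant gyroscope bias. All stochastic components are
#' reproducible from `seed`.
#'
#' @param impact_amp Amplitude (m/s^2) of the damped oscillation added to
#'   the accelerometer after each IC. Its leading lobe decelerates the
#'   sensor (the landing shock), so it carries net impulse and degrades the
#'   reconstructed trajectory as well as the midstance gravity reading.
#' @param impact_freq Oscillation frequency (Hz); the default 15 Hz is the
#'   low-frequency attachment mode representable at a 200 Hz output rate.
#' @param impact_decay Exponential decay rate (1/s).
#' @param acc_noise_sd,gyr_noise_sd White-noise standard deviations
#'   (m/s^2, rad/s).
#' @param gyr_bias Constant gyroscope bias magnitude (rad/s), direction
#'   drawn from `seed`.
#' @param seed Integer seed.
#' @return Object of class `artifact_model`.
#' @export
artifact_model <- function(impact_amp = 0, impact_freq = 15,
                           impact_decay = 10, acc_noise_sd = 0,
                           gyr_noise_sd = 0, gyr_bias = 0, seed = 1L) {
  stopifnot(impact_amp >= 0, impact_freq >= 0, impact_decay >= 0,
            acc_noise_sd >= 0, gyr_noise_sd >= 0, gyr_bias >= 0)
  structure(list(impact_amp = impact_amp, impact_freq = impact_freq,
                 impact_decay = impact_decay, acc_noise_sd = acc_noise_sd,
                 gyr_noise_sd = gyr_noise_sd, gyr_bias = gyr_bias,
                 seed = as.integer(seed)),
            class = "artifact_model")
}

# rotate rows of v (N x 3) by per-row quaternions q (N x 4): q (0,v) q^-1
rows_rotate <- function(q, v) {
  qv <- q[, 2:4, drop = FALSE]
  q0 <- q[, 1]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- cr(qv, v)
  v + 2 * q0 * t1 + 2 * cr(qv, t1)
}

rows_cross <- function(a, b) {
  if (!is.matrix(b)) b <- matrix(b, nrow(a), 3, byrow = TRUE)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# ideal sensor reading (acc, gyr) at the instants described by a pose list
sensor_measurement <- function(po, mount, g) {
  r <- mount$lever_arm
  om <- po$omega
  omd <- po$omega_dot
  # lever-arm acceleration in the body frame
  a_lever_body <- rows_cross(omd, r) + rows_cross(om, rows_cross(om, r))
  a_w <- po$acc + rows_rotate(po$quat, a_lever_body)
  f_w <- a_w
  f_w[, 3] <- f_w[, 3] + g
  # world -> shoe: rotate by conjugate attitude; shoe -> sensor: conjugate mount
  qc <- cbind(po$quat[, 1], -po$quat[, 2:4])
  f_shoe <- rows_rotate(qc, f_w)
  qm <- quat_conjugate(mount$mount_rotation)
  qm_mat <- matrix(qm, nrow(f_shoe), 4, byrow = TRUE)
  list(acc = rows_rotate(qm_mat, f_shoe), gyr = rows_rotate(qm_mat, om))
}

#' Project a ground-truth pose sequence onto an ideal sensor
#'
#' Computes what a noiseless IMU rigidly mounted at the given lever arm and
#' orientation would measure: the gyroscope reads the body angular rate
#' rotated into the sensor frame (identical for all lever arms); the
#' accelerometer reads the specific force at the sensor point, including
#' the lever-arm terms `omega_dot x r + omega x (omega x r)` and gravity.
#'
#' Two sampling front-ends are available. The default `"instantaneous"`
#' point-samples the continuous signals on the sample grid, which keeps the
#' midstance dwell and all annotated extrema exact. `"filtered"` emits the
#' mean of each channel over a centred one-sample window (zero phase, so
#' extrema keep their timing), emulating the antialiasing decimation of a
#' MEMS front-end; it requires the trajectory to carry a continuous
#' `pose_fun`.
#'
#' @param traj A `foot_trajectory` (or any list with `t, quat, omega,
#'   omega_dot, acc_world, fs`, optionally a continuous `pose_fun`).
#' @param mount A [sensor_mount()].
#' @param g Gravity magnitude (m/s^2).
#' @param position_label Label for the resulting stream.
#' @param sampling Front-end model.
#' @param oversample Sub-samples per interval for the filtered model.
#' @return An `imu_stream` in the sensor frame.
#' @export
project_to_sensor <- function(traj, mount, g = 9.81,
                              position_label = "unknown",
                              sampling = c("instantaneous", "filtered"),
                              oversample = 8) {
  sampling <- match.arg(sampling)
  if (sampling == "filtered" && is.null(traj$pose_fun)) {
    warning("no continuous pose available; falling back to instantaneous sampling")
    sampling <- "instantaneous"
  }
  if (sampling == "instantaneous") {
    ms <- sensor_measurement(
      list(quat = traj$quat, omega = traj$omega, omega_dot = traj$omega_dot,
           acc = traj$acc_world), mount, g)
  } else {
    dt <- 1 / traj$fs
    offs <- ((seq_len(oversample) - 0.5) / oversample - 0.5) * dt
    acc <- gyr <- matrix(0, length(traj$t), 3)
    for (off in offs) {
      po <- traj$pose_fun(traj$t + off)
      m1 <- sensor_measurement(
        list(quat = po$quat, omega = po$omega, omega_dot = po$omega_dot,
             acc = po$acc), mount, g)
      acc <- acc + m1$acc
      gyr <- gyr + m1$gyr
    }
    ms <- list(acc = acc / oversample, gyr = gyr / oversample)
  }
  imu_stream(acc = ms$acc, gyr = ms$gyr, fs = traj$fs, t = traj$t,
             frame = "sensor", position_label = position_label)
}

#' Apply attachment artifacts to an ideal stream
#'
#' Adds, per annotated stride, a damped sinusoid to the accelerometer
#' starting at the true IC; white noise to both modalities; and a constant
#' gyroscope bias. Deterministic given the artifact seed. An all-zero
#' artifact model returns the stream unchanged.
#'
#' @param stream Ideal `imu_stream` from [project_to_sensor()].
#' @param artifact An [artifact_model()].
#' @param annotations Annotation data frame of the parent
#'   `foot_trajectory` (needs column `t_ic`).
#' @return Corrupted `imu_stream`.
#' @export
apply_artifacts <- function(stream, artifact, annotations) {
  a <- artifact
  if (a$impact_amp == 0 && a$acc_noise_sd == 0 && a$gyr_noise_sd == 0 &&
      a$gyr_bias == 0) return(stream)
  acc <- stream$acc
  gyr <- stream$gyr
  n <- nrow(acc)
  if (a$impact_amp > 0) {
    # decelerating first lobe (-y), with vertical and lateral components
    dir <- c(0.35, -0.45, 0.82)
    dir <- dir / sqrt(sum(dir^2))
    span <- if (a$impact_decay > 0) min(0.4, 6 / a$impact_decay) else 0.4
    for (t_ic in annotations$t_ic) {
      i0 <- round(t_ic * stream$fs) + 1
      i1 <- min(n, i0 + round(span * stream$fs))
      if (i0 > n) next
      tau <- (seq(i0, i1) - i0) / stream$fs
      amp <- a$impact_amp * exp(-a$impact_decay * tau) *
        sin(2 * pi * a$impact_freq * tau)
      acc[i0:i1, ] <- acc[i0:i1, ] + outer(amp, dir)
    }
  }
  if (a$acc_noise_sd > 0 || a$gyr_noise_sd > 0 || a$gyr_bias > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(a$seed)
    if (a$acc_noise_sd > 0)
      acc <- acc + matrix(stats::rnorm(3 * n, sd = a$acc_noise_sd), n, 3)
    if (a$gyr_noise_sd > 0)
      gyr <- gyr + matrix(stats::rnorm(3 * n, sd = a$gyr_noise_sd), n, 3)
    if (a$gyr_bias > 0) {
      bdir <- stats::rnorm(3)
      bdir <- bdir / sqrt(sum(bdir^2))
      gyr <- gyr + matrix(a$gyr_bias * bdir, n, 3, byrow = TRUE)
    }
  }
  imu_stream(acc = acc, gyr = gyr, fs = stream$fs, t = stream$t,
             frame = stream$frame, position_label = stream$position_label)
}

# ---- calibration recordings ------------------------------------------------

#' Simulate the functional calibration recordings for one mount
#'
#' Static quiet stance (flat foot, identity attitude) and balance-board
#' rocking about the shoe medial/lateral axis, both projected onto the
#' sensor (lever arm and mounting rotation applied).
#'
#' @param mount A [sensor_mount()].
#' @param fs Sampling rate (Hz).
#' @param static_dur,board_dur Durations in seconds.
#' @param board_amp_deg,board_freq Board rocking amplitude (deg) and
#'   frequency (Hz).
#' @param g Gravity magnitude.
#' @param position_label Label for the streams.
#' @return List with `static` and `board` `imu_stream`s.
#' @export
simulate_calibration_recordings <- function(mount, fs = 200, static_dur = 2,
                                            board_dur = 4, board_amp_deg = 20,
                                            board_freq = 1, g = 9.81,
                                            position_label = "unknown") {
  n1 <- round(static_dur * fs)
  t1 <- (seq_len(n1) - 1) / fs
  static_pose <- function(tt) {
    n <- length(tt)
    list(quat = cbind(rep(1, n), 0, 0, 0), omega = matrix(0, n, 3),
         omega_dot = matrix(0, n, 3), acc = matrix(0, n, 3))
  }
  p1 <- static_pose(t1)
  static_traj <- list(t = t1, quat = p1$quat, omega = p1$omega,
                      omega_dot = p1$omega_dot, acc_world = p1$acc, fs = fs,
                      pose_fun = static_pose)
  n2 <- round(board_dur * fs)
  t2 <- (seq_len(n2) - 1) / fs
  A <- board_amp_deg * pi / 180
  wf <- 2 * pi * board_freq
  board_pose <- function(tt) {
    th <- A * sin(wf * tt)
    list(quat = cbind(cos(th / 2), sin(th / 2), 0, 0),
         omega = cbind(A * wf * cos(wf * tt), 0, 0),
         omega_dot = cbind(-A * wf^2 * sin(wf * tt), 0, 0),
         acc = matrix(0, length(tt), 3))
  }
  p2 <- board_pose(t2)
  board_traj <- list(t = t2, quat = p2$quat, omega = p2$omega,
                     omega_dot = p2$omega_dot, acc_world = p2$acc, fs = fs,
                     pose_fun = board_pose)
  list(static = project_to_sensor(static_traj, mount, g, position_label),
       board = project_to_sensor(board_traj, mount, g, position_label))
}

# ---- cohort ----------------------------------------------------------------

#' Default sensor mounts for the four shoe positions
#'
#' Lever arms are plausible shoe geometry relative to a reference point
#' under the arch (simulator parameters, not measured values); each mount
#' carries a distinct non-trivial mounting rotation that the functional
#' calibration must recover.
#'
#' @param artifacts Named list of [artifact_model()]s per position (e.g.
#'   [artifact_presets()]); default none.
#' @return Named list of [sensor_mount()]s: cavity, heel, instep, lateral.
#' @export
default_mounts <- function(artifacts = NULL) {
  rot <- list(
    cavity = quat_from_euler(0.05, -0.03, 0.10),
    heel = quat_from_euler(0.10, 0.60, 3.00),
    instep = quat_from_euler(-0.25, 0.50, 0.05),
    lateral = quat_from_euler(1.45, 0.05, -0.10))
  lev <- list(cavity = c(0, 0.02, -0.02), heel = c(-0.10, 0, 0.03),
              instep = c(0.02, 0.05, 0.06), lateral = c(-0.03, -0.04, 0.01))
  out <- lapply(names(lev), function(p) {
    art <- if (!is.null(artifacts) && p %in% names(artifacts))
      artifacts[[p]] else artifact_model()
    sensor_mount(lev[[p]], rot[[p]], art)
  })
  names(out) <- names(lev)
  out
}

#' Artifact presets per mounting position
#'
#' Impact amplitudes ordered cavity < lateral < heel < instep, mirroring
#' the mechanism ranking of attachment firmness (sole cavity most damped,
#' lace clip most exposed). Magnitudes are illustrative simulator
#' configuration, not measured values.
#'
#' @param seed Base seed; each position gets a distinct derived seed.
#' @param noise If `FALSE`, only the impact component is enabled.
#' @return Named list of [artifact_model()]s.
#' @export
artifact_presets <- function(seed = 1L, noise = TRUE) {
  amp <- c(cavity = 0.5, lateral = 1.5, heel = 3, instep = 5)
  out <- lapply(seq_along(amp), function(i)
    artifact_model(impact_amp = amp[[i]],
                   acc_noise_sd = if (noise) 0.15 else 0,
                   gyr_noise_sd = if (noise) 0.01 else 0,
                   gyr_bias = if (noise) 0.005 else 0,
                   seed = seed + i))
  names(out) <- names(amp)
  out
}

derive_seeds <- function(master, n) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(master)
  sample.int(.Machine$integer.max - 1, n)
}

#' Simulate a multi-trial, multi-position cohort in memory
#'
#' Mirrors the study design: trials are distributed over four 1 m/s speed
#' bins from 2 to 6 m/s; each trial is a constant-speed stride train
#' recorded simultaneously by all mounted sensors. Per-trial gait
#' parameters (velocity within the bin, stride/contact times, sole angle,
#' range of motion) are drawn reproducibly from the master seed.
#'
#' @param trials_per_bin Integer vector of trial counts for the bins
#'   2-3, 3-4, 4-5, 5-6 m/s; default `c(10, 10, 15, 15)`.
#' @param strides_per_trial Annotated strides per trial.
#' @param mounts Named list of [sensor_mount()]s.
#' @param seed Master seed; spawns per-trial child seeds.
#' @param fs Sampling rate (Hz).
#' @return Object of class `gait_cohort`: list with `trials` (each with
#'   `trial_id, bin, model, truth, streams` (ideal per position),
#'   `streams_corrupted`, `traj`), `calibration` (per position static/board
#'   streams), `mounts`, `fs`, `seed`.
#' @export
simulate_cohort <- function(trials_per_bin = c(10, 10, 15, 15),
                            strides_per_trial = 5,
                            mounts = default_mounts(),
                            seed = 1L, fs = 200) {
  stopifnot(length(trials_per_bin) == 4)
  edges <- 2:6
  n_trials <- sum(trials_per_bin)
  seeds <- derive_seeds(seed, n_trials + 1)
  calib <- lapply(names(mounts), function(p)
    simulate_calibration_recordings(mounts[[p]], fs = fs, position_label = p))
  names(calib) <- names(mounts)
  trials <- list()
  tid <- 0
  for (b in seq_len(4)) {
    for (j in seq_len(trials_per_bin[b])) {
      tid <- tid + 1
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seeds[tid])
      v <- stats::runif(1, edges[b] + 0.1, edges[b + 1] - 0.1)
      t_stride <- 0.82 - 0.028 * v
      t_gc <- 0.33 - 0.022 * v
      sole <- max(-18, min(-4, stats::rnorm(1, -10, 3)))
      rom <- max(5, min(14, stats::rnorm(1, 9, 1.5)))
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
      model <- gait_model(t_stride = t_stride, duty = t_gc / t_stride,
                          d_stride = v * t_stride, sole_angle_deg = sole,
                          rom_deg = rom)
      traj <- generate_foot_trajectory(model, strides_per_trial, fs)
      streams <- lapply(names(mounts), function(p)
        project_to_sensor(traj, mounts[[p]], position_label = p))
      names(streams) <- names(mounts)
      streams_corrupted <- lapply(names(mounts), function(p) {
        art <- mounts[[p]]$artifact
        art$seed <- art$seed + tid * 1000L
        apply_artifacts(streams[[p]], art, traj$annotations)
      })
      names(streams_corrupted) <- names(mounts)
      truth <- traj$annotations
      truth$trial_id <- tid
      truth$bin <- paste0(edges[b], "-", edges[b + 1])
      trials[[tid]] <- list(trial_id = tid, bin = truth$bin[1], model = model,
                            truth = truth, streams = streams,
                            streams_corrupted = streams_corrupted,
                            traj = traj)
    }
  }
  structure(list(trials = trials, calibration = calib, mounts = mounts,
                 fs = fs, seed = seed),
            class = "gait_cohort")
}

#' Write a simulated cohort to a dataset directory
#'
#' One CSV per trial and position (corrupted streams), per-position
#' calibration recordings, a ground-truth table with one row per stride,
#' and a JSON manifest listing files, seeds and the generation spec.
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (tr in cohort$trials) {
    for (p in names(tr$streams_corrupted)) {
      f <- sprintf("trial%03d_%s.csv", tr$trial_id, p)
      write_imu_csv(tr$streams_corrupted[[p]], file.path(out_dir, f))
      files[[length(files) + 1]] <-
        list(file = f, trial_id = tr$trial_id, position = p, bin = tr$bin)
    }
  }
  for (p in names(cohort$calibration)) {
    write_imu_csv(cohort$calibration[[p]]$static,
                  file.path(out_dir, sprintf("calib_static_%s.csv", p)))
    write_imu_csv(cohort$calibration[[p]]$board,
                  file.path(out_dir, sprintf("calib_board_%s.csv", p)))
  }
  truth <- do.call(rbind, lapply(cohort$trials, `[[`, "truth"))
  truth$speed_bin <- as.character(truth$speed_bin)
  utils::write.csv(format(truth, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(seed = cohort$seed, fs = cohort$fs,
                   positions = names(cohort$mounts),
                   n_trials = length(cohort$trials),
                   truth = "truth.csv", recordings = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
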