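test_that("forward integration is exact for zero and constant rates", {
  fs <- 200
  q0 <- integrate_forward(matrix(0, 50, 3), fs)
  expect_true(all(q0[, 1] == 1) && all(q0[, 2:4] == 0))
  # constant rate for 0.5 s: angle = |omega| * T
  om <- matrix(rep(c(0, 3, 0), each = 101), ncol = 3)
  q <- integrate_forward(om, fs)
  expect_lt(quat_angle_between(q[101, ], quat_from_axis_angle(c(0, 1, 0), 1.5)),
            1e-9)
  # every quaternion stays unit norm
  set.seed(21)
  qr <- integrate_forward(matrix(rnorm(900, sd = 5), 300, 3), fs)
  expect_lt(max(abs(sqrt(rowSums(qr^2)) - 1)), 1e-9)
})

test_that("backward integration mirrors forward integration exactly", {
  fs <- 200
  qb0 <- integrate_backward(matrix(0, 30, 3), fs)
  expect_true(all(qb0[, 1] == 1))
  # constant rate about x for 0.1 s: attitude at the start is -omega*T
  om <- matrix(rep(c(4, 0, 0), each = 21), ncol = 3)
  qb <- integrate_backward(om, fs)
  expect_lt(quat_angle_between(qb[1, ], quat_from_axis_angle(c(1, 0, 0), -0.4)),
            1e-9)
  # forward-integrating from the backward result's first attitude returns
  # to the identity at the end (inverse-composition property)
  set.seed(22)
  omr <- matrix(rnorm(150, sd = 4), 50, 3)
  qbr <- integrate_backward(omr, fs)
  qf <- integrate_forward(omr, fs)
  recomposed <- quat_multiply(qbr[1, ], qf[nrow(qf), ])
  expect_lt(quat_angle_between(recomposed, c(1, 0, 0, 0)), 1e-9)
})

test_that("gravity removal cancels gravity in static and tilted attitudes", {
  n <- 20
  qid <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  acc <- matrix(rep(c(0, 0, 9.81), each = n), ncol = 3)
  expect_lt(max(abs(remove_gravity(acc, qid))), 1e-12)
  # foot pitched 90 degrees: shoe-frame gravity along +x
  qp <- matrix(rep(quat_from_axis_angle(c(0, 1, 0), -pi / 2), each = n),
               ncol = 4)
  accp <- matrix(rep(c(9.81, 0, 0), each = n), ncol = 3)
  expect_lt(max(abs(remove_gravity(accp, qp))), 1e-12)
  expect_error(remove_gravity(acc[-1, ], qid), "length mismatch")
})

test_that("dedrifted integration has exactly zero velocity at both endpoints", {
  fs <- 200
  z <- dedrift_integrate(matrix(0, 100, 3), fs)
  expect_true(all(z$vel_dedrifted == 0) && all(z$pos == 0))
  # constant acceleration: the linear ramp removes the drift entirely
  const <- matrix(rep(c(2, 0, 0), each = 150), ncol = 3)
  dc <- dedrift_integrate(const, fs)
  expect_lt(max(abs(dc$vel_dedrifted)), 1e-12)
  expect_lt(max(abs(dc$pos)), 1e-12)
  # arbitrary random input: endpoint property holds by construction
  set.seed(23)
  for (i in 1:10) {
    a <- matrix(rnorm(3 * 120, sd = 20), 120, 3)
    d <- dedrift_integrate(a, fs)
    expect_lt(max(abs(d$vel_dedrifted[1, ])), 1e-9)
    expect_lt(max(abs(d$vel_dedrifted[120, ])), 1e-9)
    expect_true(all(d$pos[1, ] == 0))
  }
  expect_error(dedrift_integrate(matrix(0, 1, 3), fs), "2 samples")
})

test_that("raw integrated velocity nearly closes over a simulated stride", {
  # gravity removal with the true attitudes: the velocity before dedrifting
  # returns to ~0 at the next midstance. The planar components close to
  # machine precision; the vertical component carries only the trapezoidal
  # truncation of the swing bump, which must vanish at second order.
  ev <- segment_strides(std_stream)[1, ]
  idx <- ev$n_ms:ev$n_ms_next
  closure <- function(fs_eval) {
    tt <- seq(std_stream$t[idx[1]], std_stream$t[idx[length(idx)]],
              by = 1 / fs_eval)
    po <- std_traj$pose_fun(tt)
    acc_shoe <- t(vapply(seq_along(tt), function(k)
      quat_rotate(quat_conjugate(po$quat[k, ]), po$acc[k, ] + c(0, 0, 9.81)),
      numeric(3)))
    acc_gc <- remove_gravity(acc_shoe, po$quat)
    colSums((acc_gc[-1, ] + acc_gc[-nrow(acc_gc), ]) / 2) / fs_eval
  }
  v200 <- closure(200)
  v400 <- closure(400)
  expect_lt(max(abs(v200[1:2])), 1e-9)
  expect_lt(abs(v200[3]), 2e-3)
  expect_lt(abs(v400[3]), abs(v200[3]) / 3)   # ~4x reduction expected
})

test_that("compute_stride_trajectory satisfies its container invariants", {
  ev <- segment_strides(std_stream)
  traj <- compute_stride_trajectory(std_stream, ev[2, ])
  expect_equal(traj$quat[1, ], c(1, 0, 0, 0))
  expect_lt(max(abs(sqrt(rowSums(traj$quat^2)) - 1)), 1e-9)
  n <- nrow(traj$vel_dedrifted)
  expect_lt(max(abs(traj$vel_dedrifted[1, ])), 1e-9)
  expect_lt(max(abs(traj$vel_dedrifted[n, ])), 1e-9)
  expect_true(all(traj$pos[1, ] == 0))
  # euler sequence covers [n_ic, n_ms_next]
  expect_equal(nrow(traj$euler), ev$n_ms_next[2] - ev$n_ic[2] + 1)
  # degenerate stride with n_ic == n_ms still works
  ev2 <- as.list(ev[2, ])
  ev2$n_ic <- ev2$n_ms
  t2 <- compute_stride_trajectory(std_stream, ev2)
  expect_equal(nrow(t2$euler), ev2$n_ms_next - ev2$n_ms + 1)
  # zero-signal stream gives a zero trajectory
  zero <- imu_stream(matrix(0, 400, 3), matrix(0, 400, 3), 200, frame = "shoe")
  tz <- compute_stride_trajectory(
    zero, list(n_ic = 10, n_ms = 20, n_to = 100, n_ms_next = 200))
  expect_true(all(tz$euler == 0))
  expect_lt(max(abs(tz$pos)), 1e-9)
})

test_that("noise-free parameter recovery meets the headline bounds", {
  res <- analyze_recording(std_stream)
  ann <- std_traj$annotations
  expect_equal(nrow(res), 5)
  expect_lt(max(abs(res$d_stride_m - ann$d_stride)), 0.015)
  expect_lt(max(abs(res$sole_angle_deg - ann$sole_angle_deg)), 0.5)
  expect_lt(max(abs(res$rom_deg - ann$rom_deg)), 0.5)
  expect_lt(max(abs(res$t_stride_s - ann$t_stride)), 1 / 200 + 1e-12)
})

test_that("stride length is invariant under a global yaw of the scenario", {
  # body-frame signals do not change under a world-frame yaw, and stride
  # length is a planar norm: the recovered value must match bit for bit
  psi <- 1.1
  Rz <- quat_to_matrix(quat_from_axis_angle(c(0, 0, 1), psi))
  qz <- quat_from_axis_angle(c(0, 0, 1), psi)
  tr2 <- std_traj
  tr2$quat <- t(apply(std_traj$quat, 1, function(q) quat_multiply(qz, q)))
  tr2$pos <- std_traj$pos %*% t(Rz)
  tr2$acc_world <- std_traj$acc_world %*% t(Rz)
  tr2$pose_fun <- NULL
  s2 <- suppressWarnings(project_to_sensor(tr2, sensor_mount()))
  s2$frame <- "shoe"
  r1 <- analyze_recording(std_stream)
  r2 <- analyze_recording(s2)
  expect_equal(r2$d_stride_m, r1$d_stride_m, tolerance = 1e-9)
})
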