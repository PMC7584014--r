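test_that("gait model arithmetic and feasibility checks", {
  m <- gait_model(t_stride = 0.8, duty = 0.3, d_stride = 2.4)
  tr <- generate_foot_trajectory(m, 2, 200)
  expect_equal(tr$annotations$v_stride[1], 3)
  expect_equal(as.character(tr$annotations$speed_bin[1]), "3-4")
  expect_error(gait_model(t_stride = 0.8, duty = 0.05, d_stride = 2.4),
               "dwell")
  expect_error(gait_model(t_stride = 0.8, duty = 0.3, d_stride = 8),
               "velocity")
  # dwell reaching into toe off is infeasible at generation time
  expect_error(generate_foot_trajectory(
    gait_model(t_stride = 0.8, duty = 0.22, d_stride = 2.4, ms_dwell = 0.055),
    2, 200), "infeasible")
})

test_that("flat landing with zero eversion yields a flat trajectory at IC", {
  m <- gait_model(t_stride = 0.75, duty = 0.36, d_stride = 2.25,
                  sole_angle_deg = 0, rom_deg = 0)
  tr <- generate_foot_trajectory(m, 2, 200)
  po <- tr$pose_fun(tr$annotations$t_ic[1])
  expect_lt(abs(po$theta), 1e-12)
  expect_lt(abs(po$phi), 1e-12)
})

test_that("generated position is consistent with the analytic acceleration", {
  # five-point second difference of the continuous position against the
  # acceleration the sensors are built from, away from spline knots
  cy <- std_traj$cycle
  knots <- sort(unique(c(cy$omega_knots, cy$phi_knots, cy$t_to, cy$t_ic)))
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  tt <- std_traj$annotations$t_ms[1] + mids
  h <- 5e-4
  acc_fd <- sapply(c(-2, -1, 0, 1, 2), function(k) std_traj$pose_fun(tt + k * h)$pos)
  for (axis in 1:3) {
    n <- length(tt)
    rows <- (axis - 1) * n + seq_len(n)
    fd <- (-acc_fd[rows, 1] + 16 * acc_fd[rows, 2] - 30 * acc_fd[rows, 3] +
             16 * acc_fd[rows, 4] - acc_fd[rows, 5]) / (12 * h^2)
    expect_lt(max(abs(fd - std_traj$pose_fun(tt)$acc[, axis])), 1e-6)
  }
})

test_that("the midstance dwell is exactly flat and exactly stationary", {
  ann <- std_traj$annotations
  for (k in 1:2) {
    dwell <- ann$n_ms[k]:(ann$n_ms[k] + round(0.05 * 200))
    expect_true(all(std_traj$omega[dwell, ] == 0))
    expect_true(all(std_traj$quat[dwell, 1] == 1))
    expect_equal(max(abs(diff(std_traj$pos[dwell, ]))), 0)
    expect_true(all(std_traj$acc_world[dwell, ] == 0))
  }
  # planar displacement between consecutive midstances equals stride length
  d <- std_traj$pos[ann$n_ms_next[1], 1:2] - std_traj$pos[ann$n_ms[1], 1:2]
  expect_equal(sqrt(sum(d^2)), ann$d_stride[1], tolerance = 1e-12)
  # level running: height returns to zero at every midstance
  expect_equal(std_traj$pos[ann$n_ms, 3], rep(0, nrow(ann)))
})

test_that("projection reproduces closed-form rigid-body measurements", {
  # stationary flat pose, zero lever arm: pure gravity, zero rate
  rec <- simulate_calibration_recordings(sensor_mount(), position_label = "x")
  expect_true(all(rec$static$gyr == 0))
  expect_equal(rec$static$acc,
               matrix(rep(c(0, 0, 9.81), each = length(rec$static$t)), ncol = 3),
               ignore_attr = TRUE)
  # rotation about x with a lever arm perpendicular to the axis:
  # centripetal term = -|omega|^2 r at the moment of peak rate
  r <- c(0, 0.1, 0)
  board <- simulate_calibration_recordings(sensor_mount(lever_arm = r),
                                           board_freq = 1)$board
  w_peak <- 20 * pi / 180 * 2 * pi     # A * 2 pi f at t = 0
  expect_equal(unname(board$acc[1, 2]), -w_peak^2 * 0.1, tolerance = 1e-9)
  # the gyroscope stream is lever-arm independent, bitwise
  tr <- std_traj
  g1 <- project_to_sensor(tr, sensor_mount(c(0, 0.02, -0.02)))$gyr
  g2 <- project_to_sensor(tr, sensor_mount(c(-0.1, 0, 0.03)))$gyr
  expect_identical(g1, g2)
})

test_that("double-integrating the ideal accelerometer recovers the positions", {
  # second-order (trapezoidal) reference integrator: isolates simulator
  # consistency from the pipeline's own first-order scheme
  cumtrapz <- function(a, fs) c(0, cumsum((a[-1] + a[-length(a)]) / 2)) / fs
  st <- std_stream
  ann <- std_traj$annotations
  for (k in c(1, 3)) {
    idx <- ann$n_ms[k]:ann$n_ms_next[k]
    acc_gc <- remove_gravity(st$acc[idx, ], std_traj$quat[idx, ])
    v <- apply(acc_gc, 2, cumtrapz, fs = 200)
    p <- apply(v, 2, cumtrapz, fs = 200)
    truth <- sweep(std_traj$pos[idx, ], 2, std_traj$pos[idx[1], ])
    expect_lt(max(abs(p - truth)), 1e-3)
  }
})

test_that("artifacts are reproducible, seed-driven and monotone in amplitude", {
  tr <- std_traj
  st <- project_to_sensor(tr, sensor_mount(c(-0.1, 0, 0.03)))
  none <- apply_artifacts(st, artifact_model(), tr$annotations)
  expect_identical(none$acc, st$acc)
  a <- artifact_model(impact_amp = 2, acc_noise_sd = 0.1, gyr_noise_sd = 0.01,
                      gyr_bias = 0.004, seed = 99)
  c1 <- apply_artifacts(st, a, tr$annotations)
  c2 <- apply_artifacts(st, a, tr$annotations)
  expect_identical(c1$acc, c2$acc)
  expect_identical(c1$gyr, c2$gyr)
  # the running state of the global RNG is untouched
  set.seed(1); before <- .Random.seed
  invisible(apply_artifacts(st, a, tr$annotations))
  expect_identical(.Random.seed, before)
  # zupt error grows with impact amplitude
  zs <- sapply(c(0, 0.5, 1, 2), function(amp) {
    cs <- apply_artifacts(st, artifact_model(impact_amp = amp, seed = 5),
                          tr$annotations)
    median(sapply(tr$annotations$n_ms, function(nm) zupt_error(cs$acc, nm)))
  })
  expect_true(all(diff(zs) > 0))
})

test_that("cohort generation is countable and byte-stable on disk", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  co <- simulate_cohort(trials_per_bin = c(1, 1, 1, 1), strides_per_trial = 3,
                        seed = 17)
  expect_length(co$trials, 4)
  truth <- do.call(rbind, lapply(co$trials, `[[`, "truth"))
  expect_equal(nrow(truth), 12)      # 4 trials x 3 strides
  expect_setequal(unique(truth$bin), c("2-3", "3-4", "4-5", "5-6"))
  # velocities respect their declared bins
  lo <- as.numeric(substr(truth$bin, 1, 1))
  expect_true(all(truth$v_stride > lo & truth$v_stride < lo + 1))
  write_cohort(co, dir1)
  co2 <- simulate_cohort(trials_per_bin = c(1, 1, 1, 1), strides_per_trial = 3,
                         seed = 17)
  write_cohort(co2, dir2)
  f1 <- list.files(dir1)
  expect_true(all(c("manifest.json", "truth.csv") %in% f1))
  expect_equal(length(grep("^trial", f1)), 16)   # 4 trials x 4 positions
  for (f in f1)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
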