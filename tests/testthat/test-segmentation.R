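triangle_pulse <- function(n, peaks, width = 10, height = 5) {
  x <- numeric(n)
  for (p in peaks) {
    i <- pmax(1, p - width):pmin(n, p + width)
    x[i] <- pmax(x[i], height * (1 - abs(i - p) / width))
  }
  x
}

test_that("swing minima are found on periodic signals and not on flat ones", {
  fs <- 200
  tt <- seq(0, 4, by = 1 / fs)
  A <- 5; T_ <- 0.8
  x <- -A * cos(2 * pi * tt / T_)
  mins <- detect_swing_minima(x, fs)
  # interior minima sit at multiples of the period (the boundary minimum
  # at t = 0 has no left neighbour and is not a local minimum)
  expect_equal((mins - 1) / fs, T_ * seq_along(mins), tolerance = 1e-9)
  expect_gte(length(mins), 4)
  expect_true(all(x[mins] <= -3))
  expect_warning(m0 <- detect_swing_minima(rep(0, 1000), fs), "no swing")
  expect_length(m0, 0)
  # sub-prominence oscillation is ignored
  expect_warning(m1 <- detect_swing_minima(-2 * cos(2 * pi * tt / T_), fs))
  expect_length(m1, 0)
})

test_that("IC detection applies the configured bias to the first maximum", {
  fs <- 200
  x <- triangle_pulse(300, peaks = 100)
  ic <- detect_ic(x, n_sp = 50, fs = fs)
  expect_equal(ic$n_ic_raw, 100)
  expect_equal(ic$n_ic, 98)          # default -10 ms = 2 samples earlier
  ic0 <- detect_ic(x, n_sp = 50, fs = fs,
                   config = segmentation_config(ic_bias_s = 0))
  expect_equal(ic0$n_ic, 100)
  # no maximum within the horizon: stride rejected
  expect_null(detect_ic(rep(0, 300), n_sp = 50, fs = fs))
})

test_that("midstance is the first minimum of the gyroscope norm after IC", {
  fs <- 200
  gyr <- matrix(1, 300, 3)
  gyr[121:131, ] <- 0            # flat zero on [n_ic+20, n_ic+30]
  expect_equal(detect_ms(gyr, n_ic = 101, fs = fs), 121)
  gyr2 <- matrix(0, 300, 3)
  gyr2[, 1] <- c(seq(50, 1, length.out = 125), seq(1, 50, length.out = 175))
  gyr2[126, 1] <- 0.5            # strict minimum at n_ic + 25
  expect_equal(detect_ms(gyr2, n_ic = 101, fs = fs), 126)
  # window running past the signal end rejects the stride
  expect_null(detect_ms(gyr, n_ic = 260, fs = fs))
})

test_that("TO detection finds the next maximum after the raw IC maximum", {
  fs <- 200
  x <- triangle_pulse(400, peaks = c(100, 150))
  expect_equal(detect_to(x, n_ic_raw = 100, fs = fs), 145)  # -24 ms = -5
  expect_equal(detect_to(x, n_ic_raw = 100, fs = fs,
                         config = segmentation_config(to_bias_s = 0)), 150)
  expect_null(detect_to(triangle_pulse(400, peaks = 100), 100, fs))
})

test_that("simulated stride trains segment to the annotated events", {
  tr <- generate_foot_trajectory(std_model, n_strides = 10, fs = 200)
  st <- shoe_stream(tr)
  ev <- segment_strides(st)
  ann <- tr$annotations
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$n_sp - ann$n_sp) <= 2))
  expect_true(all(ev$n_ic == ann$n_ic))
  expect_true(all(ev$n_ms == ann$n_ms))
  expect_true(all(abs(ev$n_to - ann$n_to) <= 1))
  expect_true(all(ev$n_ms_next == ann$n_ms_next))
  # stride time from detected ICs matches ground truth within one sample
  expect_true(all(abs(diff(ev$n_ic) / 200 - ann$t_stride[1]) <= 1 / 200))
  # ground contact time within 15 ms
  expect_true(all(abs((ev$n_to - ev$n_ic) / 200 - ann$t_gc[1]) <= 0.015))
})

test_that("event ordering and disjointness invariants hold on every stride", {
  ev <- segment_strides(std_stream)
  n <- length(std_stream$t)
  for (i in seq_len(nrow(ev)))
    expect_true(validate_stride_events(ev[i, ], n))
  expect_true(all(diff(ev$n_ic) > 0))
  # [n_ic, n_to] intervals are pairwise disjoint
  expect_true(all(ev$n_to[-nrow(ev)] < ev$n_ic[-1]))
})

test_that("degenerate inputs give empty results, not crashes", {
  # reversed-time signal: whatever is returned must still satisfy the
  # event-ordering contract (a periodic train reversed in time can look
  # like a different but internally consistent gait)
  rev_stream <- imu_stream(std_stream$acc[nrow(std_stream$acc):1, ],
                           std_stream$gyr[nrow(std_stream$gyr):1, ],
                           fs = 200, frame = "shoe")
  ev <- suppressWarnings(segment_strides(rev_stream))
  for (i in seq_len(nrow(ev)))
    expect_true(validate_stride_events(ev[i, ], length(rev_stream$t)))
  # single stride cannot form a complete event set
  one <- generate_foot_trajectory(std_model, n_strides = 1, fs = 200)
  short <- shoe_stream(one)
  cut <- imu_window(short, 1, one$annotations$n_to[1])
  cut$frame <- "shoe"
  expect_warning(ev1 <- segment_strides(cut), regexp = ".")
  expect_equal(nrow(ev1), 0)
  # all-zero stream
  zero <- imu_stream(matrix(0, 400, 3), matrix(0, 400, 3), 200, frame = "shoe")
  expect_warning(ev0 <- segment_strides(zero), "no complete strides")
  expect_equal(nrow(ev0), 0)
})

test_that("event times are sampling-rate equivariant", {
  tr200 <- generate_foot_trajectory(std_model, n_strides = 4, fs = 200)
  tr400 <- generate_foot_trajectory(std_model, n_strides = 4, fs = 400)
  ev200 <- segment_strides(shoe_stream(tr200))
  ev400 <- segment_strides(shoe_stream(tr400))
  expect_equal(nrow(ev200), nrow(ev400))
  for (cc in c("n_ic", "n_ms", "n_to")) {
    t200 <- (ev200[[cc]] - 1) / 200
    t400 <- (ev400[[cc]] - 1) / 400
    expect_true(all(abs(t200 - t400) < 1 / 200 + 1e-9))
  }
})

test_that("segmentation survives realistic measurement noise", {
  tr <- generate_foot_trajectory(std_model, n_strides = 5, fs = 200)
  st <- project_to_sensor(tr, sensor_mount(c(-0.10, 0, 0.03)))
  noisy <- apply_artifacts(st, artifact_model(impact_amp = 3,
                                              acc_noise_sd = 0.15,
                                              gyr_noise_sd = 0.01,
                                              gyr_bias = 0.005, seed = 5),
                           tr$annotations)
  noisy$frame <- "shoe"
  ev <- segment_strides(noisy)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$n_ic - tr$annotations$n_ic) <= 2))
})
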