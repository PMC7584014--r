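# Shared fixtures, built once per test run.

# standard mid-speed rearfoot stride train (3 m/s, 5 strides)
std_model <- gait_model(t_stride = 0.75, duty = 0.36, d_stride = 2.25,
                        sole_angle_deg = -10, rom_deg = 9)
std_traj <- generate_foot_trajectory(std_model, n_strides = 5, fs = 200)

# ideal reference stream at the foot reference point, already in shoe frame
shoe_stream <- function(traj = std_traj, mount = sensor_mount()) {
  st <- project_to_sensor(traj, mount)
  st$frame <- "shoe"
  st
}
std_stream <- shoe_stream()

# random unit quaternion (uniform on SO(3) via normalized gaussians)
random_quat <- function() quat_normalize(stats::rnorm(4))

random_rotation <- function() quat_to_matrix(random_quat())

# tilt a unit vector by a given angle in a random direction
tilt_vector <- function(v, angle) {
  p <- stats::rnorm(3)
  p <- p - sum(p * v) * v
  p <- p / sqrt(sum(p^2))
  v * cos(angle) + p * sin(angle)
}
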