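#' Spatio-temporal running parameters
#'
#' Six per-stride parameters: stride time (IC to IC), ground contact time
#' (IC to TO), stride length (planar displacement between consecutive
#' midstances), average stride velocity (stride length over stride time),
#' sole angle (sagittal-plane shoe-sole angle at IC relative to the
#' flat-foot midstance; negative indicates a rearfoot strike), and frontal
#' plane range of motion (eversion excursion during ground contact).
#'
#' @name parameters
NULL

#' Temporal parameters of one stride
#'
#' `t_stride = (n_ic_next - n_ic) / fs`, `t_gc = (n_to - n_ic) / fs`.
#'
#' @param events Named list or single-row data frame with `n_ic`, `n_to`.
#' @param next_ic IC sample index of the following stride.
#' @param fs Sampling rate (Hz).
#' @return Named numeric `(t_stride, t_gc)` in seconds.
#' @export
temporal_parameters <- function(events, next_ic, fs) {
  ev <- as.list(events)
  if (next_ic <= ev$n_to)
    stop("next stride's IC must come after this stride's TO")
  c(t_stride = (next_ic - ev$n_ic) / fs, t_gc = (ev$n_to - ev$n_ic) / fs)
}

#' Spatial parameters of one stride
#'
#' Stride length is the planar (x, y) norm of the translation at the next
#' midstance (level running is assumed, so the z component is ignored);
#' average stride velocity divides it by stride time.
#'
#' @param traj A `stride_trajectory`.
#' @param t_stride Stride time in seconds.
#' @return Named numeric `(d_stride, v_stride)` in m and m/s.
#' @export
spatial_parameters <- function(traj, t_stride) {
  if (t_stride <= 0) stop("t_stride must be positive")
  p <- traj$pos[nrow(traj$pos), ]
  d <- sqrt(p[1]^2 + p[2]^2)
  c(d_stride = unname(d), v_stride = unname(d) / t_stride)
}

#' Sole angle at initial contact
#'
#' Sagittal-plane (roll about the medial/lateral shoe x axis) component of
#' the concatenated Euler sequence at IC, in degrees. Because the sequence
#' is referenced to the flat-foot midstance attitude, this is the angle
#' between the shoe sole and the ground at touchdown; negative values
#' indicate a rearfoot strike.
#'
#' @param euler Concatenated Euler matrix (radians) from
#'   [compute_stride_trajectory()], first row at `n_start`.
#' @param n_ic Global sample index of IC.
#' @param n_start Global sample index of the first euler row (defaults to
#'   `n_ic`).
#' @return Sole angle in degrees.
#' @export
sole_angle <- function(euler, n_ic, n_start = n_ic) {
  row <- n_ic - n_start + 1
  if (row < 1 || row > nrow(euler)) stop("n_ic outside the euler sequence")
  unname(euler[row, "roll"]) * 180 / pi
}

#' Frontal-plane range of motion during ground contact
#'
#' Difference between the maximum and minimum of the frontal-plane angle
#' (pitch about the anterior/posterior shoe y axis) between IC and TO, in
#' degrees; always non-negative.
#'
#' @inheritParams sole_angle
#' @param n_to Global sample index of TO.
#' @return Range of motion in degrees (>= 0).
#' @export
range_of_motion <- function(euler, n_ic, n_to, n_start = n_ic) {
  i0 <- n_ic - n_start + 1
  i1 <- n_to - n_start + 1
  if (i0 < 1 || i1 > nrow(euler) || i0 >= i1)
    stop("[n_ic, n_to] window outside the euler sequence")
  phi <- euler[i0:i1, "pitch"]
  (max(phi) - min(phi)) * 180 / pi
}

#' Analyze a calibrated recording end to end
#'
#' Segments the recording into strides and computes the six spatio-temporal
#' parameters for every complete stride. Strides rejected by segmentation
#' are excluded (never imputed).
#'
#' @param stream Shoe-frame `imu_stream`.
#' @param config A [segmentation_config()].
#' @param g Gravity magnitude (m/s^2).
#' @return Data frame with the event columns of [segment_strides()] plus
#'   `t_stride_s, t_gc_s, d_stride_m, v_stride_mps, sole_angle_deg,
#'   rom_deg`; zero rows if no complete stride is found.
#' @export
analyze_recording <- function(stream, config = segmentation_config(),
                              g = 9.81) {
  ev <- segment_strides(stream, config)
  par_cols <- c("t_stride_s", "t_gc_s", "d_stride_m", "v_stride_mps",
                "sole_angle_deg", "rom_deg")
  if (nrow(ev) == 0) {
    for (cc in par_cols) ev[[cc]] <- numeric(0)
    return(as.data.frame(ev))
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    traj <- compute_stride_trajectory(stream, e, g)
    tp <- temporal_parameters(e, e$n_ic_next, stream$fs)
    sp <- spatial_parameters(traj, tp[["t_stride"]])
    data.frame(
      t_stride_s = tp[["t_stride"]], t_gc_s = tp[["t_gc"]],
      d_stride_m = sp[["d_stride"]], v_stride_mps = sp[["v_stride"]],
      sole_angle_deg = sole_angle(traj$euler, e$n_ic, traj$n_start),
      rom_deg = range_of_motion(traj$euler, e$n_ic, e$n_to, traj$n_start))
  })
  cbind(as.data.frame(ev), do.call(rbind, rows))
}
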