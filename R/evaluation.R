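#' Evaluation of sensor positions
#'
#' Tools to compare raw signals across sensor mounting positions (phase-wise
#' Pearson correlations), to compute signed parameter errors against a gold
#' standard, to quantify zero-velocity-assumption violations, and to
#' aggregate errors into median/IQR summaries by speed bin.
#'
#' @name evaluation
NULL

#' Match strides across positions by IC proximity
#'
#' Recordings of the same run segmented independently per sensor position
#' are matched stride-to-stride: strides whose IC indices agree within half
#' a median stride duration are paired.
#'
#' @param events_list Named list of `stride_events` data frames, one per
#'   position.
#' @return Data frame with one row per matched stride and one column of row
#'   indices (into the respective events frame) per position.
#' @export
match_strides <- function(events_list) {
  stopifnot(length(events_list) >= 2)
  ref <- events_list[[1]]
  if (nrow(ref) == 0) return(data.frame())
  tol <- stats::median(diff(ref$n_ic)) / 2
  if (!is.finite(tol)) tol <- Inf
  out <- data.frame(stride = seq_len(nrow(ref)))
  out[[names(events_list)[1]]] <- seq_len(nrow(ref))
  for (nm in names(events_list)[-1]) {
    ev <- events_list[[nm]]
    idx <- vapply(ref$n_ic, function(ic) {
      if (nrow(ev) == 0) return(NA_integer_)
      j <- which.min(abs(ev$n_ic - ic))
      if (abs(ev$n_ic[j] - ic) <= tol) j else NA_integer_
    }, integer(1))
    out[[nm]] <- idx
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Phase-wise Pearson correlations between sensor positions
#'
#' For every pair of positions, stride, modality (accelerometer, gyroscope),
#' axis and gait phase (full stride `[n_ic, n_ic_next]`, ground contact
#' `[n_ic, n_to]`, swing `[n_to, n_ic_next]`), computes the Pearson
#' correlation of the two raw signal segments. Segments of unequal length
#' (from independently detected events) are truncated to the shorter one.
#' Zero-variance segments yield `NA` with a warning.
#'
#' @param streams Named list of `imu_stream`s, one per position (>= 2).
#' @param events_list Named list of `stride_events` matching `streams`.
#' @return Long data frame of class `phase_correlations` with columns
#'   `pos_a, pos_b, stride, modality, axis, phase, r`.
#' @export
pearson_by_phase <- function(streams, events_list) {
  stopifnot(length(streams) >= 2,
            identical(names(streams), names(events_list)))
  matched <- match_strides(events_list)
  if (nrow(matched) == 0) stop("no strides could be matched across positions")
  positions <- names(streams)
  pairs <- utils::combn(positions, 2, simplify = FALSE)
  phases <- c("full", "ground_contact", "swing")
  axes <- c("x", "y", "z")
  res <- list()
  n_zero_var <- 0
  for (k in seq_len(nrow(matched))) {
    evs <- lapply(positions, function(p)
      events_list[[p]][matched[[p]][k], ])
    names(evs) <- positions
    for (ph in phases) {
      rng <- lapply(evs, function(e) switch(ph,
        full = c(e$n_ic, e$n_ic_next),
        ground_contact = c(e$n_ic, e$n_to),
        swing = c(e$n_to, e$n_ic_next)))
      len <- min(vapply(rng, function(r) r[2] - r[1] + 1, numeric(1)))
      for (pr in pairs) {
        a <- streams[[pr[1]]]; b <- streams[[pr[2]]]
        ia <- rng[[pr[1]]][1] + seq_len(len) - 1
        ib <- rng[[pr[2]]][1] + seq_len(len) - 1
        for (mod in c("acc", "gyr")) {
          ma <- a[[mod]][ia, , drop = FALSE]
          mb <- b[[mod]][ib, , drop = FALSE]
          for (ax in 1:3) {
            xa <- ma[, ax]; xb <- mb[, ax]
            if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
              r <- NA_real_
              n_zero_var <- n_zero_var + 1
            } else {
              r <- stats::cor(xa, xb)
            }
            res[[length(res) + 1]] <- data.frame(
              pos_a = pr[1], pos_b = pr[2], stride = matched$stride[k],
              modality = mod, axis = axes[ax], phase = ph, r = r)
          }
        }
      }
    }
  }
  if (n_zero_var > 0)
    warning(sprintf("%d zero-variance segment(s): correlation recorded as NA",
                    n_zero_var))
  out <- do.call(rbind, res)
  structure(out, class = c("phase_correlations", "data.frame"))
}

#' Signed parameter error against the gold standard
#'
#' `error = sensor - gold`: a positive error is an overestimation.
#' Vectorized elementwise.
#'
#' @param sensor_value Parameter value(s) from the IMU pipeline.
#' @param gold_value Ground-truth value(s), same units.
#' @return Signed error(s).
#' @export
parameter_error <- function(sensor_value, gold_value) {
  sensor_value - gold_value
}

#' Zero-velocity-violation error at midstance
#'
#' L2 norm of the difference between the shoe-frame accelerometer sample at
#' midstance and the pure gravity vector `(0, 0, g)`. Under a perfect
#' zero-velocity phase the accelerometer measures only gravity and the error
#' is zero; movement artifacts at midstance increase it.
#'
#' @param acc N x 3 shoe-frame acceleration (m/s^2) or an `imu_stream`.
#' @param n_ms Midstance sample index.
#' @param g Gravity magnitude (m/s^2).
#' @return Non-negative error in m/s^2.
#' @export
zupt_error <- function(acc, n_ms, g = 9.81) {
  if (inherits(acc, "imu_stream")) acc <- acc$acc
  if (n_ms < 1 || n_ms > nrow(acc)) stop("n_ms outside the stream")
  sqrt(sum((acc[n_ms, ] - c(0, 0, g))^2))
}

#' Assign stride velocities to speed bins
#'
#' @param v Velocities in m/s.
#' @param edges Bin edges, default `2:6` giving the four 1 m/s bins.
#' @return Factor of bin labels like `"2-3"`; values outside the edges are
#'   `NA`.
#' @export
speed_bin <- function(v, edges = 2:6) {
  labs <- paste0(edges[-length(edges)], "-", edges[-1])
  # round away float fuzz so that boundary velocities land in the upper bin
  cut(round(v, 9), breaks = edges, labels = labs, include.lowest = TRUE,
      right = FALSE)
}

#' Aggregate errors into median/IQR summaries
#'
#' Groups a long table of values and reports the median, interquartile range
#' (Q3 - Q1) and the 5th/95th percentiles per cell, using the
#' linear-interpolation (type 7) quantile definition. Missing values
#' propagate as missing cells, never as zeros.
#'
#' @param df Data frame containing the value column and grouping columns.
#' @param value Name of the numeric column to summarize.
#' @param by Character vector of grouping column names.
#' @return Data frame with one row per group and columns `n, median, iqr,
#'   q05, q95`; carries attribute `quantile_type = 7`.
#' @export
aggregate_errors <- function(df, value = "error", by) {
  stopifnot(value %in% names(df), all(by %in% names(df)))
  groups <- df[, by, drop = FALSE]
  split_idx <- split(seq_len(nrow(df)), groups, drop = TRUE)
  rows <- lapply(split_idx, function(idx) {
    x <- df[[value]][idx]
    x <- x[is.finite(x)]
    g <- df[idx[1], by, drop = FALSE]
    if (length(x) == 0) {
      data.frame(g, n = 0L, median = NA_real_, iqr = NA_real_,
                 q05 = NA_real_, q95 = NA_real_, row.names = NULL)
    } else {
      qs <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95),
                            type = 7, names = FALSE)
      data.frame(g, n = length(x), median = qs[3], iqr = qs[4] - qs[2],
                 q05 = qs[1], q95 = qs[5], row.names = NULL)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 7
  out
}
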