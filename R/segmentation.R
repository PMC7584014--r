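#' Stride segmentation configuration
#'
#' Event detection works on the sagittal-plane angular rate: the forward
#' swing shows as a deep minimum, and the maxima that follow it are biased
#' estimates of initial contact (IC) and toe off (TO). The biases correct
#' the detected maxima towards the true events; at 200 Hz the defaults
#' reproduce a 2-sample IC correction and a 24 ms TO correction. Windows are
#' given in seconds and converted with the stream's sampling rate, so data
#' at other rates is handled; at 200 Hz the midstance window spans the
#' conventional 50 samples.
#'
#' @param ic_bias_s Signed correction (s) added to the detected IC maximum
#'   index; default -0.010 shifts it 2 samples earlier at 200 Hz.
#' @param to_bias_s Signed correction (s) added to the detected TO maximum
#'   index; default -0.024.
#' @param ms_window_s Length (s) of the midstance search window after IC;
#'   default 0.250.
#' @param to_window_s Length (s) of the TO search window after the raw IC
#'   maximum; default 0.400.
#' @param swing_min_prominence Minimum depth (rad/s) of the sagittal angular
#'   rate below zero for a swing-phase minimum; default 3.
#' @param min_swing_gap_s Minimum spacing (s) between retained swing minima
#'   (deepest wins); default 0.4.
#' @param peak_window_s Dominance window (s) for the IC/TO maxima: a
#'   candidate maximum counts only if it is the largest sample within this
#'   half-window on both sides, which rejects measurement-noise wiggles
#'   without altering noise-free detections; default 0.06.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ic_bias_s = -0.010, to_bias_s = -0.024,
                                ms_window_s = 0.250, to_window_s = 0.400,
                                swing_min_prominence = 3.0,
                                min_swing_gap_s = 0.4,
                                peak_window_s = 0.06) {
  stopifnot(ms_window_s > 0, to_window_s > 0, min_swing_gap_s > 0,
            abs(ic_bias_s) < 0.1, abs(to_bias_s) < 0.1,
            swing_min_prominence >= 0, peak_window_s >= 0)
  structure(list(ic_bias_s = ic_bias_s, to_bias_s = to_bias_s,
                 ms_window_s = ms_window_s, to_window_s = to_window_s,
                 swing_min_prominence = swing_min_prominence,
                 min_swing_gap_s = min_swing_gap_s,
                 peak_window_s = peak_window_s),
            class = "segmentation_config")
}

# Local extrema of a numeric vector: strictly greater (maxima) or smaller
# (minima) than both neighbours; a plateau takes its first index.
local_extrema <- function(x, maxima = TRUE) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- if (maxima) x else -x
  d <- diff(s)
  # sign of slope, carrying the last nonzero sign through plateaus (so a
  # plateau bounded by rise then fall counts once, at its first sample)
  sg <- sign(d)
  for (i in seq_along(sg)) if (sg[i] == 0 && i > 1) sg[i] <- sg[i - 1]
  idx <- which(diff(sg) < 0) + 1
  # map plateau detections back to the first sample of the plateau
  out <- integer(0)
  for (i in idx) {
    j <- i
    while (j > 1 && s[j - 1] == s[j]) j <- j - 1
    if (j == 1) next
    out <- c(out, j)
  }
  unique(out)
}

# local maxima of x that dominate a +/- w sample neighbourhood; noise
# wiggles on a monotone flank never dominate, true peaks do
dominant_maxima <- function(x, w) {
  cand <- local_extrema(x, maxima = TRUE)
  if (w <= 0) return(cand)
  n <- length(x)
  cand[vapply(cand, function(i)
    x[i] >= max(x[max(1, i - w):min(n, i + w)]), logical(1))]
}

#' Detect swing-phase minima in the sagittal angular rate
#'
#' The forward swing of the foot produces a deep negative excursion of the
#' sagittal-plane angular rate once per stride. Candidate local minima with
#' value at or below `-swing_min_prominence` are retained; minima closer
#' together than `min_swing_gap_s` are resolved in favour of the deeper one.
#'
#' @param gyr_x Sagittal-plane angular rate (rad/s).
#' @param fs Sampling rate (Hz).
#' @param config A [segmentation_config()].
#' @return Strictly increasing integer sample indices, possibly empty (with
#'   a warning).
#' @export
detect_swing_minima <- function(gyr_x, fs, config = segmentation_config()) {
  cand <- local_extrema(gyr_x, maxima = FALSE)
  cand <- cand[gyr_x[cand] <= -config$swing_min_prominence]
  if (length(cand) == 0) {
    warning("no swing-phase minima found")
    return(integer(0))
  }
  min_gap <- round(config$min_swing_gap_s * fs)
  keep <- integer(0)
  for (i in cand[order(gyr_x[cand])]) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect initial contact after a swing-phase minimum
#'
#' IC is the first local maximum of the sagittal angular rate after the
#' swing minimum, shifted by the configured bias (`round(ic_bias_s * fs)`
#' samples) and clipped to the signal range.
#'
#' @inheritParams detect_swing_minima
#' @param n_sp Swing-phase minimum sample index.
#' @param max_search_s Give up if no maximum occurs within this horizon (s).
#' @return List with `n_ic` (bias-corrected index) and `n_ic_raw` (index of
#'   the detected maximum), or `NULL` if no maximum is found.
#' @export
detect_ic <- function(gyr_x, n_sp, fs, config = segmentation_config(),
                      max_search_s = 1) {
  horizon <- min(length(gyr_x), n_sp + round(max_search_s * fs))
  if (horizon - n_sp < 2) return(NULL)
  seg <- gyr_x[n_sp:horizon]
  m <- dominant_maxima(seg, round(config$peak_window_s * fs))
  if (length(m) == 0) return(NULL)
  n_ic_raw <- n_sp + m[1] - 1
  n_ic <- n_ic_raw + round(config$ic_bias_s * fs)
  n_ic <- max(1, min(length(gyr_x), n_ic))
  list(n_ic = n_ic, n_ic_raw = n_ic_raw)
}

#' Detect midstance after initial contact
#'
#' Midstance is the minimum of the gyroscope L2 norm in a window after IC
#' (ties resolved to the first index). During midstance the foot is flat and
#' momentarily stationary, which anchors the zero-velocity update.
#'
#' @param gyr N x 3 angular rate matrix (rad/s).
#' @inheritParams detect_swing_minima
#' @param n_ic Bias-corrected IC sample index.
#' @return Midstance sample index, or `NULL` if the window exceeds the
#'   signal end.
#' @export
detect_ms <- function(gyr, n_ic, fs, config = segmentation_config()) {
  w <- round(config$ms_window_s * fs)
  if (n_ic + w > nrow(gyr)) return(NULL)
  nrm <- sqrt(rowSums(gyr[n_ic:(n_ic + w), , drop = FALSE]^2))
  n_ic + which.min(nrm) - 1
}

#' Detect toe off after the raw IC maximum
#'
#' TO is the first local maximum of the sagittal angular rate strictly after
#' the uncorrected IC maximum within `to_window_s`, shifted by the
#' configured bias.
#'
#' @inheritParams detect_swing_minima
#' @param n_ic_raw Index of the uncorrected IC maximum.
#' @return Bias-corrected TO index, or `NULL` if no maximum lies in the
#'   window.
#' @export
detect_to <- function(gyr_x, n_ic_raw, fs, config = segmentation_config()) {
  w <- round(config$to_window_s * fs)
  horizon <- min(length(gyr_x), n_ic_raw + w)
  if (horizon - n_ic_raw < 2) return(NULL)
  seg <- gyr_x[n_ic_raw:horizon]
  m <- dominant_maxima(seg, round(config$peak_window_s * fs))
  m <- m[m > 1]
  if (length(m) == 0) return(NULL)
  n_to_raw <- n_ic_raw + m[1] - 1
  n_to <- n_to_raw + round(config$to_bias_s * fs)
  max(1, min(length(gyr_x), n_to))
}

#' Segment a shoe-frame recording into strides
#'
#' Runs the full event cascade (swing minimum, IC, midstance, TO) over the
#' recording and assembles per-stride event sets. A stride is complete when
#' all its own events plus the next stride's midstance (`n_ms_next`, the end
#' of the integration interval) and next IC (`n_ic_next`, needed for stride
#' time) are available; incomplete trailing strides are dropped. Strides
#' violating the event ordering `n_sp < n_ic <= n_ms < n_to < n_ms_next`
#' are rejected with a message.
#'
#' @param stream An `imu_stream` with `frame == "shoe"`.
#' @param config A [segmentation_config()].
#' @return Data frame of class `stride_events` with columns `stride_id,
#'   n_sp, n_ic_raw, n_ic, n_ms, n_to, n_ms_next, n_ic_next`; zero rows
#'   (with a warning) if fewer than two complete strides are found.
#' @export
segment_strides <- function(stream, config = segmentation_config()) {
  if (stream$frame != "shoe")
    stop("segment_strides expects a shoe-frame stream; run align_stream first")
  gx <- stream$gyr[, 1]
  fs <- stream$fs
  empty <- structure(
    data.frame(stride_id = integer(0), n_sp = integer(0),
               n_ic_raw = integer(0), n_ic = integer(0), n_ms = integer(0),
               n_to = integer(0), n_ms_next = integer(0),
               n_ic_next = integer(0)),
    class = c("stride_events", "data.frame"))
  sps <- suppressWarnings(detect_swing_minima(gx, fs, config))
  if (length(sps) < 2) {
    warning("fewer than 2 swing minima: no complete strides")
    return(empty)
  }
  # per swing minimum: IC (raw + corrected), MS, TO
  recs <- lapply(sps, function(sp) {
    ic <- detect_ic(gx, sp, fs, config)
    if (is.null(ic)) return(NULL)
    ms <- detect_ms(stream$gyr, ic$n_ic, fs, config)
    if (is.null(ms)) return(NULL)
    to <- detect_to(gx, ic$n_ic_raw, fs, config)
    if (is.null(to)) return(NULL)
    c(n_sp = sp, n_ic_raw = ic$n_ic_raw, n_ic = ic$n_ic, n_ms = ms, n_to = to)
  })
  ok <- !vapply(recs, is.null, logical(1))
  recs <- do.call(rbind, recs[ok])
  if (is.null(recs) || nrow(recs) < 2) {
    warning("fewer than 2 complete strides detected")
    return(empty)
  }
  n <- nrow(recs)
  ev <- data.frame(stride_id = seq_len(n - 1),
                   recs[seq_len(n - 1), , drop = FALSE],
                   n_ms_next = recs[2:n, "n_ms"],
                   n_ic_next = recs[2:n, "n_ic"])
  valid <- with(ev, n_sp < n_ic & n_ic <= n_ms & n_ms < n_to &
                  n_to < n_ms_next & n_ms_next <= length(gx))
  if (any(!valid))
    message(sprintf("dropping %d stride(s) violating event ordering",
                    sum(!valid)))
  ev <- ev[valid, , drop = FALSE]
  ev$stride_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  structure(ev, class = c("stride_events", "data.frame"))
}

#' Validate a single stride's event ordering
#' @param events One row of a `stride_events` data frame (or a named list).
#' @param n_samples Total samples in the parent stream.
#' @return `TRUE` if the ordering invariant holds.
#' @export
validate_stride_events <- function(events, n_samples = Inf) {
  with(as.list(events),
       isTRUE(n_sp < n_ic && n_ic <= n_ms && n_ms < n_to &&
                n_to < n_ms_next && n_sp >= 1 && n_ms_next <= n_samples))
}
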