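# Gait event detection, stride segmentation, joint angles, filtering,
# differentiation and gait-cycle time normalization.

#' Detect right heel strikes from the vertical GRF
#'
#' Finds upward crossings of the vertical force through `threshold`,
#' debounced by a 50 ms refractory window, then refines each crossing back
#' to the onset of its contiguous contact region (the first frame with
#' `f_vert > 0`), so that on clean force records the returned frame is the
#' mechanical instant of initial contact rather than the slightly later
#' threshold crossing.
#'
#' @param grf A [force_table].
#' @param threshold Contact threshold in N (> 0). Default 20.
#' @return Integer vector of heel-strike frame indices (1-based).
#' @export
detect_heel_strikes <- function(grf, threshold = 20) {
  if (!inherits(grf, "force_table")) {
    stop("`grf` must be a force_table", call. = FALSE)
  }
  stopifnot_scalar_number(threshold, "threshold", positive = TRUE)
  f <- grf$f_vert
  n <- length(f)
  above <- f >= threshold
  crossings <- which(above & !c(FALSE, above[-n]))
  if (length(crossings) > 1L) {
    refractory <- max(1L, round(0.05 * grf$sampling_rate))
    keep <- c(TRUE, diff(crossings) > refractory)
    crossings <- crossings[keep]
  }
  # refine each crossing to the onset of its positive-support region
  onsets <- vapply(crossings, function(ic) {
    j <- ic
    while (j > 1L && f[j - 1L] > 0) j <- j - 1L
    j
  }, integer(1))
  onsets <- unique(onsets)
  if (length(onsets) < 2L) {
    stop(sprintf("segmentation error: %d heel strike(s) found (need >= 2); threshold %g N, max f_vert %g N",
                 length(onsets), threshold, max(f)), call. = FALSE)
  }
  onsets
}

#' Detect the toe-off frame within a stride
#'
#' Finds the last frame with `f_vert > threshold` strictly before the
#' closing heel strike, refined forward to the end of its contiguous
#' contact region (the last frame with `f_vert > 0`), i.e. the final frame
#' of ground contact.
#'
#' @param grf A [force_table].
#' @param heel_strike_1,heel_strike_2 Frame indices bounding the stride.
#' @param threshold Contact threshold in N (> 0). Default 20.
#' @return Toe-off frame index (1-based).
#' @export
detect_toe_off <- function(grf, heel_strike_1, heel_strike_2,
                           threshold = 20) {
  if (!inherits(grf, "force_table")) {
    stop("`grf` must be a force_table", call. = FALSE)
  }
  stopifnot_scalar_number(threshold, "threshold", positive = TRUE)
  f <- grf$f_vert
  # require a downward crossing: some frame > threshold followed by one <=
  window <- seq.int(heel_strike_1, heel_strike_2 - 1L)
  hi <- window[f[window] > threshold]
  if (length(hi) == 0L) {
    stop("segmentation error: no force above threshold between heel strikes",
         call. = FALSE)
  }
  last_hi <- max(hi)
  if (all(f[seq.int(last_hi, heel_strike_2 - 1L)] > threshold)) {
    stop("segmentation error: foot never leaves the ground before the closing heel strike",
         call. = FALSE)
  }
  j <- last_hi
  while (j < heel_strike_2 - 1L && f[j + 1L] > 0) j <- j + 1L
  j
}

#' Segment the first complete right-side stride
#'
#' @param grf A [force_table].
#' @param threshold Contact threshold in N. Default 20.
#' @return An object of class `stride_segment`: `heel_strike_1`, `toe_off`,
#'   `heel_strike_2` (frame indices), `duration` (s), `stance_fraction`.
#' @export
segment_stride <- function(grf, threshold = 20) {
  hs <- detect_heel_strikes(grf, threshold)
  hs1 <- hs[1L]
  hs2 <- hs[2L]
  to <- detect_toe_off(grf, hs1, hs2, threshold)
  if (!(hs1 < to && to < hs2)) {
    stop("segmentation error: events not ordered heel-strike < toe-off < heel-strike",
         call. = FALSE)
  }
  structure(list(
    heel_strike_1 = hs1, toe_off = to, heel_strike_2 = hs2,
    duration = (hs2 - hs1) / grf$sampling_rate,
    stance_fraction = (to - hs1 + 1L) / (hs2 - hs1)
  ), class = "stride_segment")
}

# Axis angle of a downward-pointing segment, measured from straight down,
# positive forward (degrees). d is an n-by-2 matrix of (dx, dy).
axis_angle_from_down <- function(dx, dy) {
  len <- sqrt(dx^2 + dy^2)
  if (any(len < 1e-9)) {
    stop("numerical degeneracy: coincident markers give a zero-length segment",
         call. = FALSE)
  }
  atan2(dx, -dy) * 180 / pi
}

#' Compute sagittal-plane joint angles from markers
#'
#' Planar flexion angles in degrees, flexion positive:
#' * hip: thigh axis (RHIP to RKNEE) relative to the trunk line (SACRUM to
#'   RHIP, extended);
#' * knee: deviation of the shank (RKNEE to RANKLE) from the straight
#'   continuation of the thigh;
#' * ankle: angle between the foot axis (RHEEL to RTOE) and the shank,
#'   minus the 90-degree neutral (dorsiflexion positive).
#'
#' Only the X (forward) and Y (vertical) marker coordinates enter; the
#' angles are invariant to rigid translation and rotation of the marker
#' set within the sagittal plane.
#'
#' @param markers A [marker_table] containing SACRUM, RHIP, RKNEE, RANKLE,
#'   RHEEL, RTOE.
#' @return A data.frame with columns `ankle`, `knee`, `hip` (degrees), one
#'   row per frame.
#' @export
compute_joint_angles <- function(markers) {
  if (!inherits(markers, "marker_table")) {
    stop("`markers` must be a marker_table", call. = FALSE)
  }
  check_required_markers(markers)
  m <- markers$markers
  a_trunk <- axis_angle_from_down(m$RHIP[, "X"] - m$SACRUM[, "X"],
                                  m$RHIP[, "Y"] - m$SACRUM[, "Y"])
  a_thigh <- axis_angle_from_down(m$RKNEE[, "X"] - m$RHIP[, "X"],
                                  m$RKNEE[, "Y"] - m$RHIP[, "Y"])
  a_shank <- axis_angle_from_down(m$RANKLE[, "X"] - m$RKNEE[, "X"],
                                  m$RANKLE[, "Y"] - m$RKNEE[, "Y"])
  fdx <- m$RTOE[, "X"] - m$RHEEL[, "X"]
  fdy <- m$RTOE[, "Y"] - m$RHEEL[, "Y"]
  flen <- sqrt(fdx^2 + fdy^2)
  if (any(flen < 1e-9)) {
    stop("numerical degeneracy: coincident markers give a zero-length segment",
         call. = FALSE)
  }
  a_foot <- atan2(fdy, fdx) * 180 / pi     # from horizontal, toe-up positive
  data.frame(
    ankle = a_foot - a_shank,
    knee = a_thigh - a_shank,
    hip = a_thigh - a_trunk
  )
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter (order `order`, cutoff `cutoff`
#' Hz; the single-pass magnitude is exactly -3 dB at the cutoff) and
#' applies it forward and backward (`passes = 2`, the default) for zero
#' phase lag, or forward only (`passes = 1`). Endpoint transients are
#' handled by odd-reflection padding of one second (or the series length,
#' whichever is shorter) at each end.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate, Hz. Must exceed `2 * cutoff`.
#' @param order Filter order. Default 3.
#' @param cutoff Cutoff frequency, Hz. Default 6.
#' @param passes 1 (single pass) or 2 (zero-phase forward-backward,
#'   default; squares the magnitude response, so the cutoff attenuation
#'   becomes 1/2).
#' @return Filtered numeric vector of the same length.
#' @export
lowpass_filter <- function(series, fs, order = 3, cutoff = 6, passes = 2) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (fs <= 2 * cutoff) {
    stop("`fs` must exceed 2 * cutoff", call. = FALSE)
  }
  if (!passes %in% c(1, 2)) stop("`passes` must be 1 or 2", call. = FALSE)
  n <- length(series)
  if (n <= 3 * order) {
    stop(sprintf("series too short to filter: length %d <= 3 * order", n),
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(round(fs), n - 1L)
  # odd reflection about the end points suppresses edge transients
  head_pad <- 2 * series[1L] - series[seq.int(pad + 1L, 2L)]
  tail_pad <- 2 * series[n] - series[seq.int(n - 1L, n - pad)]
  x <- c(head_pad, series, tail_pad)
  y <- as.numeric(signal::filter(bf, x))
  if (passes == 2) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  y[seq.int(pad + 1L, pad + n)]
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Central differences in the interior, second-order one-sided stencils at
#' the end points. Exact for linear series; apply twice for the second
#' derivative.
#'
#' @param series Numeric vector of length >= 3.
#' @param fs Sampling rate, Hz.
#' @return Derivative series in units of `series` per second.
#' @export
differentiate <- function(series, fs) {
  n <- length(series)
  if (n < 3L) stop("`series` must have length >= 3", call. = FALSE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  d <- numeric(n)
  d[2:(n - 1L)] <- (series[3:n] - series[1:(n - 2L)]) * fs / 2
  d[1L] <- (-3 * series[1L] + 4 * series[2L] - series[3L]) * fs / 2
  d[n] <- (3 * series[n] - 4 * series[n - 1L] + series[n - 2L]) * fs / 2
  d
}

#' Resample a stride-locked series onto the 0-100% gait cycle
#'
#' Linear interpolation onto `n_points` equispaced samples (101 by
#' default, the standard gait-cycle convention). Endpoints are preserved
#' exactly.
#'
#' @param series Numeric vector of length >= 2.
#' @param n_points Number of output samples. Default 101.
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(series, n_points = 101L) {
  n <- length(series)
  if (n < 2L) stop("`series` must have length >= 2", call. = FALSE)
  if (n == n_points) return(series)
  stats::approx(seq(0, 1, length.out = n), series,
                xout = seq(0, 1, length.out = n_points))$y
}
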