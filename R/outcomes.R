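# Outcome measures: joint power, mechanical work, peaks, and assembly of
# the speed-by-load outcome grid.

#' Joint power from torque and angular velocity
#'
#' Element-wise product of torque and angular velocity, with the angular
#' velocity converted from deg/s to rad/s so that Nm/kg times rad/s yields
#' W/kg. Positive power is energy generation, negative is absorption.
#'
#' @param torque Torque series (Nm or Nm/kg).
#' @param angular_velocity Angular velocity series, deg/s, same length.
#' @return Power series (W or W/kg).
#' @export
joint_power <- function(torque, angular_velocity) {
  if (length(torque) != length(angular_velocity)) {
    stop("`torque` and `angular_velocity` must have the same length",
         call. = FALSE)
  }
  torque * angular_velocity * pi / 180
}

#' Mechanical work over a stride
#'
#' Trapezoidal time integral of the joint power. `mode = "total"` (the
#' default) integrates the absolute power, counting generation and
#' absorption alike; `mode = "net"` integrates the signed power.
#'
#' @param power Power series (W or W/kg), length >= 2.
#' @param fs Sampling rate, Hz.
#' @param mode `"total"` or `"net"`.
#' @return Scalar work (J or J/kg); non-negative for `mode = "total"`.
#' @export
mechanical_work <- function(power, fs, mode = c("total", "net")) {
  mode <- match.arg(mode)
  if (length(power) < 2L) {
    stop("`power` must have length >= 2", call. = FALSE)
  }
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  y <- if (mode == "total") abs(power) else power
  trapz(y, 1 / fs)
}

#' Peak value of a series (maximum magnitude)
#'
#' Returns the largest absolute value over the series; the sign of the
#' extremum is attached as attribute `"sign"`.
#'
#' @param series Non-empty numeric vector.
#' @param mode `"magnitude"` (default) or `"signed"` (plain maximum).
#' @return Scalar peak; for `"magnitude"` it is `>= 0` with a `"sign"`
#'   attribute in `{-1, 0, 1}`.
#' @export
peak_value <- function(series, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  if (length(series) == 0L) stop("`series` must be non-empty", call. = FALSE)
  if (mode == "signed") return(max(series))
  i <- which.max(abs(series))
  structure(abs(series[i]), sign = sign(series[i]))
}

#' Process one gait trial under one load condition
#'
#' Runs the full single-trial pipeline: gait events are detected on the
#' trial's unloaded GRF (the load changes forces, never the kinematics or
#' the stride timing), one complete right stride is segmented, marker
#' series are low-pass filtered, joint angles are computed and filtered,
#' angular velocity and acceleration follow by differentiation, the GRF is
#' scaled for the carried load, the Newton-Euler recursion yields joint
#' moments, moments are filtered with the same Butterworth settings and
#' normalized by body mass, and power, work and peaks are extracted.
#'
#' @param trial A `gait_trial`.
#' @param subject The matching [anthropometry] object.
#' @param load Carried load, kg.
#' @param config A [study_config] (filter settings, thresholds,
#'   conventions); defaults to `study_config()`.
#' @return A list with `records` (data.frame: one row per joint with
#'   `subject_id`, `speed`, `load`, `joint`, `peak_torque`,
#'   `peak_torque_sign`, `peak_power`, `peak_power_sign`, `work`),
#'   `stride` (the [segment_stride] result), and `waveforms` (per joint:
#'   101-point normalized angle, angular velocity, torque and power).
#' @export
process_trial <- function(trial, subject, load = 0,
                          config = study_config()) {
  if (!inherits(trial, "gait_trial")) {
    stop("`trial` must be a gait_trial", call. = FALSE)
  }
  fs <- trial$markers$sampling_rate
  stride <- segment_stride(trial$grf, threshold = config$event_threshold)
  span <- seq.int(stride$heel_strike_1, stride$heel_strike_2)

  filt <- function(x) lowpass_filter(x, fs, order = config$filter_order,
                                     cutoff = config$filter_cutoff,
                                     passes = config$filter_passes)
  # filter marker coordinates over the full trial, then crop the stride
  fm <- lapply(trial$markers$markers, function(m) {
    cbind(X = filt(m[, "X"]), Y = filt(m[, "Y"]), Z = m[, "Z"])
  })
  markers_f <- marker_table(fs, fm, time = trial$markers$time)

  angles <- compute_joint_angles(markers_f)
  angles <- as.data.frame(lapply(angles, filt))

  states <- segment_states(markers_f, subject, fs)
  grf_loaded <- scale_grf(trial$grf, load, subject$mass)
  dyn <- newton_euler_bottom_up(states, grf_loaded,
                                gravity = config$gravity)
  torque_f <- as.data.frame(lapply(dyn$torque, filt))

  joints <- c("ankle", "knee", "hip")
  records <- list()
  waveforms <- list()
  for (j in joints) {
    ang <- angles[[j]][span]
    omega <- differentiate(ang, fs)                     # deg/s
    tau <- normalize_torque(torque_f[[j]][span], subject$mass)
    pw <- joint_power(tau, omega)
    pk_t <- peak_value(tau, mode = config$peak_mode)
    pk_p <- peak_value(pw, mode = config$peak_mode)
    records[[j]] <- data.frame(
      subject_id = trial$subject_id, speed = trial$speed, load = load,
      joint = j,
      peak_torque = as.numeric(pk_t),
      peak_torque_sign = attr(pk_t, "sign") %||% NA_real_,
      peak_power = as.numeric(pk_p),
      peak_power_sign = attr(pk_p, "sign") %||% NA_real_,
      work = mechanical_work(pw, fs, mode = config$work_mode),
      stringsAsFactors = FALSE
    )
    waveforms[[j]] <- list(
      angle = time_normalize(ang),
      angular_velocity = time_normalize(omega),
      torque = time_normalize(tau),
      power = time_normalize(pw)
    )
  }
  list(records = do.call(rbind, c(records, list(make.row.names = FALSE))),
       stride = stride, waveforms = waveforms)
}

#' Assemble the speed-by-load outcome grid
#'
#' Runs [process_trial()] for every trial and every load and stacks the
#' per-joint outcome records. Trials whose stride segmentation fails are
#' skipped with a warning; the assembled grid is then checked for
#' completeness (every subject x speed x load x joint combination present
#' exactly once) and an error lists any missing cells.
#'
#' @param trials List of `gait_trial` objects (all subjects x speeds).
#' @param cohort Named list of [anthropometry] objects, indexed by
#'   `subject_id`.
#' @param loads Numeric vector of carried loads, kg (non-empty).
#' @param config A [study_config].
#' @return A data.frame of outcome records (class `outcome_grid`).
#' @export
build_outcome_grid <- function(trials, cohort, loads = default_loads(),
                               config = study_config()) {
  if (length(loads) == 0L) stop("`loads` must be non-empty", call. = FALSE)
  rows <- list()
  for (trial in trials) {
    subject <- cohort[[trial$subject_id]]
    if (is.null(subject)) {
      stop(sprintf("no anthropometry for subject '%s'", trial$subject_id),
           call. = FALSE)
    }
    for (load in loads) {
      rec <- tryCatch(
        process_trial(trial, subject, load, config)$records,
        error = function(e) {
          warning(sprintf("skipping %s @ %.1f km/h, load %g kg: %s",
                          trial$subject_id, trial$speed, load,
                          conditionMessage(e)), call. = FALSE)
          NULL
        }
      )
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
    }
  }
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  check_grid_complete(grid,
                      subjects = unique(vapply(trials, `[[`, "", "subject_id")),
                      speeds = unique(vapply(trials, `[[`, 0, "speed")),
                      loads = loads)
  class(grid) <- c("outcome_grid", class(grid))
  grid
}

# Error if any subject x speed x load x joint cell is absent or duplicated.
check_grid_complete <- function(grid, subjects, speeds, loads,
                                joints = c("ankle", "knee", "hip")) {
  expected <- expand.grid(subject_id = subjects, speed = speeds,
                          load = loads, joint = joints,
                          stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$speed, d$load, d$joint,
                           sep = "|")
  have <- table(key(grid))
  want <- key(expected)
  missing <- setdiff(want, names(have))
  dup <- names(have)[have > 1L]
  if (length(missing) > 0L || length(dup) > 0L) {
    stop(sprintf("incomplete outcome grid: %d missing cell(s)%s%s",
                 length(missing),
                 if (length(missing) > 0L) paste0(" (first: ", missing[1L], ")") else "",
                 if (length(dup) > 0L) sprintf("; %d duplicated", length(dup)) else ""),
         call. = FALSE)
  }
  invisible(grid)
}
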