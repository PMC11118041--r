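# Synthetic joint-angle and GRF templates over the gait cycle.
#
# Angle templates are truncated Fourier series (order 6) fitted to
# periodic-spline shapes through normative keypoints, then calibrated with
# an exact affine correction so that three kinematic landmarks are hit at
# the reference speed of 4 km/h: knee swing-phase maximum 71 deg, ankle
# flexion at toe-off 20 deg, hip stance-phase extension -15 deg (flexion
# positive, extension negative). The knee swing peak grows and occurs
# earlier as speed increases; the ankle profile is speed-invariant; the hip
# profile shifts slightly with the stance fraction.

FOURIER_ORDER <- 6L

#' Stance fraction of the gait cycle as a function of speed
#'
#' Linear from 0.70 at 1 km/h to 0.60 at 4 km/h (slower walking spends a
#' larger share of the cycle in stance), clamped to `[0.55, 0.75]` outside
#' the study speed range.
#'
#' @param speed Walking speed in km/h.
#' @return Stance fraction in `(0, 1)`.
#' @export
stance_fraction <- function(speed) {
  pmin(0.75, pmax(0.55, 0.70 - 0.10 * (speed - 1) / 3))
}

# Fourier design matrix for phases in [0, 1).
fourier_design <- function(phase, order = FOURIER_ORDER) {
  cols <- list(rep(1, length(phase)))
  for (k in seq_len(order)) {
    cols[[length(cols) + 1L]] <- cos(2 * pi * k * phase)
    cols[[length(cols) + 1L]] <- sin(2 * pi * k * phase)
  }
  do.call(cbind, cols)
}

fourier_eval <- function(coef, phase, order = FOURIER_ORDER) {
  drop(fourier_design(phase %% 1, order) %*% coef)
}

# Fit an order-6 Fourier series to a periodic spline through keypoints.
# keys: data.frame(phase, value); phase in [0, 1), value in degrees.
fit_joint_template <- function(keys) {
  ord <- order(keys$phase)
  px <- keys$phase[ord]
  py <- keys$value[ord]
  # close the cycle for the periodic spline
  dense_x <- seq(0, 1, length.out = 241)[-241]
  dense_y <- stats::spline(c(px, px[1] + 1), c(py, py[1]),
                           method = "periodic", xout = dense_x)$y
  X <- fourier_design(dense_x)
  stats::lm.fit(X, dense_y)$coefficients
}

# Speed-dependent keypoints, degrees, flexion positive.
template_keypoints <- function(speed) {
  sf <- stance_fraction(speed)
  knee_peak <- max(30, 71 - 4 * (4 - speed))       # grows with speed
  knee_peak_phase <- pmin(0.85, pmax(0.65, 0.78 - 0.02 * (speed - 1)))
  list(
    ankle = data.frame(
      phase = c(0.00, 0.10, 0.35, sf, sf + 0.15, 0.95),
      value = c(0, -5, 8, 20, -5, -1)
    ),
    knee = data.frame(
      phase = c(0.00, 0.15, 0.40, sf, knee_peak_phase, 0.92),
      value = c(5, 18, 8, 38, knee_peak, 20)
    ),
    hip = data.frame(
      phase = c(0.00, 0.25, 0.87 * sf, sf, 0.85, 0.97),
      value = c(30, 10, -15, -10, 32, 31)
    )
  )
}

#' Build the joint-angle templates for one walking speed
#'
#' Returns smooth, exactly periodic flexion-angle waveforms (degrees,
#' flexion positive / extension negative) for the ankle, knee and hip over
#' the 0-100% gait cycle, calibrated so that the knee swing-phase maximum,
#' the ankle angle at toe-off, and the hip stance-phase extension hit their
#' reference landmarks (71, 20 and -15 degrees at 4 km/h; the knee peak
#' scales down and occurs later at slower speeds).
#'
#' @param speed Walking speed in km/h, in `(0, 8]`.
#' @return An object of class `angle_templates` with fields `speed`,
#'   `stance_fraction`, and per-joint Fourier coefficients plus affine
#'   calibration constants. Evaluate with [template_value()].
#' @export
angle_templates <- function(speed) {
  if (!is.numeric(speed) || length(speed) != 1L || !is.finite(speed) ||
      speed <= 0 || speed > 8) {
    stop("`speed` must be in (0, 8] km/h", call. = FALSE)
  }
  sf <- stance_fraction(speed)
  keys <- template_keypoints(speed)
  grid <- seq(0, 1, by = 5e-4)
  joints <- lapply(names(keys), function(j) {
    coef <- fit_joint_template(keys[[j]])
    raw <- fourier_eval(coef, grid)
    scale <- 1
    shift <- 0
    if (j == "knee") {
      target <- max(30, 71 - 4 * (4 - speed))
      swing_max <- max(raw[grid > sf])
      scale <- target / swing_max
    } else if (j == "ankle") {
      shift <- 20 - fourier_eval(coef, sf)
    } else if (j == "hip") {
      stance_min <- min(raw[grid <= sf])
      shift <- -15 - stance_min
    }
    list(coef = coef, scale = scale, shift = shift)
  })
  names(joints) <- names(keys)
  structure(list(speed = speed, stance_fraction = sf, joints = joints),
            class = "angle_templates")
}

#' Evaluate a joint-angle template
#'
#' @param templates An [angle_templates] object.
#' @param joint One of `"ankle"`, `"knee"`, `"hip"`.
#' @param phase Gait-cycle phase in cycles (0 = heel strike, 1 = next heel
#'   strike); values are wrapped modulo 1, so phase 1 returns exactly the
#'   phase-0 value.
#' @return Flexion angle(s) in degrees.
#' @export
template_value <- function(templates, joint, phase) {
  if (!inherits(templates, "angle_templates")) {
    stop("`templates` must come from angle_templates()", call. = FALSE)
  }
  joint <- match.arg(joint, c("ankle", "knee", "hip"))
  j <- templates$joints[[joint]]
  j$scale * fourier_eval(j$coef, phase %% 1) + j$shift
}

# Normalized double-hump vertical-support shape over stance time tau in
# [0, 1]: sin(pi tau) * (1 + 0.5 cos(2 pi tau)) -- two maxima bracketing a
# midstance valley, zero at stance boundaries.
grf_vertical_shape <- function(tau) {
  sin(pi * tau) * (1 + 0.5 * cos(2 * pi * tau))
}

#' Synthetic ground-reaction-force template for one stride
#'
#' Generates the GRF of one full stride (stance then swing) at 200 Hz under
#' a single-leg bookkeeping convention: the recorded leg's vertical impulse
#' over the full stride equals `mass * g * stride_duration` (the one leg
#' stands in for both, so double support is not modelled and peak vertical
#' force is correspondingly higher than experimental single-leg records).
#' The vertical component is a double-hump curve supported on the stance
#' portion; the sagittal component is braking-then-propulsion with zero net
#' impulse; the medio-lateral component stays below 10% body weight; the
#' centre of pressure progresses monotonically heel to toe during stance.
#'
#' @param speed Walking speed in km/h (> 0); sets the stance fraction.
#' @param mass Supported body mass in kg (> 0).
#' @param stride_duration Stride duration in s (> 0).
#' @param fs Sampling rate, Hz. Default 200.
#' @param gravity Gravitational acceleration, m/s^2. Default 9.81.
#' @return A [force_table] covering one stride.
#' @export
grf_template <- function(speed, mass, stride_duration, fs = 200,
                         gravity = 9.81) {
  stopifnot_scalar_number(speed, "speed", positive = TRUE)
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  stopifnot_scalar_number(stride_duration, "stride_duration",
                          positive = TRUE)
  n <- max(4L, round(stride_duration * fs))
  sf <- stance_fraction(speed)
  n_st <- max(2L, round(sf * n))
  stance <- grf_stance_profile(n, n_st, mass, stride_duration, fs, gravity)
  force_table(fs,
              f_vert = stance$f_vert, f_sag = stance$f_sag,
              f_ml = stance$f_ml,
              cop_x = stance$cop_rel * 0.2, cop_y = rep(0, n))
}

# Shared stance-profile builder: returns full-stride series with stance
# occupying frames 1..n_st. cop_rel is 0..1 progression within stance,
# 0 elsewhere. Amplitude is normalized so the discrete vertical impulse
# over the stride equals mass * g * stride_duration.
grf_stance_profile <- function(n, n_st, mass, stride_duration, fs, gravity) {
  tau <- seq_len(n_st) / (n_st + 1)   # strictly inside (0, 1): f_vert > 0
  shape <- grf_vertical_shape(tau)
  amp <- mass * gravity * stride_duration / (sum(shape) / fs)
  f_vert <- numeric(n)
  f_sag <- numeric(n)
  f_ml <- numeric(n)
  cop_rel <- numeric(n)
  f_vert[seq_len(n_st)] <- amp * shape
  f_sag[seq_len(n_st)] <- -0.06 * amp * sin(2 * pi * tau)
  f_ml[seq_len(n_st)] <- 0.04 * mass * gravity * sin(pi * tau)
  cop_rel[seq_len(n_st)] <- (tau - tau[1]) / (tau[n_st] - tau[1])
  list(f_vert = f_vert, f_sag = f_sag, f_ml = f_ml, cop_rel = cop_rel,
       amp = amp)
}
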