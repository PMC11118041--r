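# Synthetic gait-trial generator: forward kinematics of a planar
# trunk-thigh-shank-foot chain driven by the joint-angle templates, plus a
# template-consistent GRF with ground-truth gait events.
#
# Geometry (sagittal plane, X forward, Y up):
#   - the trunk is held vertical: SACRUM sits directly above RHIP;
#   - segment axis angles are measured from straight down, positive
#     forward, so hip flexion = thigh angle, knee flexion = thigh angle -
#     shank angle, and ankle flexion (dorsiflexion positive) = foot-axis
#     angle from horizontal - shank angle;
#   - the foot is a rigid triangle: heel and toe sit at fixed offsets from
#     the ankle in the foot frame (heel 25% of foot length behind the
#'    ankle, toe 75% ahead, both one ankle-height below).
# Medio-lateral (Z) marker coordinates are constant offsets. All marker
# noise is Gaussian, applied to every coordinate; the GRF is noiseless.

MARKER_Z_MM <- c(SACRUM = 0, RHIP = 80, RKNEE = 60, RANKLE = 70,
                 RHEEL = 70, RTOE = 70)

# Stride length model: 0.45 * height * sqrt(speed / 3 km/h).
stride_length_m <- function(height, speed) {
  0.45 * height * sqrt(speed / 3)
}

#' Generate one synthetic gait trial
#'
#' Produces synchronized marker trajectories and ground reaction forces at
#' 200 Hz for one subject walking at one speed, spanning two full strides
#' (three right heel strikes) plus 0.1 s of padding on each side, with the
#' mechanical ground-truth event frames recorded for testing.
#'
#' @param subject An [anthropometry] object.
#' @param speed Walking speed in km/h, in `(0, 8]`.
#' @param seed Integer seed for the marker noise; the same
#'   (subject, speed, seed) triple always yields a bit-identical trial.
#' @param noise_sd_mm Marker noise standard deviation in mm (default 0.5;
#'   0 gives noiseless markers from which the generating joint angles are
#'   recoverable to numerical precision).
#' @param subject_id Identifier stored in the trial (default "S01").
#' @param fs Sampling rate, Hz. Default 200.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return An object of class `gait_trial`: `subject_id`, `speed`,
#'   `markers` ([marker_table]), `grf` ([force_table]), `true_events`
#'   (1-based `heel_strikes` and `toe_offs` frame indices),
#'   `stride_duration` (s), `stance_fraction`, `templates`.
#' @export
generate_trial <- function(subject, speed, seed = 1, noise_sd_mm = 0.5,
                           subject_id = "S01", fs = 200, gravity = 9.81) {
  if (!inherits(subject, "anthropometry")) {
    stop("`subject` must be an anthropometry object", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd_mm, "noise_sd_mm", nonnegative = TRUE)
  tmpl <- angle_templates(speed)
  H <- subject$height
  v_mps <- speed / 3.6
  sl <- stride_length_m(H, speed)
  n_stride <- max(20L, as.integer(round(sl / v_mps * fs)))
  T_stride <- n_stride / fs
  sf <- tmpl$stance_fraction
  n_st <- max(2L, as.integer(round(sf * n_stride)))
  pad <- as.integer(round(0.1 * fs))

  e1 <- pad + 1L
  hs <- e1 + 0:2 * n_stride              # three heel strikes, two strides
  storage.mode(hs) <- "integer"
  n_frames <- hs[3] + pad
  idx <- seq_len(n_frames)
  t <- (idx - 1L) / fs
  phase <- ((idx - e1) %% n_stride) / n_stride

  th_hip <- template_value(tmpl, "hip", phase) * pi / 180
  th_knee <- template_value(tmpl, "knee", phase) * pi / 180
  th_ankle <- template_value(tmpl, "ankle", phase) * pi / 180

  seg <- lapply(c(foot = "foot", shank = "shank", thigh = "thigh"),
                function(s) segment_properties(subject, s))
  L_th <- seg$thigh$length
  L_sh <- seg$shank$length
  L_f <- seg$foot$length
  h_ankle <- 0.039 * H

  a_thigh <- th_hip                       # trunk vertical: hip angle = thigh axis angle
  a_shank <- a_thigh - th_knee
  a_foot <- a_shank + th_ankle            # foot axis angle from horizontal

  hip_x <- 0.2 + v_mps * t
  hip_y <- rep(L_th + L_sh + h_ankle, n_frames)
  knee_x <- hip_x + L_th * sin(a_thigh)
  knee_y <- hip_y - L_th * cos(a_thigh)
  ankle_x <- knee_x + L_sh * sin(a_shank)
  ankle_y <- knee_y - L_sh * cos(a_shank)
  rot <- function(bx, by, phi) {
    list(x = bx * cos(phi) - by * sin(phi),
         y = bx * sin(phi) + by * cos(phi))
  }
  heel_off <- rot(-0.25 * L_f, -h_ankle, a_foot)
  toe_off_v <- rot(0.75 * L_f, -h_ankle, a_foot)
  heel_x <- ankle_x + heel_off$x
  heel_y <- ankle_y + heel_off$y
  toe_x <- ankle_x + toe_off_v$x
  toe_y <- ankle_y + toe_off_v$y
  sac_x <- hip_x
  sac_y <- hip_y + 0.15 * H

  mk <- function(x, y, name) {
    cbind(X = x * 1000, Y = y * 1000,
          Z = rep(MARKER_Z_MM[[name]], n_frames))
  }
  markers <- list(
    SACRUM = mk(sac_x, sac_y, "SACRUM"),
    RHIP = mk(hip_x, hip_y, "RHIP"),
    RKNEE = mk(knee_x, knee_y, "RKNEE"),
    RANKLE = mk(ankle_x, ankle_y, "RANKLE"),
    RHEEL = mk(heel_x, heel_y, "RHEEL"),
    RTOE = mk(toe_x, toe_y, "RTOE")
  )
  if (noise_sd_mm > 0) {
    markers <- with_seed(seed, lapply(markers, function(m) {
      m + matrix(stats::rnorm(length(m), 0, noise_sd_mm),
                 nrow = nrow(m))
    }))
  }

  # GRF: one stance profile per heel strike; stance contact spans
  # frames e .. e + n_st - 1 (last stance truncated by the trial end).
  prof <- grf_stance_profile(n_stride, n_st, subject$mass, T_stride, fs,
                             gravity)
  f_vert <- numeric(n_frames)
  f_sag <- numeric(n_frames)
  f_ml <- numeric(n_frames)
  cop_x <- numeric(n_frames)
  for (e in hs) {
    j <- seq_len(n_st)
    keep <- (e + j - 1L) <= n_frames
    j <- j[keep]
    at <- e + j - 1L
    f_vert[at] <- prof$f_vert[j]
    f_sag[at] <- prof$f_sag[j]
    f_ml[at] <- prof$f_ml[j]
    # COP runs from the heel position at contact to the toe position at
    # the end of contact (metres), monotone within stance.
    x0 <- heel_x[e]
    x1 <- toe_x[min(e + n_st - 1L, n_frames)]
    cop_x[at] <- x0 + prof$cop_rel[j] * (x1 - x0)
  }
  grf <- force_table(fs, f_vert = f_vert, f_sag = f_sag, f_ml = f_ml,
                     cop_x = cop_x, cop_y = rep(0, n_frames))

  structure(list(
    subject_id = subject_id,
    speed = speed,
    markers = marker_table(fs, markers, time = t),
    grf = grf,
    true_events = list(heel_strikes = hs,
                       toe_offs = hs[1:2] + n_st - 1L),
    stride_duration = T_stride,
    stance_fraction = sf,
    templates = tmpl
  ), class = "gait_trial")
}

#' Assemble a gait trial from its components
#'
#' Constructor for trials loaded back from persisted TRC/MOT files (or
#' built by hand in tests). Marker and force tables must share sampling
#' rate and length.
#'
#' @param subject_id Subject identifier.
#' @param speed Walking speed, km/h.
#' @param markers A [marker_table].
#' @param grf A [force_table].
#' @param true_events Optional ground-truth event list (generator only).
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(subject_id, speed, markers, grf,
                       true_events = NULL) {
  if (!inherits(markers, "marker_table") || !inherits(grf, "force_table")) {
    stop("`markers`/`grf` must be marker_table / force_table",
         call. = FALSE)
  }
  if (length(markers$time) != length(grf$time) ||
      abs(markers$sampling_rate - grf$sampling_rate) > 1e-6) {
    stop("markers and grf must share sampling rate and length",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, speed = speed,
                 markers = markers, grf = grf, true_events = true_events),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s @ %.1f km/h, %d frames, stride %.3f s\n",
              x$subject_id, x$speed, length(x$markers$time),
              x$stride_duration))
  invisible(x)
}
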