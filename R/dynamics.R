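# Planar link-segment inverse dynamics: Newton-Euler recursion from the
# foot up to the hip, driven by segment kinematics and the (scaled) ground
# reaction forces. This replaces a full 3D musculoskeletal inverse-dynamics
# solve with the standard sagittal-plane method, because the analysed
# degrees of freedom are ankle, knee and hip flexion only.
#
# Sign conventions: X forward, Y up; positive moments are +Z (counter-
# clockwise in the sagittal view). Reported joint torques are flexion
# positive, matching the angle convention: hip = +Z moment on the thigh,
# knee = -Z moment on the shank, ankle = +Z moment on the foot.

# Unwrap a degree-valued angle series (avoids +-180 jumps before
# differentiation). Gait angles stay far from the wrap, but cheap to guard.
unwrap_deg <- function(x) {
  d <- diff(x)
  jumps <- cumsum(c(0, ifelse(d > 180, -360, ifelse(d < -180, 360, 0))))
  x + jumps
}

#' Segment kinematic states from marker trajectories
#'
#' Builds the per-frame rigid-body state of the foot, shank and thigh:
#' centre-of-mass position (from the joint centres and the COM-fraction
#' parameters), COM acceleration and segment angular acceleration (by
#' double numerical differentiation), proximal joint-centre position, and
#' the segment inertial properties. Marker series should be filtered
#' upstream if they carry measurement noise.
#'
#' @param markers A [marker_table] with the required marker set.
#' @param subject An [anthropometry] object.
#' @param fs Sampling rate, Hz (defaults to the marker table's rate).
#' @return An object of class `segment_states`: per-segment lists with
#'   fields `mass`, `inertia`, `com_x/com_y` (m), `acc_x/acc_y` (m/s^2),
#'   `alpha` (rad/s^2), `prox_x/prox_y` (m), plus `n` and `fs`.
#' @export
segment_states <- function(markers, subject, fs = markers$sampling_rate) {
  if (!inherits(markers, "marker_table")) {
    stop("`markers` must be a marker_table", call. = FALSE)
  }
  if (!inherits(subject, "anthropometry")) {
    stop("`subject` must be an anthropometry object", call. = FALSE)
  }
  check_required_markers(markers)
  m <- lapply(markers$markers, function(mm) mm[, c("X", "Y")] / 1000) # m
  n <- nrow(m$RHIP)
  if (anyNA(unlist(m))) {
    first_bad <- which(rowSums(is.na(do.call(cbind, m))) > 0)[1L]
    stop(sprintf("NaN in marker input at frame %d", first_bad),
         call. = FALSE)
  }

  seg_def <- list(
    foot = list(prox = "RANKLE", a = "RHEEL", b = "RTOE"),
    shank = list(prox = "RKNEE", a = "RKNEE", b = "RANKLE"),
    thigh = list(prox = "RHIP", a = "RHIP", b = "RKNEE")
  )
  ddiff <- function(x) differentiate(differentiate(x, fs), fs)
  segments <- lapply(names(seg_def), function(s) {
    d <- seg_def[[s]]
    props <- segment_properties(subject, s)
    pa <- m[[d$a]]
    pb <- m[[d$b]]
    com_x <- pa[, "X"] + props$com_frac * (pb[, "X"] - pa[, "X"])
    com_y <- pa[, "Y"] + props$com_frac * (pb[, "Y"] - pa[, "Y"])
    dx <- pb[, "X"] - pa[, "X"]
    dy <- pb[, "Y"] - pa[, "Y"]
    if (s == "foot") {
      phi <- unwrap_deg(atan2(dy, dx) * 180 / pi) * pi / 180
    } else {
      phi <- unwrap_deg(axis_angle_from_down(dx, dy)) * pi / 180
    }
    list(
      mass = props$mass, inertia = props$inertia,
      length = sqrt(dx^2 + dy^2),
      com_x = com_x, com_y = com_y,
      acc_x = ddiff(com_x), acc_y = ddiff(com_y),
      alpha = ddiff(phi),
      prox_x = m[[d$prox]][, "X"], prox_y = m[[d$prox]][, "Y"]
    )
  })
  names(segments) <- names(seg_def)
  structure(list(segments = segments, n = n, fs = fs),
            class = "segment_states")
}

cross2 <- function(rx, ry, fx, fy) rx * fy - ry * fx

#' Bottom-up Newton-Euler joint moments
#'
#' Recurses foot, shank, thigh. For each segment with known distal force
#' `F_d` and distal moment `M_d`, the unknown proximal load is
#' `F_p = m a_com - F_d - m g` and
#' `M_p = I alpha - M_d - (r_d - r_com) x F_d - (r_p - r_com) x F_p`.
#' The external GRF acts on the foot at the centre of pressure wherever
#' the vertical force indicates contact, and is zero during swing.
#'
#' @param states A [segment_states] object.
#' @param grf A [force_table] synchronized with `states` (same length).
#' @param gravity Gravitational acceleration, m/s^2. Default 9.81.
#' @param include_segment_dynamics If `FALSE`, the leg segments'
#'   inertial and gravitational terms (`m a`, `I alpha`, `m g`) are
#'   dropped, leaving the moments a purely linear function of the applied
#'   GRF. This isolates the load-scaling mechanism: scaled GRFs then yield
#'   exactly `(1 + load/weight)` times the unloaded moments.
#' @return An object of class `joint_dynamics`: `torque` data.frame
#'   (columns `ankle`, `knee`, `hip`, Nm, flexion positive) and
#'   `proximal_force` (per joint, columns `fx`, `fy`, N, force transmitted
#'   to the segment from its proximal neighbour).
#' @export
newton_euler_bottom_up <- function(states, grf, gravity = 9.81,
                                   include_segment_dynamics = TRUE) {
  if (!inherits(states, "segment_states")) {
    stop("`states` must come from segment_states()", call. = FALSE)
  }
  if (!inherits(grf, "force_table")) {
    stop("`grf` must be a force_table", call. = FALSE)
  }
  n <- states$n
  if (length(grf$f_vert) != n) {
    stop("`grf` length must match the segment states", call. = FALSE)
  }
  for (s in names(states$segments)) {
    seg <- states$segments[[s]]
    bad <- which(!is.finite(seg$acc_x + seg$acc_y + seg$alpha +
                            seg$com_x + seg$com_y))
    if (length(bad) > 0L) {
      stop(sprintf("NaN/Inf in %s segment state at frame %d", s, bad[1L]),
           call. = FALSE)
    }
  }
  g_y <- -gravity
  contact <- grf$f_vert > 0
  # external force on the foot (reaction from the ground)
  ext_fx <- ifelse(contact, grf$f_sag, 0)
  ext_fy <- ifelse(contact, grf$f_vert, 0)
  ext_rx <- ifelse(contact, grf$cop_x, 0)
  ext_ry <- ifelse(contact, grf$cop_y, 0)

  torque <- list()
  prox_force <- list()
  F_d_x <- ext_fx
  F_d_y <- ext_fy
  M_d <- rep(0, n)
  r_d_x <- ext_rx
  r_d_y <- ext_ry
  for (s in c("foot", "shank", "thigh")) {
    seg <- states$segments[[s]]
    if (include_segment_dynamics) {
      F_p_x <- seg$mass * seg$acc_x - F_d_x
      F_p_y <- seg$mass * seg$acc_y - F_d_y - seg$mass * g_y
      M_p <- seg$inertia * seg$alpha - M_d -
        cross2(r_d_x - seg$com_x, r_d_y - seg$com_y, F_d_x, F_d_y) -
        cross2(seg$prox_x - seg$com_x, seg$prox_y - seg$com_y,
               F_p_x, F_p_y)
    } else {
      F_p_x <- -F_d_x
      F_p_y <- -F_d_y
      M_p <- -M_d -
        cross2(r_d_x - seg$com_x, r_d_y - seg$com_y, F_d_x, F_d_y) -
        cross2(seg$prox_x - seg$com_x, seg$prox_y - seg$com_y,
               F_p_x, F_p_y)
    }
    torque[[s]] <- M_p
    prox_force[[s]] <- list(fx = F_p_x, fy = F_p_y)
    # action-reaction onto the next segment's distal end
    F_d_x <- -F_p_x
    F_d_y <- -F_p_y
    M_d <- -M_p
    r_d_x <- seg$prox_x
    r_d_y <- seg$prox_y
  }
  structure(list(
    torque = data.frame(
      ankle = torque$foot,        # +Z on foot  = dorsiflexion positive
      knee = -torque$shank,       # -Z on shank = knee flexion positive
      hip = torque$thigh          # +Z on thigh = hip flexion positive
    ),
    proximal_force = list(
      ankle = prox_force$foot,
      knee = prox_force$shank,
      hip = prox_force$thigh
    )
  ), class = "joint_dynamics")
}

#' Normalize joint torque by body mass
#'
#' Element-wise division by the subject's body mass in kg. The carried
#' load is excluded from the denominator, so loaded torques grow with
#' load, consistent with reporting outcomes per kilogram of body mass.
#'
#' @param torque Torque series, Nm.
#' @param mass Body mass, kg (> 0).
#' @return Torque series in Nm/kg.
#' @export
normalize_torque <- function(torque, mass) {
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  torque / mass
}
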