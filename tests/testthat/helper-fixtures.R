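# Shared fixtures and independent oracles for the test suite.

default_subject <- function(mass = 66.6, height = 1.69, ...) {
  anthropometry(mass, height, ...)
}

# Static neutral standing pose: straight vertical leg, foot flat, repeated
# over `n` frames. Ankle at (x0, ankle height); heel/toe on the ground.
static_pose_markers <- function(subject, n = 50, x0 = 1.0, fs = 200) {
  H <- subject$height
  L_th <- 0.245 * H; L_sh <- 0.246 * H; L_f <- 0.152 * H
  h_a <- 0.039 * H
  mk <- function(x, y, z) cbind(X = rep(x * 1000, n),
                                Y = rep(y * 1000, n),
                                Z = rep(z, n))
  marker_table(fs, list(
    SACRUM = mk(x0, h_a + L_sh + L_th + 0.25, 0),
    RHIP   = mk(x0, h_a + L_sh + L_th, 80),
    RKNEE  = mk(x0, h_a + L_sh, 60),
    RANKLE = mk(x0, h_a, 70),
    RHEEL  = mk(x0 - 0.25 * L_f, 0, 70),
    RTOE   = mk(x0 + 0.75 * L_f, 0, 70)
  ))
}

# Closed-form static joint moments (independent oracle): for each joint,
# the transmitted moment balances the moments of all external forces on
# the subsystem distal to it (GRF at the COP plus gravity on the distal
# segments). Returns moments in the package's reporting convention
# (ankle +Z on foot, knee -Z on shank, hip +Z on thigh).
static_moment_oracle <- function(states, grf_force, cop, gravity = 9.81,
                                 frame = 1L) {
  seg <- states$segments
  cross_z <- function(r, f) r[1] * f[2] - r[2] * f[1]
  at <- function(s, what) c(seg[[s]][[paste0(what, "_x")]][frame],
                            seg[[s]][[paste0(what, "_y")]][frame])
  grav <- function(s) c(0, -seg[[s]]$mass * gravity)
  moment_about <- function(jpos, members) {
    m <- cross_z(cop - jpos, grf_force)
    for (s in members) m <- m + cross_z(at(s, "com") - jpos, grav(s))
    -m   # proximal moment balances the external moments
  }
  ankle <- moment_about(at("foot", "prox"), "foot")
  knee <- moment_about(at("shank", "prox"), c("foot", "shank"))
  hip <- moment_about(at("thigh", "prox"), c("foot", "shank", "thigh"))
  c(ankle = ankle, knee = -knee, hip = hip)
}

# Compound-pendulum segment states: shank + foot rigidly joined, swinging
# about a fixed knee with prescribed angle psi(t) (from vertical, +Z).
# Positions/accelerations are analytic, so the Newton-Euler result can be
# compared with the closed-form pendulum equation at machine precision.
pendulum_states <- function(subject, psi, psi_d, psi_dd, fs = 200) {
  H <- subject$height
  L_sh <- 0.246 * H; L_f <- 0.152 * H; h_a <- 0.039 * H
  pr_sh <- segment_properties(subject, "shank")
  pr_f <- segment_properties(subject, "foot")
  n <- length(psi)
  # body-frame offsets from the knee at psi = 0 (shank pointing down,
  # foot flat): shank COM on the axis, foot COM offset from the ankle.
  b_shank <- c(0, -pr_sh$com_frac * L_sh)
  b_foot <- c(0.25 * L_f, -(L_sh + h_a))
  seg_state <- function(b, props, prox_b) {
    rx <- b[1] * cos(psi) - b[2] * sin(psi)
    ry <- b[1] * sin(psi) + b[2] * cos(psi)
    px <- prox_b[1] * cos(psi) - prox_b[2] * sin(psi)
    py <- prox_b[1] * sin(psi) + prox_b[2] * cos(psi)
    list(mass = props$mass, inertia = props$inertia,
         com_x = rx, com_y = ry,
         acc_x = psi_dd * (-ry) - psi_d^2 * rx,
         acc_y = psi_dd * rx - psi_d^2 * ry,
         alpha = psi_dd,
         prox_x = px, prox_y = py)
  }
  thigh_static <- list(mass = segment_properties(subject, "thigh")$mass,
                       inertia = segment_properties(subject, "thigh")$inertia,
                       com_x = rep(0, n), com_y = rep(0.1, n),
                       acc_x = rep(0, n), acc_y = rep(0, n),
                       alpha = rep(0, n),
                       prox_x = rep(0, n), prox_y = rep(0.245 * H, n))
  structure(list(segments = list(
    foot = seg_state(b_foot, pr_f, c(0, -L_sh)),
    shank = seg_state(b_shank, pr_sh, c(0, 0)),
    thigh = thigh_static
  ), n = n, fs = fs), class = "segment_states")
}

# Analytic pendulum knee torque (package reporting convention).
pendulum_knee_torque <- function(subject, psi, psi_dd, gravity = 9.81) {
  H <- subject$height
  L_sh <- 0.246 * H; L_f <- 0.152 * H; h_a <- 0.039 * H
  pr_sh <- segment_properties(subject, "shank")
  pr_f <- segment_properties(subject, "foot")
  b_shank <- c(0, -pr_sh$com_frac * L_sh)
  b_foot <- c(0.25 * L_f, -(L_sh + h_a))
  I_tot <- pr_sh$inertia + pr_sh$mass * sum(b_shank^2) +
    pr_f$inertia + pr_f$mass * sum(b_foot^2)
  # world COM x-offsets from the knee
  rx <- function(b) b[1] * cos(psi) - b[2] * sin(psi)
  grav_z <- gravity * (pr_sh$mass * rx(b_shank) + pr_f$mass * rx(b_foot))
  -(I_tot * psi_dd + grav_z)   # knee reported as -Z moment on the shank
}

# Brute-force balanced two-way ANOVA by explicit loops over cells
# (independent oracle for the SS decomposition).
brute_force_anova <- function(df, response, fa, fb) {
  A <- sort(unique(df[[fa]])); B <- sort(unique(df[[fb]]))
  y <- df[[response]]
  grand <- mean(y)
  r <- nrow(df) / (length(A) * length(B))
  ssa <- ssb <- ssab <- sse <- 0
  for (a in A) {
    ma <- mean(y[df[[fa]] == a])
    ssa <- ssa + length(B) * r * (ma - grand)^2
  }
  for (b in B) {
    mb <- mean(y[df[[fb]] == b])
    ssb <- ssb + length(A) * r * (mb - grand)^2
  }
  for (a in A) for (b in B) {
    sel <- df[[fa]] == a & df[[fb]] == b
    mab <- mean(y[sel])
    ma <- mean(y[df[[fa]] == a]); mb <- mean(y[df[[fb]] == b])
    ssab <- ssab + r * (mab - ma - mb + grand)^2
    sse <- sse + sum((y[sel] - mab)^2)
  }
  c(a = ssa, b = ssb, ab = ssab, e = sse,
    total = sum((y - grand)^2))
}

# Small grid data.frame builder for the statistics tests.
null_grid_df <- function(n_subjects, speeds = 1:3, loads = 1:3,
                         seed = 1, effect = function(s, l) 0, sd = 1) {
  cells <- expand.grid(subject = seq_len(n_subjects), speed = speeds,
                       load = loads)
  set.seed(seed)
  cells$value <- stats::rnorm(nrow(cells), sd = sd) +
    mapply(effect, cells$speed, cells$load)
  cells
}
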