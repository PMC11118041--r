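# Newton-Euler inverse dynamics against independent closed-form oracles.

test_that("segment states reproduce the generator's construction", {
  s <- default_subject()
  tr <- generate_trial(s, 3, seed = 2, noise_sd_mm = 0)
  st <- segment_states(tr$markers, s)
  H <- s$height
  expect_equal(max(abs(st$segments$thigh$length - 0.245 * H)), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(st$segments$shank$length - 0.246 * H)), 0,
               tolerance = 1e-9)
  # foot axis heel->toe spans the full foot length
  expect_equal(max(abs(st$segments$foot$length - 0.152 * H)), 0,
               tolerance = 1e-9)
  # default leg mass fractions sum to 0.162 of body mass
  leg_mass <- sum(vapply(st$segments, `[[`, 0, "mass"))
  expect_equal(leg_mass, (0.0145 + 0.0465 + 0.100) * s$mass)

  # stationary input: negligible accelerations
  static <- segment_states(static_pose_markers(s), s)
  expect_lt(max(abs(unlist(lapply(static$segments, function(x)
    c(x$acc_x, x$acc_y, x$alpha))))), 1e-6)
})

test_that("a null system produces exactly zero moments", {
  s <- default_subject()
  static <- segment_states(static_pose_markers(s), s)
  n <- static$n
  zero_grf <- force_table(200, f_vert = rep(0, n), f_sag = rep(0, n),
                          f_ml = rep(0, n), cop_x = rep(0, n),
                          cop_y = rep(0, n))
  dyn <- newton_euler_bottom_up(static, zero_grf, gravity = 0)
  expect_equal(max(abs(unlist(dyn$torque))), 0, tolerance = 1e-9)
})

test_that("static standing moments match the closed-form balance", {
  s <- default_subject()
  states <- segment_states(static_pose_markers(s, x0 = 1.0), s)
  n <- states$n
  g <- 9.81
  cop <- c(1.0 + 0.05, 0)   # 5 cm anterior to the ankle
  grf <- force_table(200, f_vert = rep(s$mass * g, n),
                     f_sag = rep(0, n), f_ml = rep(0, n),
                     cop_x = rep(cop[1], n), cop_y = rep(cop[2], n))
  dyn <- newton_euler_bottom_up(states, grf)
  oracle <- static_moment_oracle(states, c(0, s$mass * g), cop)
  got <- c(ankle = dyn$torque$ankle[25], knee = dyn$torque$knee[25],
           hip = dyn$torque$hip[25])
  expect_equal(got, oracle, tolerance = 1e-9)

  # with a (near-)massless foot the ankle moment is m g times the COP
  # lever arm: 66.6 kg * 9.81 * 0.05 m = 32.67 Nm
  sp <- default_segment_params()
  sp$mass_frac[sp$segment == "foot"] <- 1e-12
  s2 <- anthropometry(66.6, 1.69, segment_params = sp)
  states2 <- segment_states(static_pose_markers(s2, x0 = 1.0), s2)
  dyn2 <- newton_euler_bottom_up(states2, grf)
  expect_equal(abs(dyn2$torque$ankle[25]), 66.6 * 9.81 * 0.05,
               tolerance = 1e-6)
  expect_equal(abs(dyn2$torque$ankle[25]), 32.67, tolerance = 1e-4)
})

test_that("swing-phase compound pendulum matches the analytic equation", {
  s <- default_subject()
  fs <- 200
  t <- seq(0, 1.5, by = 1 / fs)
  w <- 2 * pi * 0.8
  psi <- 0.3 * sin(w * t)
  psi_d <- 0.3 * w * cos(w * t)
  psi_dd <- -0.3 * w^2 * sin(w * t)
  states <- pendulum_states(s, psi, psi_d, psi_dd, fs)
  n <- length(t)
  zero_grf <- force_table(fs, f_vert = rep(0, n), f_sag = rep(0, n),
                          f_ml = rep(0, n), cop_x = rep(0, n),
                          cop_y = rep(0, n))
  dyn <- newton_euler_bottom_up(states, zero_grf)
  truth <- pendulum_knee_torque(s, psi, psi_dd)
  rel_err <- max(abs(dyn$torque$knee - truth)) / max(abs(truth))
  expect_lt(rel_err, 1e-6)
})

test_that("with leg dynamics off, moments scale exactly with (1 + load/weight)", {
  s <- default_subject()
  tr <- generate_trial(s, 3, seed = 2)
  states <- segment_states(tr$markers, s)
  base <- newton_euler_bottom_up(states, tr$grf,
                                 include_segment_dynamics = FALSE)
  stance <- tr$grf$f_vert > 0
  for (load in c(1, 5, 20)) {
    k <- 1 + load / s$mass
    loaded <- newton_euler_bottom_up(states, scale_grf(tr$grf, load, s$mass),
                                     include_segment_dynamics = FALSE)
    for (j in c("ankle", "knee", "hip")) {
      scale_ref <- max(abs(k * base$torque[[j]][stance]))
      expect_lt(max(abs(loaded$torque[[j]][stance] -
                        k * base$torque[[j]][stance])) / scale_ref, 1e-12)
    }
  }
})

test_that("hip proximal force averages to the supported body weight", {
  s <- default_subject()
  tr <- generate_trial(s, 2.5, seed = 6)
  # filter marker noise before double differentiation
  filt <- function(x) lowpass_filter(x, 200)
  fm <- lapply(tr$markers$markers, function(m) {
    cbind(X = filt(m[, "X"]), Y = filt(m[, "Y"]), Z = m[, "Z"])
  })
  states <- segment_states(marker_table(200, fm, time = tr$markers$time), s)
  dyn <- newton_euler_bottom_up(states, tr$grf)
  e <- tr$true_events$heel_strikes
  stride <- seq.int(e[1], e[2] - 1L)
  leg_mass <- (0.0145 + 0.0465 + 0.100) * s$mass
  mean_fy <- mean(dyn$proximal_force$hip$fy[stride])
  expect_equal(mean_fy, -(s$mass - leg_mass) * 9.81, tolerance = 0.05)
})

test_that("NaN inputs are reported with the offending frame", {
  s <- default_subject()
  m <- static_pose_markers(s)
  m$markers$RKNEE[7, "X"] <- NaN
  expect_error(segment_states(m, s), "frame 7")
})

test_that("torque normalization divides by body mass", {
  expect_equal(normalize_torque(80, 66.6), 1.2012, tolerance = 1e-4)
  expect_equal(normalize_torque(rep(0, 5), 70), rep(0, 5))
  x <- c(-3, 1, 8)
  expect_equal(normalize_torque(3 * x, 70), 3 * normalize_torque(x, 70))
  expect_error(normalize_torque(x, 0), "> 0")
})
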