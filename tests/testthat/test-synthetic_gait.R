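# Synthetic cohort, joint-angle templates, GRF template and trial
# generation.

test_that("cohort sampling reproduces the configured population", {
  cohort <- sample_cohort(15, seed = 42)
  expect_length(cohort, 15L)
  masses <- vapply(cohort, `[[`, 0, "mass")
  heights <- vapply(cohort, `[[`, 0, "height")
  expect_true(all(masses > 30))
  expect_true(all(heights > 1.2))
  expect_identical(cohort, sample_cohort(15, seed = 42))

  frozen <- sample_cohort(4, seed = 1, sd_mass = 0, sd_height = 0)
  expect_true(all(vapply(frozen, `[[`, 0, "mass") == 66.6))
  expect_true(all(vapply(frozen, `[[`, 0, "height") == 1.69))

  big <- sample_cohort(10000, seed = 1)
  m <- vapply(big, `[[`, 0, "mass")
  se <- 10.8 / sqrt(10000)
  expect_lt(abs(mean(m) - 66.6), 3 * se)

  expect_error(sample_cohort(0), ">= 1")
})

test_that("angle templates hit the kinematic landmarks at 4 km/h", {
  tm <- angle_templates(4)
  g <- seq(0, 1, by = 5e-4)
  sf <- tm$stance_fraction
  knee <- template_value(tm, "knee", g)
  hip <- template_value(tm, "hip", g)
  swing_max <- max(knee[g > sf])
  expect_equal(swing_max, 71, tolerance = 0.5 / 71)
  expect_gt(g[g > sf][which.max(knee[g > sf])], 0.6)  # peak in swing
  expect_equal(template_value(tm, "ankle", sf), 20, tolerance = 0.5 / 20)
  expect_equal(min(hip[g <= sf]), -15, tolerance = 0.5 / 15)
})

test_that("templates are periodic and speed-modulated", {
  for (speed in c(1, 2.5, 4)) {
    tm <- angle_templates(speed)
    for (j in c("ankle", "knee", "hip")) {
      expect_identical(template_value(tm, j, 0),
                       template_value(tm, j, 1))
    }
  }
  # knee swing peak grows and occurs earlier as speed increases
  g <- seq(0, 1, by = 5e-4)
  peaks <- sapply(c(1, 2.5, 4), function(v) {
    tm <- angle_templates(v)
    k <- template_value(tm, "knee", g)
    c(value = max(k), phase = g[which.max(k)])
  })
  expect_true(all(diff(peaks["value", ]) > 0))
  expect_true(all(diff(peaks["phase", ]) < 0))
  expect_error(angle_templates(0), "km/h")
  expect_error(angle_templates(-2), "km/h")
})

test_that("GRF template satisfies the impulse and shape conventions", {
  for (speed in c(1, 2.5, 4)) {
    mass <- 66.6
    T_s <- 1.1
    gt <- grf_template(speed, mass, T_s)
    dt <- 1 / gt$sampling_rate
    impulse <- dt * (sum(gt$f_vert) - (gt$f_vert[1] + tail(gt$f_vert, 1)) / 2)
    expect_gt(impulse / (mass * 9.81 * T_s), 0.98)
    expect_lt(impulse / (mass * 9.81 * T_s), 1.02)

    sf <- stance_fraction(speed)
    n <- length(gt$f_vert)
    n_st <- round(sf * n)
    # swing: no contact at all
    expect_true(all(gt$f_vert[(n_st + 1):n] == 0))
    # double hump: two local maxima bracketing a midstance valley
    stance <- gt$f_vert[1:n_st]
    valley <- stance[round(n_st / 2)]
    expect_gt(max(stance[1:round(n_st / 2)]), valley)
    expect_gt(max(stance[round(n_st / 2):n_st]), valley)
    # braking then propulsion, zero net fore-aft impulse
    expect_lt(abs(mean(gt$f_sag)), 0.01 * max(abs(gt$f_sag)))
    expect_lt(min(gt$f_sag[1:round(n_st / 2)]), 0)
    expect_gt(max(gt$f_sag[round(n_st / 2):n_st]), 0)
    # medio-lateral below 10% body weight
    expect_lt(max(abs(gt$f_ml)), 0.1 * mass * 9.81)
    # COP monotone heel-to-toe during stance
    expect_true(all(diff(gt$cop_x[1:n_st]) > 0))
  }
})

test_that("trial generation is deterministic and internally consistent", {
  s <- default_subject()
  t1 <- generate_trial(s, 3.5, seed = 77)
  t2 <- generate_trial(s, 3.5, seed = 77)
  expect_identical(t1, t2)
  t3 <- generate_trial(s, 3.5, seed = 78)
  expect_false(identical(t1$markers, t3$markers))

  expect_equal(t1$markers$sampling_rate, 200)
  expect_equal(t1$grf$sampling_rate, 200)
  expect_gte(length(t1$true_events$heel_strikes), 2L)
})

test_that("noiseless forward kinematics invert to the templates", {
  s <- default_subject(72, 1.75)
  for (speed in c(1.5, 4)) {
    tr <- generate_trial(s, speed, seed = 5, noise_sd_mm = 0)
    ang <- compute_joint_angles(tr$markers)
    n_stride <- round(tr$stride_duration * 200)
    e1 <- tr$true_events$heel_strikes[1]
    phase <- ((seq_along(tr$markers$time) - e1) %% n_stride) / n_stride
    for (j in c("ankle", "knee", "hip")) {
      expect_lt(max(abs(ang[[j]] - template_value(tr$templates, j, phase))),
                0.01)
    }
  }
})

test_that("generated GRF supports body weight over each stride", {
  s <- default_subject()
  tr <- generate_trial(s, 2, seed = 9)
  e <- tr$true_events$heel_strikes
  stride <- seq.int(e[1], e[2] - 1L)
  mean_force <- mean(tr$grf$f_vert[stride])
  expect_equal(mean_force, s$mass * 9.81, tolerance = 0.02)
})
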