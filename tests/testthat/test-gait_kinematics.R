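# Event detection, stride segmentation, joint angles, filtering,
# differentiation and time normalization.

test_that("gait events are recovered exactly from noiseless synthetic GRF", {
  for (speed in c(1, 2.5, 4)) {
    tr <- generate_trial(default_subject(), speed, seed = 3)
    hs <- detect_heel_strikes(tr$grf)
    expect_identical(hs, tr$true_events$heel_strikes)
    st <- segment_stride(tr$grf)
    expect_identical(st$toe_off, tr$true_events$toe_offs[1])
    expect_true(st$heel_strike_1 < st$toe_off &&
                st$toe_off < st$heel_strike_2)
  }
  # stance occupies about 60% of the cycle at 4 km/h
  tr4 <- generate_trial(default_subject(), 4, seed = 3)
  st4 <- segment_stride(tr4$grf)
  expect_equal(st4$stance_fraction, 0.6, tolerance = 0.05)
})

test_that("segmentation errors are raised on degenerate force records", {
  flat <- force_table(200, f_vert = rep(0, 400), f_sag = rep(0, 400),
                      f_ml = rep(0, 400), cop_x = rep(0, 400),
                      cop_y = rep(0, 400))
  expect_error(detect_heel_strikes(flat), "segmentation error")

  tr <- generate_trial(default_subject(), 3, seed = 1)
  expect_error(detect_heel_strikes(tr$grf,
                                   threshold = max(tr$grf$f_vert) * 2),
               "segmentation error")

  always_on <- force_table(200, f_vert = rep(500, 400),
                           f_sag = rep(0, 400), f_ml = rep(0, 400),
                           cop_x = rep(0, 400), cop_y = rep(0, 400))
  expect_error(detect_toe_off(always_on, 10, 300), "segmentation error")
})

test_that("joint angles are zero in the neutral pose and rigid-motion invariant", {
  s <- default_subject()
  m <- static_pose_markers(s)
  ang <- compute_joint_angles(m)
  expect_equal(max(abs(ang$hip)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ang$knee)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ang$ankle)), 0, tolerance = 1e-9)

  # rigid rotation + translation in the sagittal plane leaves angles alone
  tr <- generate_trial(s, 3, seed = 8, noise_sd_mm = 0)
  ang0 <- compute_joint_angles(tr$markers)
  th <- 10 * pi / 180
  rotated <- lapply(tr$markers$markers, function(mm) {
    cbind(X = cos(th) * mm[, "X"] - sin(th) * mm[, "Y"] + 500,
          Y = sin(th) * mm[, "X"] + cos(th) * mm[, "Y"] - 200,
          Z = mm[, "Z"])
  })
  ang1 <- compute_joint_angles(
    marker_table(200, rotated, time = tr$markers$time))
  for (j in c("ankle", "knee", "hip")) {
    expect_equal(ang1[[j]], ang0[[j]], tolerance = 1e-9)
  }
})

test_that("joint angle computation validates its marker input", {
  s <- default_subject()
  m <- static_pose_markers(s)
  m$markers$RKNEE <- NULL
  expect_error(compute_joint_angles(
    marker_table(200, m$markers)), "missing required marker.*RKNEE")

  m2 <- static_pose_markers(s)
  m2$markers$RKNEE <- m2$markers$RHIP   # coincident: zero-length thigh
  expect_error(compute_joint_angles(m2), "degeneracy")
})

test_that("Butterworth filter has the designed passband and cutoff", {
  fs <- 200
  t <- seq(0, 4, by = 1 / fs)

  const <- rep(3.7, length(t))
  expect_equal(lowpass_filter(const, fs), const, tolerance = 1e-6)

  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  s1 <- sin(2 * pi * 1 * t)
  r1 <- max(abs(lowpass_filter(s1, fs)[mid]))
  expect_gte(r1, 0.999)

  # zero-phase squares the single-pass magnitude: 1/2 at the cutoff
  s6 <- sin(2 * pi * 6 * t)
  r6 <- max(abs(lowpass_filter(s6, fs)[mid]))
  expect_equal(r6, 0.5, tolerance = 0.02)
  r6_single <- max(abs(lowpass_filter(s6, fs, passes = 1)[mid]))
  expect_equal(r6_single, 1 / sqrt(2), tolerance = 0.02)

  # in-band idempotence: < 0.1% RMS change below 1 Hz
  slow <- sin(2 * pi * 0.5 * t) + 0.3 * cos(2 * pi * 0.8 * t)
  out <- lowpass_filter(slow, fs)
  expect_lt(sqrt(mean((out - slow)^2)) / sqrt(mean(slow^2)), 1e-3)

  expect_error(lowpass_filter(1:5, fs), "too short")
  expect_error(lowpass_filter(s1, fs, cutoff = 150), "2 \\* cutoff")
})

test_that("numerical differentiation matches analytic derivatives", {
  fs <- 200
  t <- seq(0, 1, by = 1 / fs)

  ramp <- 2.5 * t
  expect_equal(differentiate(ramp, fs), rep(2.5, length(t)))

  s <- sin(2 * pi * t)
  d <- differentiate(s, fs)
  truth <- 2 * pi * cos(2 * pi * t)
  # interior central differences respect the Taylor bound h^2/6 max|f'''|
  h <- 1 / fs
  bound <- h^2 / 6 * (2 * pi)^3
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(d[interior] - truth[interior])), bound * 1.01)

  expect_equal(differentiate(rep(4, 10), fs), rep(0, 10))
  expect_error(differentiate(c(1, 2), fs), ">= 3")
})

test_that("time normalization maps strides onto 101 points", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_identical(time_normalize(x), x)

  ramp <- seq(2, 9, length.out = 57)
  out <- time_normalize(ramp)
  expect_length(out, 101L)
  expect_equal(out[1], 2)
  expect_equal(out[101], 9)
  expect_equal(out, seq(2, 9, length.out = 101))

  smooth <- sin(seq(0, 2 * pi, length.out = 101))
  round_trip <- time_normalize(time_normalize(smooth, 201L))
  expect_equal(round_trip, smooth, tolerance = 1e-9)

  expect_error(time_normalize(1), ">= 2")
})
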