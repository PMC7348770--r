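test_that("heading rotation matches its printed layout and trig values", {
  expect_equal(heading_rotation(0), diag(3))
  expect_equal(heading_rotation(90),
               matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, byrow = TRUE),
               tolerance = 1e-12)
  a <- 7 * pi / 180
  expect_equal(heading_rotation(7),
               matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3,
                      byrow = TRUE),
               tolerance = 1e-12)
})

test_that("correction and linking equations follow their printed order", {
  set.seed(5)
  # RGs0G = I passes the sensor rotation through
  r <- random_rotation()
  expect_equal(correct_sensor(r, diag(3)), r)
  # optical modality is a no-op
  expect_equal(correct_sensor(r, heading_rotation(40), modality = "optical"), r)
  # product order: single-axis rotations compose
  expect_equal(correct_sensor(rot_y_test <- heading_rotation(30), heading_rotation(40)),
               heading_rotation(70), tolerance = 1e-12)
  for (i in 1:10) {
    a <- random_rotation(); b <- random_rotation()
    expect_equal(correct_sensor(a, b), b %*% a)               # Rs0G
    expect_equal(sensor_to_bone(a, b), t(a) %*% b)            # Rs0b
    expect_equal(bone_absolute(a, b), a %*% t(b))             # RbiG
    expect_equal(bone_relative(a, b), t(a) %*% b)             # Rbip
    # closure: linking then evaluating at instant 0 returns the bone pose
    Rs0G <- a; Rb0G <- b
    Rs0b <- sensor_to_bone(Rb0G, Rs0G)
    expect_equal(bone_absolute(Rs0G, Rs0b), Rb0G, tolerance = 1e-9)
    # recomposition: parent %*% relative = child
    expect_equal(a %*% bone_relative(a, b), b, tolerance = 1e-12)
  }
  # trivial identities
  expect_equal(sensor_to_bone(diag(3), r), r)
  expect_equal(sensor_to_bone(r, r), diag(3), tolerance = 1e-12)
  expect_equal(bone_absolute(r, diag(3)), r)
})

test_that("a perturbed sensor propagates its rotation delta to the bone", {
  set.seed(9)
  Rs0 <- random_rotation()
  Rs0b <- sensor_to_bone(diag(3), Rs0)
  delta <- matrix_from_euler_rxzy(12, -5, 31)
  RbiG <- bone_absolute(delta %*% Rs0, Rs0b)
  expect_equal(RbiG, delta, tolerance = 1e-9)
})

test_that("heading alpha recovers a known yaw offset", {
  # a thigh-style mount: Y axis anterior in the neutral pose
  mount <- cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0))
  pelvis <- cbind(c(0, -1, 0), c(-1, 0, 0), c(0, 0, -1))
  expect_equal(heading_alpha(mount, pelvis, "Y", 90), 0, tolerance = 1e-9)
  for (beta in c(-170, -45, 7, 33, 120)) {
    sensed <- heading_rotation(-beta) %*% mount
    expect_equal(heading_alpha(sensed, pelvis, "Y", 90), beta, tolerance = 1e-9)
  }
  # the worked example: measured 83 when 90 was expected leaves alpha = 7
  sensed83 <- heading_rotation(-7) %*% mount
  expect_equal(heading_alpha(sensed83, pelvis, "Y", 90), 7, tolerance = 1e-9)
  # an assumed axis near vertical is a mis-mounted device
  vertical_mount <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(heading_alpha(vertical_mount, pelvis, "Y", 90), "vertical")
})

test_that("calibration on a neutral capture zeroes every joint angle", {
  sim <- simulate_gait_session(gait_profile(), n_strides = 2,
                               noise = noise_none(seed = 4))
  cal <- calibrate(sim$session, sim$trajectories$skeleton)
  ser <- track(sim$session, cal, sim$trajectories$skeleton)
  f0 <- cal$frame0
  expect_lt(max(abs(ser$angles[f0, , ])), 1e-6)
  # neutral segment throughout: all angles stay zero
  nf <- sim$session$neutral_frames
  expect_lt(max(abs(ser$angles[nf, , ])), 1e-6)
})

test_that("random per-sensor headings are fully corrected (magnetometer-free equivalence)", {
  prof <- gait_profile()
  traj <- joint_trajectories(prof, n_strides = 3)
  sk <- traj$skeleton
  with_headings <- synthesize_imu(traj, noise_none(heading_offsets = TRUE, seed = 8))
  without <- synthesize_imu(traj, noise_none(heading_offsets = FALSE, seed = 8))
  ser1 <- track(with_headings, calibrate(with_headings, sk), sk)
  ser2 <- track(without, calibrate(without, sk), sk)
  expect_lt(max(abs(ser1$angles - ser2$angles)), 1e-6)
  # and both match the generator's joint angles
  expect_lt(max(abs(ser1$angles - traj$angles)), 1e-6)
})

test_that("a common yaw applied to all sensors leaves joint angles unchanged", {
  prof <- gait_profile()
  traj <- joint_trajectories(prof, n_strides = 2)
  sk <- traj$skeleton
  ses <- synthesize_imu(traj, noise_none(seed = 6))
  ses2 <- ses
  common <- 57
  for (d in seq_along(ses2$devices)) {
    for (f in seq_len(length(ses2$time))) {
      r <- quat_to_rotation(ses2$quat[f, d, ])
      # extra shared heading in each sensor's private frame (Z-up: yaw
      # about the third axis)
      rz <- matrix(c(cos(common * pi / 180), -sin(common * pi / 180), 0,
                     sin(common * pi / 180), cos(common * pi / 180), 0,
                     0, 0, 1), 3, byrow = TRUE)
      ses2$quat[f, d, ] <- rotation_to_quat(rz %*% r)
    }
  }
  a1 <- track(ses, calibrate(ses, sk), sk)$angles
  a2 <- track(ses2, calibrate(ses2, sk), sk)$angles
  expect_lt(max(abs(a1 - a2)), 1e-6)
})

test_that("the sensor-to-bone rotation is time-invariant on a rigid capture", {
  prof <- gait_profile()
  traj <- joint_trajectories(prof, n_strides = 2)
  sk <- traj$skeleton
  ses <- synthesize_imu(traj, noise_none(seed = 2))
  cal <- calibrate(ses, sk)
  # recompute the link at several frames: corrected sensor vs true bone
  corr <- heading_rotation(cal$devices$thigh_r$correction)
  for (f in seq(1, length(ses$time), by = 97)) {
    Rs <- gaitmocap:::session_rotation(ses, f, "thigh_r")
    RsG <- correct_sensor(Rs, corr)
    Rb <- matrix(traj$rotations[f, "thigh_r", ], 3, byrow = TRUE)
    expect_equal(sensor_to_bone(Rb, RsG), cal$devices$thigh_r$Rs0b,
                 tolerance = 1e-9)
  }
})

test_that("calibration errors are informative", {
  sim <- simulate_gait_session(gait_profile(), n_strides = 2,
                               noise = noise_none(seed = 4))
  sk <- sim$trajectories$skeleton
  ses <- sim$session
  ses$quat[ses$neutral_frames, match("calf_l", ses$devices), ] <- NA
  expect_error(calibrate(ses, sk), "calf_l")
  expect_error(calibrate(sim$session, sk, frame0 = 10 * length(ses$time)),
               "outside")
  ses2 <- sim$session
  ses2$devices <- setdiff(ses2$devices, "pelvis")
  ses2$quat <- sim$session$quat[, -1, , drop = FALSE]
  expect_error(calibrate(ses2, sk), "pelvis")
})

test_that("calibration survives a JSON round trip", {
  sim <- simulate_gait_session(gait_profile(), n_strides = 2,
                               noise = noise_none(seed = 12))
  sk <- sim$trajectories$skeleton
  cal <- calibrate(sim$session, sk)
  path <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(cal, path)
  cal2 <- calibration_from_json(path)
  expect_equal(cal2$devices$thigh_r$Rs0b, cal$devices$thigh_r$Rs0b,
               tolerance = 1e-12)
  expect_equal(cal2$devices$foot_l$alpha, cal$devices$foot_l$alpha)
  a1 <- track(sim$session, cal, sk)$angles
  a2 <- track(sim$session, cal2, sk)$angles
  expect_lt(max(abs(a1 - a2)), 1e-9)
})

test_that("short stream gaps are interpolated, long gaps rejected", {
  sim <- simulate_gait_session(gait_profile(), n_strides = 2,
                               noise = noise_none(seed = 14))
  sk <- sim$trajectories$skeleton
  cal <- calibrate(sim$session, sk)
  ses <- sim$session
  mid <- round(length(ses$time) * 0.6)
  d <- match("calf_r", ses$devices)
  ses$quat[mid:(mid + 3), d, ] <- NA        # 4 frames < 0.1 s at 60 Hz
  ser <- track(ses, cal, sk)
  expect_true(all(is.finite(ser$angles)))
  ses$quat[mid:(mid + 30), d, ] <- NA       # 0.5 s gap
  expect_error(track(ses, cal, sk), "gap")
})
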