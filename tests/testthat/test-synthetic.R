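test_that("the simulator is bit-identical under a fixed seed", {
  s1 <- simulate_gait_session(gait_profile(), 3, noise_model(seed = 42))
  s2 <- simulate_gait_session(gait_profile(), 3, noise_model(seed = 42))
  expect_identical(s1$session$quat, s2$session$quat)
  s3 <- simulate_gait_session(gait_profile(), 3, noise_model(seed = 43))
  expect_false(identical(s1$session$quat, s3$session$quat))

  o1 <- simulate_gait_session(gait_profile("optical"), 2, noise_model(seed = 4))
  o2 <- simulate_gait_session(gait_profile("optical"), 2, noise_model(seed = 4))
  expect_identical(o1$session$rot, o2$session$rot)
  expect_identical(o1$session$trans, o2$session$trans)
})

test_that("profile validation enforces the commanded-parameter contract", {
  expect_error(gait_profile(step_length = 59, hip_fe_range = 35),
               "exactly one")
  expect_error(gait_profile(step_length = NULL, hip_fe_range = NULL),
               "exactly one")
  expect_error(gait_profile(step_length = -3), "positive")
  expect_error(gait_profile(step_length = 300), NA)  # construction only
  expect_error(joint_trajectories(gait_profile(step_length = 300), 1),
               "unreachable")
  expect_error(joint_trajectories(gait_profile(), 1, rate = 10), "alias")
})

test_that("consecutive initial contacts are one stride time apart", {
  prof <- gait_profile()
  traj <- joint_trajectories(prof, n_strides = 6, rate = 60)
  ev <- traj$truth$events
  t1R <- ev$T1[ev$side == "R"]
  spacing <- diff(t1R) / 60
  expect_true(all(abs(spacing - traj$truth$stride_time) <= 1.5 / 60))
  expect_equal(mean(spacing), traj$truth$stride_time, tolerance = 1e-2)
})

test_that("zero hip amplitude is a static pose with no events", {
  prof <- gait_profile(hip_fe_range = 0, pelvic_tilt_range = 0,
                       trunk_tilt_range = 0, ankle_ie_range = 0,
                       ankle_dp_range = 0, hip_aa_range = 0, knee_peak = 0,
                       pelvic_rotation_amp = 0, hip_mid = 0, knee_min = 0,
                       step_width = 0.7 * 0.16 * 173.1)
  traj <- joint_trajectories(prof, n_strides = 2)
  expect_identical(nrow(traj$truth$events), 0L)
  # static: nothing moves over time (the solved ab/adduction offset that
  # sets the stance width is a constant, not motion)
  moving <- apply(traj$angles, c(2, 3), function(x) max(x) - min(x))
  expect_lt(max(moving), 1e-9)
})

test_that("commanded profile parameters appear in the ground truth", {
  tr <- joint_trajectories(gait_profile(step_length = 59), 2)
  tv <- stats::setNames(tr$truth$variables$value, tr$truth$variables$variable)
  expect_equal(unname(tv["step_length"]), 59, tolerance = 1e-6)
  tr2 <- joint_trajectories(gait_profile(hip_fe_range = 35, step_width = 10), 2)
  tv2 <- stats::setNames(tr2$truth$variables$value, tr2$truth$variables$variable)
  expect_equal(unname(tv2["hip_flexion_extension"]), 35, tolerance = 1e-9)
  expect_equal(unname(tv2["step_width"]), 10, tolerance = 1e-6)
  # default profile hits the single-support design value
  expect_equal(unname(tv2["single_support"]), 40, tolerance = 1)
})

test_that("heading drift grows the tracked heading error about linearly", {
  sim <- simulate_gait_session(
    gait_profile(), 12,
    noise_model(drift_dps = 0.5, orientation_sd_deg = 0, soft_tissue_deg = 0,
                seed = 9))
  sk <- sim$trajectories$skeleton
  ser <- track(sim$session, calibrate(sim$session, sk), sk)
  errY <- abs(ser$angles[, "thigh_r", "y"] -
                sim$trajectories$angles[, "thigh_r", "y"])
  tru <- sim$truth$events
  truR <- tru[tru$side == "R", ]
  per_stride <- vapply(seq_len(nrow(truR)), function(i) {
    mean(errY[truR$T1[i]:truR$T6[i]])
  }, numeric(1))
  expect_gt(stats::cor(seq_along(per_stride), per_stride), 0.99)
  expect_gt(per_stride[length(per_stride)], 2 * per_stride[2])
})

test_that("optical orientation jitter stays below each cluster's error bound", {
  prof <- gait_profile("optical")
  traj <- joint_trajectories(prof, 2)
  ses <- synthesize_opt(traj, noise_model(marker_sd_mm = 0.34,
                                          orientation_sd_deg = 0,
                                          soft_tissue_deg = 0, seed = 5))
  d <- match("foot_r", ses$devices)
  eo_bound <- 2 * asin(0.34 / 63.9) * 180 / pi  # right-foot cluster
  mount <- gaitmocap:::SIM_MOUNTS[["foot_r"]]
  angs <- vapply(seq(1, length(ses$time), by = 7), function(f) {
    Rs <- matrix(ses$rot[f, d, ], 3, byrow = TRUE)
    Rb <- matrix(traj$rotations[f, "foot_r", ], 3, byrow = TRUE)
    jit <- t(Rb %*% mount) %*% Rs
    acos(min(1, (sum(diag(jit)) - 1) / 2)) * 180 / pi
  }, numeric(1))
  expect_lt(max(angs), eo_bound + 1e-9)
  expect_gt(max(angs), 0.1 * eo_bound)  # noise is actually present
})

test_that("treadmill ankle trajectories oscillate about a fixed station", {
  sim <- simulate_gait_session(gait_profile("optical"), 8, noise_none(seed = 2))
  z <- sim$trajectories$positions[, "foot_r", "z"]
  walk <- z[seq(round(length(z) * 0.4), length(z))]
  expect_lt(abs(mean(walk)), 25)
  expect_gt(max(walk) - min(walk), 50)
  expect_equal(sim$session$belt_speed, 120)
})

test_that("the test-retest generator has the commanded error structure", {
  tab <- simulate_test_retest(n_subjects = 200, between_subject_sd = 4.5,
                              within_subject_sd = 1.2, seed = 31)
  rep <- reliability_report(tab)
  # SEM estimates the within-subject error SD
  expect_true(all(abs(rep$sem - 1.2) / 1.2 < 0.15))
  expect_equal(mean(rep$sem), 1.2, tolerance = 0.05)

  # zero within-subject error -> perfect agreement downstream
  tab0 <- simulate_test_retest(n_subjects = 20, between_subject_sd = 4,
                               within_subject_sd = 0, seed = 5)
  rep0 <- reliability_report(tab0)
  expect_true(all(rep0$icc == 1))
  expect_true(all(rep0$mdc95 == 0))

  expect_error(simulate_test_retest(n_subjects = 1), "at least 2")
  expect_error(simulate_test_retest(between_subject_sd = 0), "positive")
  expect_error(simulate_test_retest(within_subject_sd = -1), "non-negative")

  # a cohort with reference-like dispersion lands MDC95 in the
  # few-centimetre range for step length
  tab33 <- simulate_test_retest(n_subjects = 33, between_subject_sd = 4.6,
                                within_subject_sd = 1.7, seed = 8)
  rep33 <- reliability_report(tab33)
  sl <- rep33[rep33$variable == "step_length", ]
  expect_gt(sl$mdc95, 2)
  expect_lt(sl$mdc95, 7)
})

test_that("increasing orientation noise does not improve event timing", {
  timing_err <- function(sd) {
    errs <- c()
    for (seed in 1:2) {
      r <- run_sim_pipeline(
        gait_profile(),
        noise_model(orientation_sd_deg = sd, soft_tissue_deg = 0, seed = seed),
        6)
      m <- match_truth_events(r$events, r$sim$truth$events)
      errs <- c(errs, abs(m$errors))
    }
    mean(errs, na.rm = TRUE)
  }
  e_low <- timing_err(0.05)
  e_high <- timing_err(1.0)
  expect_lte(e_low, e_high)
})
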