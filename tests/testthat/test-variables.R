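geom_at <- function(ipsi_t1, contra_t1, ipsi_t6, dur = 1, belt = NA_real_) {
  stride_geometry(ipsi_t1, contra_t1, ipsi_t6, dur, belt)
}

test_that("step length and width read the right components and are translation invariant", {
  g <- geom_at(c(5, 4, 60), c(-7, 4, 1), c(5, 4, 119))
  expect_equal(step_length(g), 59)
  expect_equal(step_width(g), 12)
  # coincident ankles
  g0 <- geom_at(c(0, 4, 0), c(0, 4, 0), c(0, 4, 0))
  expect_equal(step_length(g0), 0)
  expect_equal(step_width(g0), 0)
  # rigid translation of the world frame changes nothing
  off <- c(13, -2, 101)
  g2 <- geom_at(c(5, 4, 60) + off, c(-7, 4, 1) + off, c(5, 4, 119) + off)
  expect_equal(step_length(g2), step_length(g))
  expect_equal(step_width(g2), step_width(g))
  g_na <- geom_at(c(5, 4, 60), c(NA, NA, NA), c(5, 4, 119))
  expect_error(step_length(g_na), "contralateral")
})

test_that("support percentages follow their event definitions", {
  s <- support_percentages(t1 = 0, t2 = 6, t4 = 30, t5 = 36, t6 = 60)
  expect_equal(s[["single"]], 40)
  expect_equal(s[["double"]], 20)
  # degenerate double support
  s0 <- support_percentages(0, 0, 30, 30, 60)
  expect_equal(s0[["double"]], 0)
  # uniform time dilation leaves percentages unchanged
  s2 <- support_percentages(0, 18, 90, 108, 180)
  expect_equal(s2, s)
  expect_error(support_percentages(10, 12, 20, 24, 10), "T6")
})

test_that("gait speed distinguishes over-ground and treadmill", {
  g <- geom_at(c(0, 4, 10), c(0, 4, -40), c(0, 4, 130), dur = 1)
  expect_equal(gait_speed(g, treadmill = FALSE), 120)
  still <- geom_at(c(0, 4, 10), c(0, 4, -40), c(0, 4, 10), dur = 1)
  expect_equal(gait_speed(still, treadmill = FALSE), 0)
  tread <- geom_at(c(0, 4, 10), c(0, 4, -40), c(0, 4, 10), dur = 0.9,
                   belt = 114.2)
  expect_equal(gait_speed(tread), 114.2)
  expect_error(gait_speed(still, treadmill = TRUE), "belt")
})

test_that("range of motion between events is a windowed max-min", {
  expect_equal(rom_between_events(rep(4.2, 100), 10, 60), 0)
  expect_equal(rom_between_events(seq(-10, 25, length.out = 100), 1, 100), 35)
  x <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(rom_between_events(x, 1, 100), 2, tolerance = 1e-3)
  # constant offset leaves the range unchanged
  expect_equal(rom_between_events(x + 57, 1, 100), rom_between_events(x, 1, 100))
  expect_error(rom_between_events(x, 60, 10), "window")
  expect_error(rom_between_events(x, 1, 200), "window")
})

test_that("support identity singleR + singleL + double = 100 on simulator tables", {
  for (modality in c("imu", "optical")) {
    r <- run_sim_pipeline(gait_profile(modality), noise_model(seed = 17), 8)
    st <- r$variables$strides
    singles <- tapply(st$single_support, st$side, mean)
    doubles <- tapply(st$double_support, st$side, mean)
    total <- singles[["R"]] + singles[["L"]] + mean(doubles)
    expect_lt(abs(total - 100), 0.5)
  }
})

test_that("25 identical strides give zero dispersion and a stable mean", {
  r <- run_sim_pipeline(gait_profile(), noise_none(seed = 23), 25)
  m <- match_truth_events(r$events, r$sim$truth$events)
  st <- r$variables$strides[r$variables$strides$stride %in% m$stride_ids, ]
  stR <- st[st$side == "R", ]
  # noise-free periodic gait: every stride identical up to frame rounding
  # (the ankle separation changes ~1.2 cm per frame at contact, so half a
  # frame of event quantisation bounds the residual dispersion)
  expect_lt(stats::sd(stR$step_length), 0.7)
  expect_lt(stats::sd(stR$hip_flexion_extension), 0.3)
  expect_equal(mean(stR$step_length), stR$step_length[1], tolerance = 0.7)
})

test_that("fewer valid strides than recommended warns; none is an error", {
  r <- run_sim_pipeline(gait_profile(), noise_none(seed = 29), 4)
  expect_warning(compute_gait_variables(r$series, r$events), "strides")
  empty <- r$events[r$events$valid == FALSE, ]
  expect_error(suppressWarnings(compute_gait_variables(r$series, empty)),
               "valid")
})

test_that("averaging reduces between-stride dispersion roughly as sqrt(n)", {
  # i.i.d. per-stride noise: the SD of a 25-stride mean must come out near
  # SD/5 (factor 1.5 slack)
  set.seed(41)
  per_stride_sd <- 2.0
  strides <- matrix(stats::rnorm(25 * 200, mean = 59, sd = per_stride_sd),
                    nrow = 25)
  means <- colMeans(strides)
  expect_lt(stats::sd(means), 1.5 * per_stride_sd / sqrt(25))
  expect_gt(stats::sd(means), per_stride_sd / sqrt(25) / 1.5)
})
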