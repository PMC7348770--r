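test_that("sliding-window smoothing preserves constants and length", {
  const <- event_curve(rep(3.7, 200), rate = 60)
  expect_equal(smooth_curve(const, 0.2)$values, const$values)
  # a sub-sample window is the identity
  noisy <- event_curve(sin(1:100) + 0.1, rate = 60)
  expect_equal(smooth_curve(noisy, 0.01)$values, noisy$values)
  # flat window behaves too
  expect_equal(smooth_curve(const, 0.2, shape = "flat")$values, const$values)
  expect_error(smooth_curve(event_curve(1:5, rate = 60), 0.2), "shorter")
})

test_that("smoothing reduces the error of a noisy sinusoid", {
  set.seed(2)
  t <- seq(0, 10, by = 1 / 60)
  clean <- 10 * sin(2 * pi * t)
  noisy <- clean + stats::rnorm(length(t), sd = 1)
  sm <- smooth_curve(event_curve(noisy, 60), 0.2)$values
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(sm - clean), rms(noisy - clean))
})

test_that("extrema of a sinusoid land on analytic phases and alternate", {
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  cv <- smooth_curve(event_curve(sin(2 * pi * t), 60), 0.2)
  ext <- find_extrema(cv)
  expect_identical(sum(ext$type == "max"), 10L)
  expect_identical(sum(ext$type == "min"), 10L)
  expect_true(all(ext$type[-1] != ext$type[-nrow(ext)]))
  # maxima at t = 0.25 + k, minima at 0.75 + k, within one frame
  maxima <- ext$frame[ext$type == "max"]
  expect_true(all(abs(maxima - ((0.25 + 0:9) * 60 + 1)) <= 1))

  ramp <- event_curve(seq(0, 1, length.out = 300), 60)
  expect_identical(nrow(find_extrema(ramp)), 0L)
})

test_that("extrema match a brute-force neighbour scan on a compound signal", {
  set.seed(5)
  t <- seq(0, 8, by = 1 / 60)
  x <- 8 * sin(2 * pi * 0.9 * t) + 2 * sin(2 * pi * 1.8 * t + 1) +
    stats::rnorm(length(t), sd = 0.2)
  sm <- smooth_curve(event_curve(x, 60), 0.2)$values
  ext <- find_extrema(event_curve(sm, 60), min_separation_s = 0.25)
  # oracle: exhaustive local comparison on the same smoothed series
  oracle <- c()
  for (i in 2:(length(sm) - 1)) {
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]) oracle <- c(oracle, i)
    if (sm[i] < sm[i - 1] && sm[i] <= sm[i + 1]) oracle <- c(oracle, -i)
  }
  # every retained extremum is a true local extremum of the smoothed curve
  expect_true(all(ext$frame %in% abs(oracle)))
})

test_that("event detection is exact on noise-free simulator strides", {
  r <- run_sim_pipeline(gait_profile(), noise_none(seed = 31), 6)
  m <- match_truth_events(r$events, r$sim$truth$events)
  expect_true(all(!is.na(m$stride_ids)))
  expect_identical(max(abs(m$errors)), 0)
  # ordering invariant on every valid stride
  ev <- as.data.frame(r$events)
  v <- ev[ev$valid, ]
  expect_true(all(v$T1 < v$T2 & v$T2 <= v$T3 & v$T3 < v$T4 &
                    v$T4 < v$T5 & v$T5 < v$T6))
})

test_that("flat curves yield a no-events error", {
  flat <- event_curve(rep(0.3, 600), 60)
  expect_error(detect_events_imu(flat, flat), "minimum of flexion")
  expect_error(detect_events_opt(flat, flat), "minimum of flexion")
})

test_that("swapping left and right curves swaps the event table sides", {
  r <- run_sim_pipeline(gait_profile("optical"), noise_none(seed = 8), 4)
  aR <- ankle_displacement_curve(r$series, "R")
  aL <- ankle_displacement_curve(r$series, "L")
  e1 <- as.data.frame(detect_events_opt(aR, aL))
  e2 <- as.data.frame(detect_events_opt(aL, aR))
  e2$side <- ifelse(e2$side == "R", "L", "R")
  e2 <- e2[order(e2$T1, e2$side), ]
  e1 <- e1[order(e1$T1, e1$side), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1[, -1], e2[, -1])
})

test_that("shifting curves in time shifts every event equally", {
  r <- run_sim_pipeline(gait_profile(), noise_none(seed = 13), 4)
  hR <- hip_fe_curve(r$series, "R")
  hL <- hip_fe_curve(r$series, "L")
  k <- 17
  shift <- function(cv) {
    cv$values <- c(rep(cv$values[1], k), cv$values[seq_len(length(cv$values) - k)])
    cv
  }
  e1 <- as.data.frame(detect_events_imu(hR, hL))
  e2 <- as.data.frame(detect_events_imu(shift(hR), shift(hL)))
  v1 <- e1[e1$valid, ]; v2 <- e2[e2$valid, ]
  # compare strides present in both (boundary strides may differ)
  # ignore strides near the truncated end of the shifted series
  n_curve <- length(hR$values)
  v1 <- v1[v1$T6 + k + 30 < n_curve, ]
  common <- intersect(paste(v1$side, v1$T1 + k), paste(v2$side, v2$T1))
  expect_gte(length(common), nrow(v1) - 2)
  for (key in common) {
    i <- match(key, paste(v1$side, v1$T1 + k))
    j <- match(key, paste(v2$side, v2$T1))
    expect_equal(as.numeric(v2[j, c("T2", "T3", "T4", "T5", "T6")]),
                 as.numeric(v1[i, c("T2", "T3", "T4", "T5", "T6")]) + k)
  }
})

test_that("straight-section selection validates manual ranges and finds turns", {
  r <- run_sim_pipeline(gait_profile(), noise_none(seed = 3), 4)
  nf <- length(r$series$time)
  sec <- select_straight_sections(r$series, manual = list(c(1, nf)))
  expect_identical(nrow(sec), 1L)
  expect_identical(c(sec$start, sec$end), c(1L, nf))
  expect_error(
    select_straight_sections(r$series, manual = list(c(1, 100), c(50, 200))),
    "overlap")
  # empty manual list: one full-session section (treadmill use)
  sec0 <- select_straight_sections(r$series, manual = list())
  expect_identical(c(sec0$start, sec0$end), c(1L, nf))

  # a 180-degree turn splits the capture into two straight sections
  turn <- run_sim_pipeline(gait_profile(turn_after_strides = 4),
                           noise_none(seed = 3), 9)
  auto <- select_straight_sections(turn$series)
  expect_identical(nrow(auto), 2L)
  t_turn <- turn$sim$truth$walk_start_s +
    (1 + 4) * turn$sim$truth$stride_time
  f_turn <- round(t_turn * turn$series$rate)
  expect_lt(auto$end[1], f_turn + 2 * turn$series$rate)
  expect_gt(auto$start[2], f_turn)
})

test_that("stride normalisation resamples to 101 points with exact endpoints", {
  ramp <- seq(0, 50, by = 0.5)
  out <- normalize_stride(ramp, 1, length(ramp))
  expect_identical(length(out), 101L)
  expect_equal(out, seq(0, 50, length.out = 101))
  expect_identical(out[1], ramp[1])
  expect_identical(out[101], ramp[length(ramp)])

  # a sinusoidal stride keeps its peak within 1% of the analytic phase
  t <- seq(0, 1, by = 1 / 200)
  y <- sin(2 * pi * (t - 0.1))
  out2 <- normalize_stride(y, 1, length(y))
  expect_lt(abs(which.max(out2) - 1 - 35), 1.01)  # peak at 35% of the cycle
  expect_error(normalize_stride(y, 1, 2), "3 frames")
  expect_error(normalize_stride(y, 1, 1e5), "outside")
})
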