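test_that("pooled SD follows the RMS convention with a mean option", {
  expect_equal(pooled_sd(0.9, 0.9), 0.9)
  expect_equal(pooled_sd(0, 0), 0)
  # hand evaluation of sqrt((4.6^2 + 4.8^2)/2)
  expect_equal(pooled_sd(4.6, 4.8), 4.701063, tolerance = 1e-6)
  expect_equal(pooled_sd(4.6, 4.8, method = "mean"), 4.7)
  expect_error(pooled_sd(-1, 2), "non-negative")
})

test_that("ICC(2,1) matches a variance-component oracle and its edge cases", {
  test <- c(10, 12, 15, 19)
  retest <- c(11, 13, 14, 20)
  # brute-force two-way ANOVA mean squares, written out from sums
  n <- 4; k <- 2
  vals <- rbind(test, retest)
  grand <- mean(vals)
  ssr <- k * sum((colMeans(vals) - grand)^2)
  ssc <- n * sum((rowMeans(vals) - grand)^2)
  sst <- sum((vals - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_agreement(test, retest), icc_oracle, tolerance = 1e-12)

  expect_equal(icc_agreement(test, test), 1)
  expect_error(icc_agreement(c(3, 3, 3), c(3, 3, 3)), "between-subject")
  expect_error(icc_agreement(1, 2), "at least 2")

  # consistency form differs when a systematic session shift exists
  shifted <- test + 5
  expect_gt(icc_agreement(test, shifted, model = "3,1"),
            icc_agreement(test, shifted))
})

test_that("ICC recovers a known variance ratio generatively", {
  set.seed(77)
  n <- 500
  true <- stats::rnorm(n, 50, sqrt(9))      # between-subject variance 9
  e1 <- stats::rnorm(n, 0, 1)               # error variance 1 -> ICC = 0.9
  e2 <- stats::rnorm(n, 0, 1)
  expect_equal(icc_agreement(true + e1, true + e2), 0.9, tolerance = 0.02)
})

test_that("MDC95 and its derived forms follow the closed formulas", {
  # printed single-support row: SDs 0.9/0.9, ICC 0.89 -> 0.8 at 1 d.p.
  expect_equal(round(mdc95(0.9, 0.9, 0.89), 1), 0.8)
  expect_equal(mdc95(0.9, 0.9, 0.89), 1.96 * sqrt(2) * 0.9 * sqrt(0.11),
               tolerance = 1e-12)
  expect_equal(mdc95(3, 5, 1), 0)
  # hand evaluation with unrounded pooling (prints as 3.45, not the
  # table's 3.5 which propagates rounded intermediates)
  expect_equal(mdc95(4.6, 4.8, 0.93), 3.447, tolerance = 1e-3)
  expect_error(mdc95(1, 1, 1.2), "exceed")

  expect_equal(mdces95(0, 2), 0)
  expect_equal(mdces95(2, 2), 1)
  expect_equal(mdces95(3.45, 4.6), 0.75, tolerance = 1e-3)
  expect_error(mdces95(1, 0), "undefined")

  expect_equal(mdc_group(3, 1), 3)
  expect_equal(mdc_group(3, 4), 1.5)
  expect_equal(mdc_group(3, 25), 0.6)
  expect_error(mdc_group(3, 0), "positive")
})

test_that("MDC95 is monotone in its arguments", {
  iccs <- seq(0, 0.99, by = 0.01)
  vals <- mdc95(2, 2, iccs)
  expect_true(all(diff(vals) < 0))  # increasing in (1 - ICC)
  ns <- 1:30
  expect_true(all(diff(mdc_group(5, ns)) < 0))
})

test_that("SEM and MDC scale with the data; ICC and MDCes95 do not", {
  set.seed(12)
  test <- stats::rnorm(40, 30, 4)
  retest <- test + stats::rnorm(40, 0, 1.5)
  c0 <- 3.7
  icc1 <- icc_agreement(test, retest)
  icc2 <- icc_agreement(c0 * test, c0 * retest)
  expect_equal(icc1, icc2, tolerance = 1e-9)
  m1 <- mdc95(stats::sd(test), stats::sd(retest), icc1)
  m2 <- mdc95(stats::sd(c0 * test), stats::sd(c0 * retest), icc2)
  expect_equal(m2, c0 * m1, tolerance = 1e-9)
  expect_equal(mdces95(m2, stats::sd(c0 * test)),
               mdces95(m1, stats::sd(test)), tolerance = 1e-9)
})

test_that("the reliability report reproduces per-variable statistics", {
  tab <- simulate_test_retest(n_subjects = 40, between_subject_sd = 4,
                              within_subject_sd = 1, seed = 3)
  rep <- reliability_report(tab)
  expect_identical(nrow(rep), 12L)
  expect_true(all(rep$icc >= -1 & rep$icc <= 1))
  expect_true(all(rep$mdc95 >= 0))
  expect_equal(rep$mdc95, 1.96 * sqrt(2) * rep$sem, tolerance = 1e-12)
  # one variable cross-checked by hand
  sl <- tab[tab$variable == "step_length", ]
  wide <- merge(sl[sl$session == "test", c("subject", "value")],
                sl[sl$session == "retest", c("subject", "value")],
                by = "subject")
  row <- rep[rep$variable == "step_length", ]
  expect_equal(row$test_mean, mean(wide$value.x))
  expect_equal(row$icc, icc_agreement(wide$value.x, wide$value.y))

  # degenerate agreement: identical sessions
  tab2 <- tab
  tab2$value[tab2$session == "retest"] <-
    tab2$value[tab2$session == "test"]
  rep2 <- reliability_report(tab2)
  expect_true(all(rep2$icc == 1))
  expect_true(all(rep2$mdc95 == 0))
  expect_true(all(rep2$sem == 0))
})

test_that("category summaries average the right rows", {
  rep <- data.frame(
    variable = c("step_length", "step_length", "step_width", "single_support",
                 "gait_speed", "trunk_tilt", "hip_flexion_extension"),
    side = c("R", "L", "R", "R", NA, "R", "R"),
    mdc95 = c(3.5, 3.0, 5.5, 1.6, 6.5, 1.7, 2.8),
    icc = c(0.93, 0.95, 0.72, 0.93, 0.97, 0.94, 0.93),
    mdces95 = c(0.8, 0.6, 1.6, 0.7, 0.5, 0.7, 0.8))
  s <- reliability_summary(rep)
  expect_equal(unname(s$mdc95_by_category[["step"]]), mean(c(3.5, 3.0, 5.5)))
  expect_equal(unname(s$mdc95_by_category[["kinematic"]]), mean(c(1.7, 2.8)))
  expect_equal(s$mean_icc, mean(rep$icc))
  # sides averaged per variable
  sl <- s$mdc95_by_variable
  expect_equal(sl$mdc95[sl$variable == "step_length"], 3.25)
  # a single-variable report summarises to itself
  s1 <- suppressWarnings(reliability_summary(rep[5, ]))
  expect_equal(unname(s1$mdc95_by_category[["speed"]]), 6.5)
})
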