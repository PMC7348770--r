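#' @title Test-retest reproducibility statistics
#'
#' @description
#' Reproducibility of a gait variable measured twice on the same subjects
#' is summarised by the intraclass correlation coefficient (ICC), the
#' standard error of measurement `SEM = SDpooled * sqrt(1 - ICC)` and the
#' minimal detectable change at 95% confidence
#' `MDC95 = 1.96 * sqrt(2) * SEM`, plus its effect-size form
#' `MDCes95 = MDC95 / SDtest` and the group form
#' `MDC95group = MDC95 / sqrt(n)`.  `SDpooled` pools the test and retest
#' standard deviations.
#'
#' @name reliability
NULL

#' Pooled standard deviation of test and retest
#'
#' Root-mean-square pooling `sqrt((sd_test^2 + sd_retest^2) / 2)` by
#' default (the variance-pooling convention); `method = "mean"` uses the
#' arithmetic mean of the two SDs.  The two coincide for equal SDs.
#'
#' @param sd_test,sd_retest non-negative standard deviations.
#' @param method `"rms"` (default) or `"mean"`.
#' @return pooled SD.
#' @export
pooled_sd <- function(sd_test, sd_retest, method = c("rms", "mean")) {
  method <- match.arg(method)
  if (any(c(sd_test, sd_retest) < 0) || !all(is.finite(c(sd_test, sd_retest)))) {
    stop("standard deviations must be finite and non-negative", call. = FALSE)
  }
  if (method == "rms") sqrt((sd_test^2 + sd_retest^2) / 2)
  else (sd_test + sd_retest) / 2
}

#' Intraclass correlation coefficient for test-retest agreement
#'
#' ICC(2,1): two-way random effects, absolute agreement, single
#' measurement -- the standard model for same-rater test-retest designs.
#' `model = "3,1"` gives the two-way mixed, consistency form.  Mean squares
#' come from the two-way ANOVA `value ~ subject + session`.
#'
#' @param test,retest paired numeric vectors (one value per subject).
#' @param model `"2,1"` (default) or `"3,1"`.
#' @return ICC clipped to `[-1, 1]`.
#' @export
icc_agreement <- function(test, retest, model = c("2,1", "3,1")) {
  model <- match.arg(model)
  stopifnot(length(test) == length(retest))
  ok <- is.finite(test) & is.finite(retest)
  test <- test[ok]; retest <- retest[ok]
  n <- length(test)
  if (n < 2L) stop("ICC needs at least 2 complete subject pairs", call. = FALSE)
  k <- 2L
  d <- data.frame(value = c(test, retest),
                  subject = factor(rep(seq_len(n), times = k)),
                  session = factor(rep(c("test", "retest"), each = n)))
  # F-tests are not used, only the mean squares; aov warns about them on a
  # perfect fit (retest identical to test), which is a legitimate input here
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + session, data = d))[["Mean Sq"]])
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  if (msr <= .Machine$double.eps * max(1, mean(d$value)^2)) {
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  }
  icc <- if (model == "2,1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  min(1, max(-1, icc))
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SDpooled * sqrt(1 - ICC)`.
#'
#' @param sd_test,sd_retest standard deviations of the test and retest
#'   session means across subjects.
#' @param icc intraclass correlation coefficient (`<= 1`).
#' @param method SD pooling method, see [pooled_sd()].
#' @return MDC95 in the units of the variable.
#' @export
mdc95 <- function(sd_test, sd_retest, icc, method = c("rms", "mean")) {
  if (any(icc > 1)) stop("ICC cannot exceed 1", call. = FALSE)
  sem <- pooled_sd(sd_test, sd_retest, method) * sqrt(1 - icc)
  1.96 * sqrt(2) * sem
}

#' Effect-size form of the MDC95
#'
#' `MDCes95 = MDC95 / SDtest`: the number of baseline standard deviations
#' the experiment can detect.
#'
#' @param mdc95_value an [mdc95()] value.
#' @param sd_test baseline (test) SD, strictly positive.
#' @return dimensionless ratio.
#' @export
mdces95 <- function(mdc95_value, sd_test) {
  if (any(sd_test <= 0)) stop("MDCes95 undefined for sd_test <= 0", call. = FALSE)
  mdc95_value / sd_test
}

#' Group-level MDC95
#'
#' `MDC95group = MDC95 / sqrt(n)` for evaluating mean changes in a group
#' of `n` subjects.
#'
#' @param mdc95_value an [mdc95()] value.
#' @param n group size (integer `>= 1`).
#' @return group MDC95.
#' @export
mdc_group <- function(mdc95_value, n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer", call. = FALSE)
  mdc95_value / sqrt(n)
}

#' Category of a gait variable
#'
#' Maps variable names onto the four reporting categories: step measures,
#' support percentages, gait speed and kinematic ranges.
#'
#' @param variable character vector of variable names.
#' @return character vector of categories.
#' @export
variable_category <- function(variable) {
  v <- tolower(variable)
  ifelse(grepl("step", v), "step",
         ifelse(grepl("support", v), "support",
                ifelse(grepl("speed", v), "speed", "kinematic")))
}

#' Per-variable test-retest reliability report
#'
#' @param table long-format data frame with columns `subject`, `variable`,
#'   `side`, `session` (`"test"`/`"retest"`) and `value`.
#' @param icc_model `"2,1"` (default) or `"3,1"`.
#' @param sd_method SD pooling method, see [pooled_sd()].
#' @return data frame of class `reliability_report`: one row per variable
#'   and side with test/retest mean and SD, mean difference, ICC, SEM,
#'   MDC95 and MDCes95.
#' @export
reliability_report <- function(table, icc_model = "2,1", sd_method = "rms") {
  need <- c("subject", "variable", "side", "session", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  combos <- unique(table[, c("variable", "side")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    v <- combos$variable[i]; s <- combos$side[i]
    sub <- table[table$variable == v & (table$side %in% s | (is.na(s) & is.na(table$side))), ]
    wide <- merge(sub[sub$session == "test", c("subject", "value")],
                  sub[sub$session == "retest", c("subject", "value")],
                  by = "subject", suffixes = c("_test", "_retest"))
    if (nrow(wide) < 2L) {
      stop("variable ", v, " needs at least 2 complete test/retest pairs",
           call. = FALSE)
    }
    sd_t <- stats::sd(wide$value_test)
    sd_r <- stats::sd(wide$value_retest)
    icc <- icc_agreement(wide$value_test, wide$value_retest, icc_model)
    mdc <- mdc95(sd_t, sd_r, icc, sd_method)
    dif <- wide$value_retest - wide$value_test
    data.frame(variable = v, side = s,
               category = variable_category(v),
               n = nrow(wide),
               test_mean = mean(wide$value_test), test_sd = sd_t,
               retest_mean = mean(wide$value_retest), retest_sd = sd_r,
               dif_mean = mean(dif), dif_sd = stats::sd(dif),
               icc = icc,
               sem = pooled_sd(sd_t, sd_r, sd_method) * sqrt(1 - icc),
               mdc95 = mdc,
               mdces95 = if (sd_t > 0) mdces95(mdc, sd_t) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' Category summaries of a reliability report
#'
#' Unweighted means of the MDC95 column within each reporting category
#' (step measures, support percentages, gait speed, kinematic ranges), the
#' mean ICC and mean MDCes95 over all rows, and the right/left-averaged
#' MDC95 per variable.  Accepts any data frame carrying `variable`,
#' `mdc95`, `icc` and (optionally) `mdces95` and `side` columns, so it can
#' equally summarise an externally tabulated report.
#'
#' @param report a [reliability_report()] or compatible data frame.
#' @return list with `mdc95_by_category`, `mean_icc`, `mean_mdces95` and
#'   `mdc95_by_variable` (sides averaged).
#' @export
reliability_summary <- function(report) {
  if (!all(c("variable", "mdc95", "icc") %in% names(report))) {
    stop("report needs variable, mdc95 and icc columns", call. = FALSE)
  }
  if (!"category" %in% names(report)) {
    report$category <- variable_category(report$variable)
  }
  expected <- c("step", "support", "speed", "kinematic")
  missing_cat <- setdiff(expected, unique(report$category))
  if (length(missing_cat)) {
    warning("partial summary: no rows for category ",
            paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  by_cat <- tapply(report$mdc95, report$category, mean)
  by_var <- stats::aggregate(mdc95 ~ variable, data = report, FUN = mean)
  list(mdc95_by_category = by_cat[intersect(expected, names(by_cat))],
       mean_icc = mean(report$icc),
       mean_mdces95 = if ("mdces95" %in% names(report)) {
         mean(report$mdces95, na.rm = TRUE)
       } else NA_real_,
       mdc95_by_variable = by_var)
}

#' Bundled reference reliability table
#'
#' Reference test-retest results for the two configurations (IMU
#' over-ground and optical treadmill) of the measurement system this
#' package models, as published for a 33-subject healthy cohort: per
#' variable and side the session means and SDs, mean difference, ICC,
#' MDCes95 and MDC95.  Useful as a comparison baseline and for exercising
#' [reliability_summary()] on real-world numbers.
#'
#' @param configuration `"imu"` or `"optical"`.
#' @return data frame with one row per variable and side.
#' @export
reference_reliability <- function(configuration = c("imu", "optical")) {
  configuration <- match.arg(configuration)
  path <- system.file("extdata", "reference_reliability.csv",
                      package = "gaitmocap", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$configuration == configuration, ]
  tab$category <- variable_category(tab$variable)
  rownames(tab) <- NULL
  tab
}
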