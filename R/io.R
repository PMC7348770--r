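#' @title Capture files, configuration and the analysis pipeline
#'
#' @description
#' Captures are stored as plain CSV with a small `#`-prefixed header
#' (schema version, modality, rate, units).  IMU rows carry one quaternion
#' per device, optical rows one row-major rotation plus a translation.
#' [run_pipeline()] ties the modules together: (simulate or read) ->
#' calibrate -> track -> select sections -> detect events -> variables.
#'
#' @name io
NULL

CAPTURE_SCHEMA <- "gaitmocap/capture/1"

#' Write a capture session to CSV
#'
#' @param session a [capture_session()].
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_capture <- function(session, path) {
  stopifnot(inherits(session, "capture_session"))
  header <- c(
    paste0("# schema: ", CAPTURE_SCHEMA),
    paste0("# modality: ", session$modality),
    paste0("# rate_hz: ", format(session$rate, digits = 12)),
    paste0("# devices: ", paste(session$devices, collapse = ";")),
    paste0("# units: time=s;length=cm;quaternion=wxyz"),
    paste0("# neutral_frames: ",
           if (length(session$neutral_frames)) {
             paste0(min(session$neutral_frames), ":", max(session$neutral_frames))
           } else ""),
    paste0("# belt_speed_cms: ",
           if (is.na(session$belt_speed)) "" else format(session$belt_speed))
  )
  df <- data.frame(time = session$time)
  for (d in seq_along(session$devices)) {
    dev <- session$devices[d]
    if (session$modality == "imu") {
      q <- session$quat[, d, , drop = TRUE]
      cols <- paste0(dev, ".q", c("w", "x", "y", "z"))
      for (j in 1:4) df[[cols[j]]] <- q[, j]
    } else {
      r <- session$rot[, d, , drop = TRUE]
      tr <- session$trans[, d, , drop = TRUE]
      rc <- paste0(dev, ".r", c("11", "12", "13", "21", "22", "23", "31", "32", "33"))
      for (j in 1:9) df[[rc[j]]] <- r[, j]
      tc <- paste0(dev, ".t", c("x", "y", "z"))
      for (j in 1:3) df[[tc[j]]] <- tr[, j]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a capture session from CSV
#'
#' Validates the schema version, timestamp monotonicity and the declared
#' rate against the median frame spacing (within 1%).
#'
#' @param path a file written by [write_capture()].
#' @return a [capture_session()].
#' @export
read_capture <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1L]))
  }
  schema <- get("schema")
  if (is.null(schema) || !startsWith(schema, "gaitmocap/capture/")) {
    stop("not a capture file (missing schema header)", call. = FALSE)
  }
  major <- sub("^gaitmocap/capture/", "", schema)
  if (major != "1") stop("unsupported capture schema version ", major, call. = FALSE)
  modality <- get("modality")
  rate <- as.numeric(get("rate_hz"))
  devices <- strsplit(get("devices"), ";")[[1L]]
  nf_txt <- get("neutral_frames")
  neutral <- if (!is.null(nf_txt) && nzchar(nf_txt)) {
    rng <- as.integer(strsplit(nf_txt, ":")[[1L]])
    rng[1L]:rng[2L]
  } else integer()
  belt_txt <- get("belt_speed_cms")
  belt <- if (!is.null(belt_txt) && nzchar(belt_txt)) as.numeric(belt_txt) else NA_real_

  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (anyNA(df$time) || is.unsorted(df$time, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  spacing <- stats::median(diff(df$time))
  if (abs(1 / spacing - rate) > 0.01 * rate) {
    stop("declared rate ", rate, " Hz disagrees with median frame spacing (",
         format(1 / spacing, digits = 6), " Hz)", call. = FALSE)
  }
  nf <- nrow(df)
  pick <- function(cols) {
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      stop("capture file misses column(s) ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    as.matrix(df[, cols])
  }
  if (modality == "imu") {
    quat <- array(NA_real_, c(nf, length(devices), 4L))
    for (d in seq_along(devices)) {
      quat[, d, ] <- pick(paste0(devices[d], ".q", c("w", "x", "y", "z")))
    }
    capture_session("imu", rate, df$time, devices, quat = quat,
                    neutral_frames = neutral, belt_speed = belt)
  } else {
    rot <- array(NA_real_, c(nf, length(devices), 9L))
    trans <- array(NA_real_, c(nf, length(devices), 3L))
    for (d in seq_along(devices)) {
      rot[, d, ] <- pick(paste0(devices[d], ".r",
                                c("11", "12", "13", "21", "22", "23", "31", "32", "33")))
      trans[, d, ] <- pick(paste0(devices[d], ".t", c("x", "y", "z")))
    }
    capture_session("optical", rate, df$time, devices, rot = rot, trans = trans,
                    neutral_frames = neutral, belt_speed = belt)
  }
}

#' Write a gait event table to CSV
#' @param events a `gait_event_table`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Run the full gait-analysis pipeline
#'
#' Stages: obtain a capture (simulate from a profile, or read a capture
#' file), Fitbody calibration, tracking, straight-section selection, event
#' detection and gait variables.  Every stage logs the parameters it uses;
#' a failing stage aborts with its name.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{capture}{path to a capture CSV, or `NULL` to simulate;}
#'     \item{simulate}{list of [gait_profile()] arguments plus optional
#'       `n_strides` and `noise` ([noise_model()] arguments);}
#'     \item{seed}{RNG seed for simulation;}
#'     \item{frame0}{calibration frame or `NULL` for the neutral segment
#'       midpoint;}
#'     \item{sections}{list of `c(start, end)` ranges, `"auto"`, or `NULL`
#'       for the full capture;}
#'     \item{height}{subject stature (cm) when reading a capture;}
#'     \item{out_dir}{output directory (created); `NULL` returns results
#'       without writing.}
#'   }
#' @return list with `session`, `calibration`, `series`, `sections`,
#'   `events`, `variables` and the paths written (if any).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$capture)) {
    session <- stage("read", read_capture(config$capture))
    say("read capture: ", config$capture, " (", session$modality, ", ",
        session$rate, " Hz)")
    height <- config$height %||% 173.1
    profile <- NULL
  } else {
    args <- config$simulate %||% list()
    noise_args <- args$noise %||% list()
    args$noise <- NULL
    n_strides <- args$n_strides %||% 25
    args$n_strides <- NULL
    profile <- do.call(gait_profile, args)
    noise_args$seed <- noise_args$seed %||% (config$seed %||% 1L)
    noise <- do.call(noise_model, noise_args)
    say("simulating ", n_strides, " strides (", profile$modality,
        ", seed ", noise$seed, ")")
    sim <- stage("simulate", simulate_gait_session(profile, n_strides, noise))
    session <- sim$session
    truth <- sim$truth
    height <- profile$height
  }

  skeleton <- stage("skeleton",
                    build_skeleton(anthropometrics(height), mode = "imu"))
  calibration <- stage("calibrate",
                       calibrate(session, skeleton, frame0 = config$frame0))
  say("calibrated at frame ", calibration$frame0)
  series <- stage("track", track(session, calibration, skeleton))

  sections <- NULL
  if (identical(config$sections, "auto")) {
    sections <- stage("sections", select_straight_sections(series))
    say("auto sections: ", nrow(sections))
  } else if (!is.null(config$sections)) {
    sections <- stage("sections",
                      select_straight_sections(series, manual = config$sections))
  }

  events <- stage("events", {
    if (session$modality == "imu") {
      detect_events_imu(hip_fe_curve(series, "R"), hip_fe_curve(series, "L"),
                        sections)
    } else {
      detect_events_opt(ankle_displacement_curve(series, "R"),
                        ankle_displacement_curve(series, "L"), sections)
    }
  })
  say("detected ", nrow(events), " strides (", sum(events$valid), " valid)")
  variables <- stage("variables", compute_gait_variables(series, events))

  out <- list(session = session, calibration = calibration, series = series,
              sections = sections, events = events, variables = variables,
              truth = truth, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      calibration = file.path(config$out_dir, "calibration.json"),
      events = file.path(config$out_dir, "events.csv"),
      variables = file.path(config$out_dir, "variables.csv"),
      summary = file.path(config$out_dir, "summary.csv"),
      log = file.path(config$out_dir, "pipeline.log"))
    calibration_to_json(calibration, paths$calibration)
    write_events(events, paths$events)
    write_gait_variables(variables, paths$variables)
    utils::write.csv(variables$summary, paths$summary, row.names = FALSE)
    writeLines(log, paths$log)
    out$paths <- paths
  }
  out
}
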