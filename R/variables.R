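#' @title Spatio-temporal and kinematic gait variables
#'
#' @description
#' Twelve variables are computed per stride and side from the tracked bone
#' poses and the detected events, then averaged over the stride set:
#'
#' * step length (cm): anteroposterior distance between the two ankle
#'   centres at T1;
#' * step width (cm): mediolateral distance between the two ankle centres
#'   at T1;
#' * single support (%): T2-to-T4 time over stride time;
#' * double support (%): (T1-to-T2 plus T4-to-T5) time over stride time;
#' * gait speed (cm/s): stride length over stride time, where stride
#'   length is the anteroposterior path of the ankle centre from T1 to T6
#'   (on a treadmill the belt displacement is added back);
#' * seven kinematic ranges (degrees): trunk tilt T2-T5, pelvic tilt T1-T4,
#'   hip flexion/extension T1-T4, hip adduction/abduction T4-T5, knee
#'   flexion/extension T4-T5, ankle dorsi/plantar flexion T4-T5 and ankle
#'   inversion/eversion T1-T3, each the max-minus-min of the corresponding
#'   rxzy Euler component between the two events.
#'
#' @name variables
NULL

#' Stride geometry at the gait events
#'
#' @param ankle_ipsi_t1,ankle_contra_t1 world ankle-centre positions (cm)
#'   of the ipsilateral and contralateral side at T1.
#' @param ankle_ipsi_t6 ipsilateral ankle-centre position at T6.
#' @param duration stride duration in seconds.
#' @param belt_speed treadmill belt speed (cm/s) or `NA` for over-ground.
#' @return object of class `stride_geometry`.
#' @export
stride_geometry <- function(ankle_ipsi_t1, ankle_contra_t1, ankle_ipsi_t6,
                            duration, belt_speed = NA_real_) {
  stopifnot(duration > 0)
  structure(list(ankle_ipsi_t1 = ankle_ipsi_t1,
                 ankle_contra_t1 = ankle_contra_t1,
                 ankle_ipsi_t6 = ankle_ipsi_t6,
                 duration = duration, belt_speed = belt_speed),
            class = "stride_geometry")
}

pos_component <- function(p, axis) p[[match(axis, c("x", "y", "z"))]]

#' Step length of a stride
#'
#' Anteroposterior (sagittal-plane) distance between the centres of both
#' ankle joints at initial contact.
#'
#' @param geom a [stride_geometry()].
#' @return step length in cm.
#' @export
step_length <- function(geom) {
  if (anyNA(geom$ankle_contra_t1)) stop("contralateral ankle missing at T1", call. = FALSE)
  abs(pos_component(geom$ankle_ipsi_t1, "z") - pos_component(geom$ankle_contra_t1, "z"))
}

#' Step width of a stride
#'
#' Mediolateral (frontal-plane) distance between the centres of both ankle
#' joints at initial contact.
#'
#' @param geom a [stride_geometry()].
#' @return step width in cm.
#' @export
step_width <- function(geom) {
  if (anyNA(geom$ankle_contra_t1)) stop("contralateral ankle missing at T1", call. = FALSE)
  abs(pos_component(geom$ankle_ipsi_t1, "x") - pos_component(geom$ankle_contra_t1, "x"))
}

#' Support percentages of a stride
#'
#' Single support is the T2-to-T4 fraction of the stride; double support
#' the T1-to-T2 plus T4-to-T5 fraction.
#'
#' @param t1,t2,t4,t5,t6 event frames of one valid stride.
#' @return named numeric `c(single, double)` in percent.
#' @export
support_percentages <- function(t1, t2, t4, t5, t6) {
  dur <- t6 - t1
  if (dur <= 0) stop("invalid stride: T6 must follow T1", call. = FALSE)
  c(single = 100 * (t4 - t2) / dur,
    double = 100 * ((t2 - t1) + (t5 - t4)) / dur)
}

#' Gait speed of a stride
#'
#' Stride length divided by stride time.  Over-ground the stride length is
#' the anteroposterior displacement of the ankle centre from T1 to T6; on a
#' treadmill the belt carries the path, so `belt_speed * duration` is added
#' to the (near-zero) world displacement.
#'
#' @param geom a [stride_geometry()].
#' @param treadmill logical; when `TRUE` the geometry must carry a belt
#'   speed.
#' @return gait speed in cm/s.
#' @export
gait_speed <- function(geom, treadmill = !is.na(geom$belt_speed)) {
  disp <- abs(pos_component(geom$ankle_ipsi_t6, "z") -
                pos_component(geom$ankle_ipsi_t1, "z"))
  if (treadmill) {
    if (is.na(geom$belt_speed)) {
      stop("treadmill mode requires a configured belt speed", call. = FALSE)
    }
    (disp + geom$belt_speed * geom$duration) / geom$duration
  } else {
    disp / geom$duration
  }
}

#' Range of motion between two events
#'
#' Max minus min of an angle series on the closed window `[a, b]`.
#'
#' @param values numeric angle series (degrees).
#' @param a,b event frames, `a <= b`, inside the series.
#' @return range in degrees.
#' @export
rom_between_events <- function(values, a, b) {
  if (is.na(a) || is.na(b) || a > b || a < 1L || b > length(values)) {
    stop("invalid event window [", a, ", ", b, "]", call. = FALSE)
  }
  win <- values[a:b]
  max(win) - min(win)
}

#' Reconstruct over-ground root translation by stance-foot pinning
#'
#' IMU tracking yields joint centres relative to a fixed pelvis.  For
#' over-ground walking the world path is recovered by pinning the stance
#' ankle: at each detected initial contact the newly contacted ankle is
#' anchored at its current world position, and the pelvis translates so
#' that this ankle stays put until the next contralateral contact.  Only
#' the horizontal components are reconstructed.
#'
#' @param series an IMU-mode [track()] result.
#' @param events a `gait_event_table` for the same series.
#' @return the series with world-translated positions.
#' @export
reconstruct_root <- function(series, events) {
  if (series$root_reconstructed) return(series)
  nf <- length(series$time)
  # initial contacts of both feet: each stride contributes its own T1 and,
  # through T4, the contralateral contact (needed when the capture ends
  # before that contact starts a detected stride of its own)
  contacts <- rbind(
    data.frame(T1 = events$T1, side = events$side, src = "T1"),
    data.frame(T1 = events$T4[events$valid],
               side = ifelse(events$side[events$valid] == "R", "L", "R"),
               src = "T4"))
  # a directly detected T1 is the contact estimate; a contralateral T4 only
  # stands in when no T1 was detected within 3 frames of it
  contacts <- contacts[order(contacts$T1, contacts$src), , drop = FALSE]
  keep <- !logical(nrow(contacts))
  for (i in seq_len(nrow(contacts))) {
    if (!keep[i]) next
    near <- which(abs(contacts$T1 - contacts$T1[i]) <= 3L &
                    contacts$side == contacts$side[i])
    if (any(contacts$src[near] == "T1")) {
      keep[near] <- contacts$src[near] == "T1"
      keep[near][which(keep[near])[-1L]] <- FALSE
    } else {
      keep[near] <- seq_along(near) == 1L
    }
  }
  contacts <- contacts[keep, , drop = FALSE]
  contacts <- contacts[order(contacts$T1), , drop = FALSE]
  contacts <- contacts[!duplicated(contacts$T1), , drop = FALSE]
  offset <- matrix(0, nf, 2L)  # columns x, z
  if (nrow(contacts)) {
    bounds <- c(contacts$T1, nf + 1L)
    prev_bone <- NULL
    anchor <- NULL
    for (k in seq_len(nrow(contacts))) {
      bone <- if (contacts$side[k] == "R") "foot_r" else "foot_l"
      f0 <- contacts$T1[k]; f1 <- bounds[k + 1L] - 1L
      # the offset at the switch frame still follows the outgoing stance
      # foot; the incoming foot is anchored at its world position there
      cur <- if (is.null(prev_bone)) c(0, 0) else
        anchor - series$positions[f0, prev_bone, c("x", "z")]
      anchor <- series$positions[f0, bone, c("x", "z")] + cur
      rng <- f0:f1
      offset[rng, 1L] <- anchor[1L] - series$positions[rng, bone, "x"]
      offset[rng, 2L] <- anchor[2L] - series$positions[rng, bone, "z"]
      prev_bone <- bone
    }
  }
  for (b in series$bones) {
    series$positions[, b, "x"] <- series$positions[, b, "x"] + offset[, 1L]
    series$positions[, b, "z"] <- series$positions[, b, "z"] + offset[, 2L]
  }
  series$root_reconstructed <- TRUE
  series
}

KINEMATIC_VARIABLES <- data.frame(
  variable = c("trunk_tilt", "pelvic_tilt", "hip_flexion_extension",
               "hip_adduction_abduction", "knee_flexion_extension",
               "ankle_dorsi_plantar", "ankle_inversion_eversion"),
  label = c("Range of trunk tilt T2 to T5 [deg]",
            "Range of pelvic tilt T1 to T4 [deg]",
            "Range of hip flexion-extension T1 to T4 [deg]",
            "Range of hip adduction-abduction T4 to T5 [deg]",
            "Range of knee flexion-extension T4 to T5 [deg]",
            "Range of ankle dorsi flexion T4 to T5 [deg]",
            "Range of ankle inv.-ev. T1 to T3 [deg]"),
  bone = c("thorax", "pelvis", "thigh", "thigh", "calf", "foot", "foot"),
  component = c("z", "z", "x", "z", "x", "x", "z"),
  from = c("T2", "T1", "T1", "T4", "T4", "T4", "T1"),
  to = c("T5", "T4", "T4", "T5", "T5", "T5", "T3"),
  stringsAsFactors = FALSE
)

kin_bone <- function(base, side) {
  if (base %in% c("thorax", "pelvis")) base
  else paste0(base, if (side == "R") "_r" else "_l")
}

#' Compute all gait variables
#'
#' Per-stride spatio-temporal and kinematic variables for every valid
#' stride in the event table, plus per-side means and standard deviations.
#' Invalid strides are skipped (never imputed).  For over-ground IMU series
#' the root translation is reconstructed first (see [reconstruct_root()]).
#' A warning is raised when fewer valid strides are available than the
#' count usually recommended for a stable gait mean.
#'
#' @param series a [track()] result.
#' @param events a `gait_event_table` for the same series.
#' @param treadmill logical; `TRUE` uses belt-speed-compensated stride
#'   length (requires `series$belt_speed`).
#' @param min_strides warning threshold on valid strides (default 23).
#' @return object of class `gait_variable_table`: `$strides` (one row per
#'   valid stride) and `$summary` (per-side mean and SD per variable).
#' @export
compute_gait_variables <- function(series, events,
                                   treadmill = !is.na(series$belt_speed),
                                   min_strides = 23L) {
  stopifnot(inherits(series, "bone_pose_series"))
  ev <- events[events$valid, , drop = FALSE]
  if (!nrow(ev)) stop("no valid strides", call. = FALSE)
  if (nrow(ev) < min_strides) {
    warning("only ", nrow(ev), " valid strides; means may not be stable",
            call. = FALSE)
  }
  if (!treadmill && !series$root_reconstructed) {
    series <- reconstruct_root(series, events)
  }
  rate <- series$rate

  rows <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    side <- e$side
    ipsi <- if (side == "R") "foot_r" else "foot_l"
    contra <- if (side == "R") "foot_l" else "foot_r"
    geom <- stride_geometry(
      ankle_ipsi_t1 = series$positions[e$T1, ipsi, ],
      ankle_contra_t1 = series$positions[e$T1, contra, ],
      ankle_ipsi_t6 = series$positions[e$T6, ipsi, ],
      duration = (e$T6 - e$T1) / rate,
      belt_speed = series$belt_speed)
    sup <- support_percentages(e$T1, e$T2, e$T4, e$T5, e$T6)
    out <- data.frame(stride = e$stride, side = side,
                      step_length = step_length(geom),
                      step_width = step_width(geom),
                      single_support = sup[["single"]],
                      double_support = sup[["double"]],
                      gait_speed = gait_speed(geom, treadmill))
    for (k in seq_len(nrow(KINEMATIC_VARIABLES))) {
      v <- KINEMATIC_VARIABLES[k, ]
      ang <- series$angles[, kin_bone(v$bone, side), v$component]
      out[[v$variable]] <- rom_between_events(ang, e[[v$from]], e[[v$to]])
    }
    out
  })
  strides <- do.call(rbind, rows)

  vars <- setdiff(names(strides), c("stride", "side"))
  summary <- do.call(rbind, lapply(c("R", "L"), function(s) {
    sub <- strides[strides$side == s, vars, drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(side = s, variable = vars,
               n = nrow(sub),
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)),
               row.names = NULL)
  }))

  structure(list(strides = strides, summary = summary),
            class = "gait_variable_table")
}

#' @export
print.gait_variable_table <- function(x, ...) {
  cat(sprintf("<gait_variable_table> %d strides\n", nrow(x$strides)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a gait-variable table to CSV
#'
#' Stride rows followed by summary rows (marked in the `stride` column).
#'
#' @param table a [compute_gait_variables()] result.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_gait_variables <- function(table, path) {
  utils::write.csv(table$strides, path, row.names = FALSE)
  invisible(path)
}
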