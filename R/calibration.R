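#' @title Fitbody anatomical calibration and skeletal tracking
#'
#' @description
#' The Fitbody procedure links each device (IMU or optical rigid body) to a
#' bone of the avatar from a single static neutral pose, and -- for
#' magnetometer-free IMUs -- recovers each sensor's arbitrary heading.
#'
#' Without a magnetometer every IMU reports orientation in a private global
#' frame that shares only the gravity direction with the world: its
#' horizontal reference points in a random direction.  The correction relies
#' on mounting assumptions: in the calibration pose one known axis of each
#' sensor lies (nearly) parallel to the ground at a known bearing (0 or 90
#' degrees) from the pelvis sensor's projected Y axis.  The residual between
#' the expected and the measured bearing is the per-sensor heading
#' correction `alpha`.  The pelvis sensor itself defines the shared frame:
#' its projected Y axis is yawed onto the world mediolateral axis.
#'
#' After heading correction, the sensor-to-bone rotation
#' `Rs0b = t(Rb0G) %*% Rs0G` is computed once at the calibration instant and
#' held constant (the device is assumed not to move on the segment).  During
#' tracking the absolute bone rotation is `RbiG = RsiG %*% t(Rs0b)` and the
#' joint (parent-relative) rotation is `Rbip = t(RpiG) %*% RbiG`, decomposed
#' into rxzy Euler angles.
#'
#' @name calibration
NULL

# Fixed axis permutation applied at ingestion: IMU sensor-fusion global
# frames are Z-up; the package world frame is Y-up.  This is the single
# place where the two conventions meet.
GS_TO_WORLD <- matrix(c(1, 0, 0,
                        0, 0, 1,
                        0, -1, 0), 3L, byrow = TRUE)

sensor_frame_to_world <- function(r_gs) GS_TO_WORLD %*% r_gs

world_to_sensor_frame <- function(r_world) t(GS_TO_WORLD) %*% r_world

#' Heading-correction assumptions per body part
#'
#' For each device the sensor axis assumed ground-parallel in the
#' calibration pose, and its expected ground-plane bearing (degrees,
#' magnitude) from the pelvis sensor's projected Y axis.  The pelvis is
#' excluded: it defines the shared frame.
#'
#' @return data frame with columns `bone`, `axis` ("X" or "Y"), `expected`.
#' @export
default_heading_assumptions <- function() {
  data.frame(
    bone = c("head", "arm_r", "arm_l", "forearm_r", "forearm_l",
             "hand_r", "hand_l", "thorax",
             "thigh_r", "thigh_l", "calf_r", "calf_l", "foot_r", "foot_l"),
    axis = c("X", "Y", "Y", "X", "X", "X", "X", "Y",
             "Y", "Y", "Y", "Y", "Y", "Y"),
    expected = c(90, 90, 90, 90, 90, 90, 90, 0,
                 90, 90, 90, 90, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Per-sensor heading correction angle
#'
#' Measures the ground-plane bearing of the sensor's assumed axis from the
#' pelvis sensor's projected Y axis and returns
#' `alpha = expected - measured`, wrapped to (-180, 180].  The expected
#' bearing is signed under the package's ground-angle convention (the
#' mounting guidelines orient every lateral-surface sensor the same way),
#' which is what makes the correction unambiguous for arbitrary sensor
#' headings.
#'
#' @param sensor_rotation rotation of the sensor (its private global frame,
#'   world axis convention) at the calibration instant.
#' @param pelvis_rotation pelvis sensor rotation at the calibration instant.
#' @param axis `"X"` or `"Y"`: the sensor axis assumed ground-parallel.
#' @param expected expected bearing in degrees (0 or 90 in the default
#'   assumption table).
#' @return heading correction `alpha` in degrees.
#' @export
heading_alpha <- function(sensor_rotation, pelvis_rotation, axis, expected) {
  check_rotation(sensor_rotation, tol = 1e-6)
  check_rotation(pelvis_rotation, tol = 1e-6)
  col <- match(toupper(axis), c("X", "Y", "Z"))
  if (is.na(col)) stop("axis must be 'X' or 'Y'", call. = FALSE)
  proj_p <- project_to_ground(pelvis_rotation[, 2L])
  proj_d <- tryCatch(
    project_to_ground(sensor_rotation[, col]),
    error = function(e) stop("calibration pose error: assumed ", axis,
                             "-axis is near vertical (device mis-mounted?)",
                             call. = FALSE)
  )
  measured <- angle_between_projections(proj_p, proj_d)
  wrap_angle(expected - measured)
}

#' Heading (yaw) correction rotation
#'
#' Rotation about the vertical axis by `alpha` degrees, with the layout
#' `rbind(c(cos, 0, sin), c(0, 1, 0), c(-sin, 0, cos))` in the world frame
#' (vertical = Y).
#'
#' @param alpha angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
heading_rotation <- function(alpha) {
  if (!is.finite(alpha)) stop("alpha must be finite", call. = FALSE)
  rot_y(alpha)
}

#' Apply the heading correction to a sensor rotation
#'
#' `Rs0G = RGs0G %*% Rs0Gs`: the corrected sensor orientation in the shared
#' global frame.  In the optical configuration the device already reports in
#' the shared frame and the input is returned unchanged.
#'
#' @param Rs0Gs sensor rotation in its private global frame.
#' @param RGs0G heading correction rotation (e.g. [heading_rotation()]).
#' @param modality `"imu"` or `"optical"`.
#' @return corrected rotation.
#' @export
correct_sensor <- function(Rs0Gs, RGs0G, modality = "imu") {
  if (identical(modality, "optical")) return(Rs0Gs)
  RGs0G %*% Rs0Gs
}

#' Constant sensor-to-bone rotation
#'
#' `Rs0b = t(Rb0G) %*% Rs0G`, computed once at the calibration instant and
#' assumed constant while the device stays fixed to the segment.
#'
#' @param Rb0G neutral-pose bone rotation (identity in this package's
#'   neutral convention).
#' @param Rs0G corrected sensor rotation at the calibration instant.
#' @return 3x3 rotation matrix.
#' @export
sensor_to_bone <- function(Rb0G, Rs0G) t(Rb0G) %*% Rs0G

#' Absolute bone rotation at a capture instant
#'
#' `RbiG = RsiG %*% t(Rs0b)`.  At the calibration instant this reproduces
#' the neutral bone rotation.
#'
#' @param RsiG corrected sensor rotation at instant i.
#' @param Rs0b constant sensor-to-bone rotation from [sensor_to_bone()].
#' @return 3x3 rotation matrix.
#' @export
bone_absolute <- function(RsiG, Rs0b) RsiG %*% t(Rs0b)

#' Joint (parent-relative) bone rotation
#'
#' `Rbip = t(RpiG) %*% RbiG`.  The pelvis, as the root of the chain,
#' reports its absolute rotation.
#'
#' @param RpiG parent bone absolute rotation (identity for the root).
#' @param RbiG bone absolute rotation.
#' @return 3x3 rotation matrix.
#' @export
bone_relative <- function(RpiG, RbiG) t(RpiG) %*% RbiG

# ---- capture sessions -------------------------------------------------------

#' Construct a capture session
#'
#' A capture session holds synchronous per-frame orientation streams for a
#' set of devices, each named after the bone it is mounted on.  IMU sessions
#' carry unit quaternions (w, x, y, z) expressed in each sensor's private
#' Z-up global frame; optical sessions carry rotations plus translations in
#' the shared world frame.
#'
#' @param modality `"imu"` or `"optical"`.
#' @param rate sample rate in Hz.
#' @param time numeric vector of frame timestamps (s).
#' @param devices character vector of bone names carrying a device.
#' @param quat `[frame, device, 4]` array (IMU).
#' @param rot `[frame, device, 9]` array of row-major rotation entries
#'   (optical).
#' @param trans `[frame, device, 3]` array of translations in cm (optical).
#' @param neutral_frames integer vector of frames during which the subject
#'   holds the calibration pose.
#' @param belt_speed treadmill belt speed in cm/s, or `NA` for over-ground.
#' @return object of class `capture_session`.
#' @export
capture_session <- function(modality, rate, time, devices,
                            quat = NULL, rot = NULL, trans = NULL,
                            neutral_frames = integer(),
                            belt_speed = NA_real_) {
  modality <- match.arg(modality, c("imu", "optical"))
  stopifnot(rate > 0, length(time) >= 1L)
  if (modality == "imu") {
    stopifnot(!is.null(quat), dim(quat)[2L] == length(devices))
  } else {
    stopifnot(!is.null(rot), !is.null(trans), dim(rot)[2L] == length(devices))
  }
  structure(list(modality = modality, rate = rate, time = time,
                 devices = devices, quat = quat, rot = rot, trans = trans,
                 neutral_frames = neutral_frames, belt_speed = belt_speed),
            class = "capture_session")
}

#' @export
print.capture_session <- function(x, ...) {
  cat(sprintf("<capture_session> %s, %g Hz, %d frames, %d devices (%s)\n",
              x$modality, x$rate, length(x$time), length(x$devices),
              paste(x$devices, collapse = ", ")))
  invisible(x)
}

n_frames <- function(session) length(session$time)

# Rotation of one device at one frame, in the world axis convention.
# IMU readings stay in the sensor's private heading until corrected.
session_rotation <- function(session, frame, device) {
  d <- match(device, session$devices)
  if (is.na(d)) stop("no device on bone '", device, "'", call. = FALSE)
  if (session$modality == "imu") {
    q <- session$quat[frame, d, ]
    if (anyNA(q)) return(NULL)
    sensor_frame_to_world(quat_to_rotation(q))
  } else {
    r <- session$rot[frame, d, ]
    if (anyNA(r)) return(NULL)
    matrix(r, 3L, 3L, byrow = TRUE)
  }
}

session_translation <- function(session, frame, device) {
  d <- match(device, session$devices)
  session$trans[frame, d, ]
}

# Fill NA frame runs not longer than max_gap_s by linear quaternion
# interpolation (sign-aligned, renormalised); longer runs are an error.
fill_gaps <- function(session, max_gap_s = 0.1) {
  max_run <- max(1L, floor(max_gap_s * session$rate))
  interp_block <- function(block) {  # [frame, 4] or [frame, k] numeric
    bad <- apply(block, 1L, anyNA)
    if (!any(bad)) return(block)
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (!runs$values[j]) next
      len <- runs$lengths[j]
      lo <- starts[j] - 1L; hi <- ends[j] + 1L
      if (len > max_run || lo < 1L || hi > nrow(block)) {
        stop("stream gap of ", len, " frames exceeds ", max_gap_s,
             " s (or touches the capture boundary)", call. = FALSE)
      }
      a <- block[lo, ]; b <- block[hi, ]
      if (ncol(block) == 4L && sum(a * b) < 0) b <- -b  # quaternion double cover
      for (f in seq.int(starts[j], ends[j])) {
        w <- (f - lo) / (hi - lo)
        v <- (1 - w) * a + w * b
        if (ncol(block) == 4L) v <- v / sqrt(sum(v^2))
        block[f, ] <- v
      }
    }
    block
  }
  for (d in seq_along(session$devices)) {
    if (session$modality == "imu") {
      session$quat[, d, ] <- interp_block(session$quat[, d, , drop = TRUE])
    } else {
      session$rot[, d, ] <- interp_block(session$rot[, d, , drop = TRUE])
      session$trans[, d, ] <- interp_block(session$trans[, d, , drop = TRUE])
    }
  }
  session
}

# Mean sensor rotation over a window of frames (quaternion average).
window_rotation <- function(session, frames, device) {
  qs <- lapply(frames, function(f) {
    r <- session_rotation(session, f, device)
    if (is.null(r)) NULL else rotation_to_quat(r)
  })
  qs <- qs[!vapply(qs, is.null, TRUE)]
  if (!length(qs)) return(NULL)
  ref <- qs[[1L]]
  m <- colMeans(do.call(rbind, lapply(qs, function(q) if (sum(q * ref) < 0) -q else q)))
  quat_to_rotation(m / sqrt(sum(m^2)))
}

# ---- calibration ------------------------------------------------------------

#' Run the Fitbody calibration
#'
#' Computes, from a single calibration frame (optionally an averaging
#' window), the per-device heading correction and the constant
#' sensor-to-bone rotation for every device present in the session.  The
#' subject is assumed to hold the neutral pose (upright, legs vertical,
#' feet pointing forward) at `frame0`.
#'
#' @param session a [capture_session()].
#' @param skeleton a [build_skeleton()] result.
#' @param frame0 calibration frame index (default: middle of the session's
#'   declared neutral segment, else frame 1).
#' @param assumptions heading-assumption table
#'   ([default_heading_assumptions()]); ignored for optical sessions.
#' @param window_s optional averaging window in seconds centred on `frame0`
#'   (0 = single frame).
#' @return object of class `gait_calibration` with per-device heading
#'   correction angles and sensor-to-bone rotations.
#' @export
calibrate <- function(session, skeleton, frame0 = NULL,
                      assumptions = default_heading_assumptions(),
                      window_s = 0) {
  stopifnot(inherits(session, "capture_session"))
  if (is.null(frame0)) {
    frame0 <- if (length(session$neutral_frames)) {
      session$neutral_frames[ceiling(length(session$neutral_frames) / 2)]
    } else 1L
  }
  if (frame0 < 1L || frame0 > n_frames(session)) {
    stop("frame0 outside the capture", call. = FALSE)
  }
  frames <- if (window_s > 0) {
    half <- floor(window_s * session$rate / 2)
    max(1L, frame0 - half):min(n_frames(session), frame0 + half)
  } else frame0

  get_rot <- function(dev) {
    if (length(frames) > 1L) window_rotation(session, frames, dev)
    else session_rotation(session, frames, dev)
  }

  raw <- lapply(session$devices, get_rot)
  names(raw) <- session$devices
  absent <- session$devices[vapply(raw, is.null, TRUE)]
  if (length(absent)) {
    stop("calibration failed: no data at frame0 for device(s) ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  is_imu <- session$modality == "imu"
  gamma <- 0
  if (is_imu) {
    if (!"pelvis" %in% session$devices) {
      stop("IMU calibration requires a pelvis sensor (it defines the shared frame)",
           call. = FALSE)
    }
    proj_p <- project_to_ground(raw$pelvis[, 2L])
    # anchor: the pelvis sensor's projected Y axis points to the subject's
    # left in the mounting guidelines, so yaw it onto the world -X axis
    gamma <- angle_between_projections(proj_p, c(-1, 0))
  }

  devices <- lapply(session$devices, function(dev) {
    alpha <- 0
    if (is_imu && dev != "pelvis") {
      row <- assumptions[assumptions$bone == dev, ]
      if (nrow(row) != 1L) {
        stop("no heading assumption for device '", dev, "'", call. = FALSE)
      }
      alpha <- heading_alpha(raw[[dev]], raw$pelvis, row$axis, row$expected)
    }
    correction <- if (is_imu) wrap_angle(gamma + alpha) else 0
    Rs0G <- correct_sensor(raw[[dev]], heading_rotation(correction),
                           session$modality)
    Rb0G <- diag(3)  # neutral bone frames are world-aligned
    Rs0b <- sensor_to_bone(Rb0G, Rs0G)
    local_offset <- NULL
    if (session$modality == "optical") {
      rots <- stats::setNames(rep(list(diag(3)), sum(skeleton$instrumented)),
                              instrumented_bones(skeleton))
      neutral_pos <- forward_kinematics(skeleton, rots)
      t0 <- session_translation(session, frames[ceiling(length(frames) / 2)], dev)
      local_offset <- as.numeric(t(raw[[dev]]) %*% (neutral_pos[dev, ] - t0))
    }
    list(bone = dev, alpha = alpha, correction = correction,
         Rs0b = Rs0b, Rb0G = Rb0G, local_offset = local_offset)
  })
  names(devices) <- session$devices

  structure(list(modality = session$modality, frame0 = frame0,
                 window_s = window_s, gamma = gamma, devices = devices,
                 timestamp = session$time[frame0]),
            class = "gait_calibration")
}

#' @export
print.gait_calibration <- function(x, ...) {
  cat(sprintf("<gait_calibration> %s, frame0 = %d, %d devices\n",
              x$modality, x$frame0, length(x$devices)))
  for (d in x$devices) {
    cat(sprintf("  %-10s alpha = %8.3f deg\n", d$bone, d$alpha))
  }
  invisible(x)
}

#' Serialise a calibration to JSON
#'
#' @param calibration a [calibrate()] result.
#' @param path optional file path; when missing the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
calibration_to_json <- function(calibration, path = NULL) {
  devs <- lapply(calibration$devices, function(d) {
    list(bone = d$bone, alpha = d$alpha, correction = d$correction,
         Rs0b = as.numeric(t(d$Rs0b)),  # row-major, 9 entries
         local_offset = d$local_offset)
  })
  obj <- list(schema = "gaitmocap/calibration/1", modality = calibration$modality,
              frame0 = calibration$frame0, gamma = calibration$gamma,
              window_s = calibration$window_s, devices = devs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a calibration from JSON
#' @param path file path or JSON string produced by [calibration_to_json()].
#' @return a `gait_calibration` object.
#' @export
calibration_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "gaitmocap/calibration/1")) {
    stop("unknown calibration schema: ", obj$schema, call. = FALSE)
  }
  devices <- lapply(obj$devices, function(d) {
    list(bone = d$bone, alpha = d$alpha, correction = d$correction,
         Rs0b = matrix(unlist(d$Rs0b), 3L, 3L, byrow = TRUE),
         Rb0G = diag(3),
         local_offset = if (is.null(d$local_offset)) NULL else unlist(d$local_offset))
  })
  names(devices) <- vapply(devices, `[[`, "", "bone")
  structure(list(modality = obj$modality, frame0 = obj$frame0,
                 window_s = obj$window_s, gamma = obj$gamma,
                 devices = devices, timestamp = NA_real_),
            class = "gait_calibration")
}

# ---- tracking ---------------------------------------------------------------

#' Track bone poses through a capture
#'
#' Applies the calibration frame by frame: corrects each sensor's heading
#' (IMU), converts sensor to bone rotations, decomposes joint rotations
#' into rxzy Euler angles, and places joint centres -- by forward
#' kinematics from the bone hierarchy in the IMU configuration, or driven
#' by the rigid-body translations in the optical configuration.  Stream
#' gaps up to 0.1 s are linearly interpolated on quaternions; longer gaps
#' raise an error.
#'
#' @param session a [capture_session()].
#' @param calibration a [calibrate()] result from the same session.
#' @param skeleton the [build_skeleton()] used at calibration.
#' @return object of class `bone_pose_series`: per-frame joint angles
#'   (`angles[frame, bone, c("x","z","y")]`, degrees, parent-relative),
#'   absolute rotations, and joint-centre positions (cm).
#' @export
track <- function(session, calibration, skeleton) {
  stopifnot(inherits(session, "capture_session"),
            inherits(calibration, "gait_calibration"))
  if (!identical(session$modality, calibration$modality)) {
    stop("calibration modality does not match the session", call. = FALSE)
  }
  session <- fill_gaps(session)
  devs <- session$devices
  nf <- n_frames(session)
  corr <- lapply(calibration$devices, function(d) heading_rotation(d$correction))

  parent_of <- stats::setNames(skeleton$parent, skeleton$name)
  # instrumented parent for joint decomposition (skip static in-betweens)
  joint_parent <- function(b) {
    p <- parent_of[[b]]
    while (!is.na(p) && !(p %in% devs)) p <- parent_of[[p]]
    p
  }
  jparents <- stats::setNames(lapply(devs, joint_parent), devs)

  angles <- array(NA_real_, c(nf, length(devs), 3L),
                  dimnames = list(NULL, devs, c("x", "z", "y")))
  absrot <- array(NA_real_, c(nf, length(devs), 9L), dimnames = list(NULL, devs, NULL))
  positions <- array(NA_real_, c(nf, length(devs), 3L),
                     dimnames = list(NULL, devs, c("x", "y", "z")))

  for (f in seq_len(nf)) {
    RbG <- vector("list", length(devs)); names(RbG) <- devs
    for (dev in devs) {
      Rs <- session_rotation(session, f, dev)
      RsG <- correct_sensor(Rs, corr[[dev]], session$modality)
      RbG[[dev]] <- bone_absolute(RsG, calibration$devices[[dev]]$Rs0b)
      absrot[f, dev, ] <- as.numeric(t(RbG[[dev]]))
    }
    for (dev in devs) {
      p <- jparents[[dev]]
      Rrel <- if (is.na(p)) RbG[[dev]] else bone_relative(RbG[[p]], RbG[[dev]])
      angles[f, dev, ] <- as.numeric(euler_rxzy(Rrel))
    }
    if (session$modality == "imu") {
      pos <- forward_kinematics(skeleton, RbG, missing = "inherit")
      positions[f, , ] <- pos[devs, , drop = FALSE]
    } else {
      for (dev in devs) {
        tt <- session_translation(session, f, dev)
        off <- calibration$devices[[dev]]$local_offset
        Rs <- session_rotation(session, f, dev)
        positions[f, dev, ] <- tt + as.numeric(Rs %*% off)
      }
    }
  }

  structure(list(time = session$time, rate = session$rate, bones = devs,
                 modality = session$modality, angles = angles,
                 rotations = absrot, positions = positions,
                 belt_speed = session$belt_speed,
                 root_reconstructed = session$modality == "optical"),
            class = "bone_pose_series")
}

#' @export
print.bone_pose_series <- function(x, ...) {
  cat(sprintf("<bone_pose_series> %s, %g Hz, %d frames, bones: %s\n",
              x$modality, x$rate, length(x$time), paste(x$bones, collapse = ", ")))
  invisible(x)
}

#' Extract a joint-angle curve from a tracked series
#'
#' Returns one Euler component of one bone's parent-relative rotation as an
#' event curve.  `component` follows the rxzy order: `"x"` is the
#' flexion-extension plane, `"z"` ab/adduction (tilt), `"y"` axial rotation.
#' With the world X axis pointing to the subject's right, a right-hand-rule
#' positive X rotation tips a downward-pointing segment posteriorly, so
#' clinical "flexion-positive" curves use `sign = -1` (the default for
#' [hip_fe_curve()]).
#'
#' @param series a [track()] result.
#' @param bone bone name.
#' @param component `"x"`, `"z"` or `"y"`.
#' @param sign +1 or -1 multiplier applied to the angle.
#' @return an `event_curve` (see [event_curve()]).
#' @export
joint_angle_curve <- function(series, bone, component = c("x", "z", "y"), sign = 1) {
  component <- match.arg(component)
  if (!bone %in% series$bones) stop("bone '", bone, "' not tracked", call. = FALSE)
  event_curve(sign * series$angles[, bone, component], rate = series$rate,
              kind = paste0(bone, ":", component),
              side = if (grepl("_r$", bone)) "R" else if (grepl("_l$", bone)) "L" else NA)
}

#' Hip flexion-extension curve (flexion positive)
#'
#' @param series a [track()] result.
#' @param side `"R"` or `"L"`.
#' @return an `event_curve` of hip flexion-extension in degrees.
#' @export
hip_fe_curve <- function(series, side = c("R", "L")) {
  side <- match.arg(side)
  bone <- if (side == "R") "thigh_r" else "thigh_l"
  cv <- joint_angle_curve(series, bone, "x", sign = -1)
  cv$kind <- "hip-flexion-extension"
  cv$side <- side
  cv
}

#' Ankle-centre anteroposterior displacement curve
#'
#' World Z position of the ankle joint centre (= the foot bone origin).
#'
#' @param series a [track()] result.
#' @param side `"R"` or `"L"`.
#' @param axis world axis, `"z"` (anteroposterior, default) or `"y"`
#'   (vertical).
#' @return an `event_curve` in cm.
#' @export
ankle_displacement_curve <- function(series, side = c("R", "L"), axis = c("z", "y")) {
  side <- match.arg(side)
  axis <- match.arg(axis)
  bone <- if (side == "R") "foot_r" else "foot_l"
  event_curve(series$positions[, bone, axis], rate = series$rate,
              kind = paste0("ankle-", axis, "-displacement"), side = side)
}
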