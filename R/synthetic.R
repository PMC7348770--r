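#' @title Parameterised walking-avatar simulator
#'
#' @description
#' Generates IMU quaternion streams and optical rigid-transform streams for
#' a walking avatar with known ("ground-truth") gait events and variables,
#' so the whole calibration -> tracking -> event-detection -> variables
#' pipeline can be validated without hardware.
#'
#' Joint curves belong to a time-warped cosine family: a cosine of the
#' warped stride phase `u(phi)` (piecewise linear, mapping the stance
#' fraction `[0, p]` onto `[0, 0.5]` and the swing fraction onto
#' `[0.5, 1]`, with `p = 0.5 + double_support/2`).  The family is
#' C1-periodic and places each curve's only extrema exactly at initial
#' contact and toe-off, which is what the event-detection rules assume of
#' real gait, while producing the asymmetric single/double-support timing
#' structure of human walking.
#'
#' Step geometry and hip amplitude are coupled through the leg kinematics,
#' so exactly one of `step_length` and `hip_fe_range` is commanded and the
#' other derived: commanding the hip range derives the step length from
#' the forward kinematics at contact; commanding the step length solves
#' the hip amplitude that produces it.  A constant hip ab/adduction offset
#' is always solved so that the mediolateral ankle-to-ankle distance at
#' contact equals the commanded step width.
#'
#' IMU emulation gives each sensor a private global frame: a random
#' constant heading offset (uniform on 0-360 degrees, the
#' magnetometer-free situation), optional slow heading drift, white
#' orientation noise and a low-frequency soft-tissue artefact.  Optical
#' emulation adds marker positional noise and the orientation jitter it
#' induces through each cluster's minimum marker distance.
#'
#' @name synthetic
NULL

#' Gait profile for the simulator
#'
#' Defaults describe a comfortable healthy adult walk; the kinematic-range
#' parameters are the per-stride ranges the pipeline measures between its
#' gait events (not full joint excursions).
#'
#' @param modality `"imu"` (over-ground, 60 Hz) or `"optical"` (treadmill,
#'   120 Hz).
#' @param height subject stature in cm.
#' @param step_length commanded step length, cm; `NULL` (default) derives
#'   it from the leg geometry under the commanded hip range.
#' @param step_width commanded step width, cm.
#' @param gait_speed commanded progression speed, cm/s (equals the belt
#'   speed on the treadmill); the stride time is
#'   `2 * step_length / gait_speed` once the step length is known.
#' @param double_support double-support fraction of the stride (0-1);
#'   single support is `0.5 - double_support/2` per side.
#' @param hip_fe_range hip flexion-extension range T1-T4, degrees; `NULL`
#'   solves it from a commanded `step_length`.  Exactly one of
#'   `step_length` and `hip_fe_range` must be given.
#' @param pelvic_rotation_amp pelvic axial-rotation half-amplitude,
#'   degrees.
#' @param hip_mid mid-value of the hip flexion-extension curve, degrees.
#' @param knee_peak knee flexion amplitude above `knee_min`, degrees; the
#'   knee rises monotonically through stance to its peak at toe-off (the
#'   curve family places every extremum on a gait event, so the measured
#'   T4-T5 knee range is a small fraction of this amplitude).
#' @param knee_min minimum knee flexion, degrees.
#' @param ankle_dp_range ankle dorsi/plantar range T4-T5, degrees.
#' @param hip_aa_range hip ab/adduction range T4-T5, degrees.
#' @param pelvic_tilt_range pelvic tilt range T1-T4, degrees.
#' @param trunk_tilt_range trunk tilt range T2-T5, degrees.
#' @param ankle_ie_range ankle inversion/eversion range T1-T3, degrees.
#' @param neutral_s duration of the initial neutral (calibration) segment,
#'   seconds.
#' @param ramp_strides strides over which amplitudes ramp from standing to
#'   steady gait.
#' @param turn_after_strides optional: insert a turn after this many steady
#'   strides (over-ground scenarios).
#' @param turn_angle,turn_duration_s turn magnitude (degrees about the
#'   vertical) and duration.
#' @return object of class `gait_profile`.
#' @export
gait_profile <- function(modality = c("imu", "optical"),
                         height = 173.1,
                         step_length = NULL,
                         step_width = 12,
                         gait_speed = 120,
                         double_support = 0.20,
                         hip_fe_range = if (is.null(step_length)) 35 else NULL,
                         pelvic_rotation_amp = 5,
                         hip_mid = 10,
                         knee_peak = 15,
                         knee_min = 3,
                         ankle_dp_range = 5,
                         hip_aa_range = 2.5,
                         pelvic_tilt_range = 4.8,
                         trunk_tilt_range = 6,
                         ankle_ie_range = 9,
                         neutral_s = 1.0,
                         ramp_strides = 1,
                         turn_after_strides = NULL,
                         turn_angle = 180,
                         turn_duration_s = 2) {
  modality <- match.arg(modality)
  if (is.null(step_length) == is.null(hip_fe_range)) {
    stop("specify exactly one of step_length and hip_fe_range; ",
         "the other is derived from the leg geometry", call. = FALSE)
  }
  stopifnot(gait_speed > 0, step_width >= 0,
            double_support > 0, double_support < 0.5)
  ranges <- c(hip_fe_range, knee_peak, ankle_dp_range, hip_aa_range,
              pelvic_tilt_range, trunk_tilt_range, ankle_ie_range)
  if (any(ranges < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (!is.null(step_length) && step_length <= 0) {
    stop("step_length must be positive", call. = FALSE)
  }
  structure(list(modality = modality, height = height,
                 step_length = step_length, step_width = step_width,
                 gait_speed = gait_speed,
                 double_support = double_support,
                 p_toeoff = 0.5 + double_support / 2,
                 hip_fe_range = hip_fe_range,
                 pelvic_rotation_amp = pelvic_rotation_amp,
                 hip_mid = hip_mid,
                 knee_peak = knee_peak, knee_min = knee_min,
                 ankle_dp_range = ankle_dp_range, hip_aa_range = hip_aa_range,
                 pelvic_tilt_range = pelvic_tilt_range,
                 trunk_tilt_range = trunk_tilt_range,
                 ankle_ie_range = ankle_ie_range,
                 neutral_s = neutral_s, ramp_strides = ramp_strides,
                 treadmill = modality == "optical",
                 turn_after_strides = turn_after_strides,
                 turn_angle = turn_angle, turn_duration_s = turn_duration_s),
            class = "gait_profile")
}

#' Noise model for the simulator
#'
#' @param heading_offsets random per-sensor constant heading offsets
#'   (uniform 0-360 degrees): the magnetometer-free situation.  `FALSE`
#'   emulates sensors sharing a common heading reference.
#' @param drift_dps heading drift rate magnitude, degrees/second (each
#'   sensor drifts at this rate with a random sign).
#' @param orientation_sd_deg white (frame-to-frame) orientation noise SD
#'   per axis, degrees.  Fused IMU orientation output is smooth, so the
#'   white component is small; most of the error budget lives in the
#'   slowly varying term below.
#' @param marker_sd_mm marker positional noise SD (optical), mm.
#' @param soft_tissue_deg SD of the low-frequency soft-tissue artefact
#'   added to the sensor (not bone) orientation, degrees; the dominant
#'   error source of body-worn sensors.
#' @param seed RNG seed; a fixed seed gives bit-identical streams.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(heading_offsets = TRUE, drift_dps = 0,
                        orientation_sd_deg = 0.1, marker_sd_mm = 0.34,
                        soft_tissue_deg = 0.2, seed = 1L) {
  stopifnot(drift_dps >= 0, orientation_sd_deg >= 0, marker_sd_mm >= 0,
            soft_tissue_deg >= 0)
  structure(list(heading_offsets = heading_offsets, drift_dps = drift_dps,
                 orientation_sd_deg = orientation_sd_deg,
                 marker_sd_mm = marker_sd_mm,
                 soft_tissue_deg = soft_tissue_deg, seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free noise model (random headings only)
#' @param heading_offsets keep the random per-sensor headings (default
#'   `TRUE`; they are what the calibration must undo).
#' @param seed RNG seed.
#' @return a [noise_model()] with all noise sources at zero.
#' @export
noise_none <- function(heading_offsets = TRUE, seed = 1L) {
  noise_model(heading_offsets = heading_offsets, drift_dps = 0,
              orientation_sd_deg = 0, marker_sd_mm = 0, soft_tissue_deg = 0,
              seed = seed)
}

SIM_BONES <- c("pelvis", "thorax", "thigh_r", "thigh_l",
               "calf_r", "calf_l", "foot_r", "foot_l")

# Device mounting rotations (sensor axes as columns, world coordinates, in
# the neutral pose).  Lateral-surface sensors carry Y anterior; spine
# sensors carry X along the spine; foot sensors X forward.  These satisfy
# the heading-assumption table exactly when mounted perfectly.
SIM_MOUNTS <- list(
  pelvis = cbind(c(0, -1, 0), c(-1, 0, 0), c(0, 0, -1)),
  thorax = cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)),
  thigh_r = cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0)),
  thigh_l = cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0)),
  calf_r = cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0)),
  calf_l = cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0)),
  foot_r = cbind(c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0)),
  foot_l = cbind(c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0))
)

# Map simulator bones onto bundled rigid-body clusters (for optical
# orientation jitter bounds).
SIM_CLUSTER <- c(pelvis = "pelvis", thorax = "chest",
                 thigh_r = "thigh_R", thigh_l = "thigh_L",
                 calf_r = "calf_R", calf_l = "calf_L",
                 foot_r = "foot_R", foot_l = "foot_L")

# Piecewise-linear stride-phase warp: [0, p] -> [0, 0.5], [p, 1] -> [0.5, 1].
warp_u <- function(phi, p) {
  phi <- phi %% 1
  ifelse(phi < p, phi / (2 * p), 0.5 + (phi - p) / (2 * (1 - p)))
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# Build the continuous-phase joint-angle curves for one profile.  Solves
# the constant hip ab/adduction offset (step width) and, when the step
# length is commanded, the hip amplitude.  Angles returned are rxzy Euler
# components per bone.
make_gait_curves <- function(profile, skeleton) {
  p <- profile$p_toeoff
  u <- function(phi) warp_u(phi, p)

  rom_scale <- function(shape, lo, hi) {
    grid <- seq(lo, hi, length.out = 2001L)
    v <- shape(grid)
    r <- max(v) - min(v)
    if (r <= 0) 0 else 1 / r
  }

  # unit shapes (amplitude 1 before scaling)
  hip_shape <- function(phi) 0.5 * cos(2 * pi * u(phi))
  knee_shape <- function(phi) 0.5 * (1 - cos(2 * pi * u(phi)))
  sin_shape <- function(phi) 0.5 * sin(2 * pi * u(phi))
  obl_shape <- function(phi) 0.5 * sin(2 * pi * (phi %% 1))
  trunk_shape <- function(phi) -0.5 * sin(2 * pi * (phi %% 1))

  hip_unit_rom <- rom_scale(hip_shape, 0, 0.5)
  a_knee <- profile$knee_peak  # peak value of the unit knee shape is 1
  a_dp <- profile$ankle_dp_range * rom_scale(sin_shape, 0.5, p)
  a_aa <- profile$hip_aa_range * rom_scale(sin_shape, 0.5, p)
  a_obl <- profile$pelvic_tilt_range * rom_scale(obl_shape, 0, 0.5)
  a_tr <- profile$trunk_tilt_range * rom_scale(trunk_shape, p - 0.5, p)
  a_ie <- profile$ankle_ie_range * rom_scale(sin_shape, 0, p / 2)

  # state: hip amplitude and ab/adduction offset, possibly solved below
  state <- list(
    a_hip = if (is.null(profile$hip_fe_range)) 35 * hip_unit_rom
            else profile$hip_fe_range * hip_unit_rom,
    aa_mid = 0)

  eulers_at <- function(phi, st = state) {
    phL <- phi - 0.5
    hip <- function(ph) profile$hip_mid + st$a_hip * hip_shape(ph)
    knee <- function(ph) profile$knee_min + a_knee * knee_shape(ph)
    list(
      pelvis = c(0, a_obl * obl_shape(phi),
                 profile$pelvic_rotation_amp * cos(2 * pi * phi)),
      thorax = c(0, a_tr * trunk_shape(phi), 0),
      thigh_r = c(-hip(phi), st$aa_mid + a_aa * sin_shape(phi), 0),
      thigh_l = c(-hip(phL), -(st$aa_mid + a_aa * sin_shape(phL)), 0),
      calf_r = c(knee(phi), 0, 0),
      calf_l = c(knee(phL), 0, 0),
      foot_r = c(-a_dp * sin_shape(phi), a_ie * sin_shape(phi), 0),
      foot_l = c(-a_dp * sin_shape(phL), -a_ie * sin_shape(phL), 0)
    )
  }

  positions_at <- function(phi, st = state) {
    eu <- eulers_at(phi, st)
    rel <- lapply(eu, function(a) matrix_from_euler_rxzy(a[1L], a[2L], a[3L]))
    abs <- list(pelvis = rel$pelvis)
    abs$thorax <- abs$pelvis %*% rel$thorax
    for (s in c("r", "l")) {
      abs[[paste0("thigh_", s)]] <- abs$pelvis %*% rel[[paste0("thigh_", s)]]
      abs[[paste0("calf_", s)]] <- abs[[paste0("thigh_", s)]] %*% rel[[paste0("calf_", s)]]
      abs[[paste0("foot_", s)]] <- abs[[paste0("calf_", s)]] %*% rel[[paste0("foot_", s)]]
    }
    forward_kinematics(skeleton, abs, missing = "inherit")
  }

  step_at <- function(st) {
    pos <- positions_at(0, st)
    pos["foot_r", "z"] - pos["foot_l", "z"]
  }

  # solve the ab/adduction offset for step width and, if commanded, the
  # hip amplitude for step length (both signed and monotone in their
  # parameter; weakly coupled, so iterate twice)
  for (pass in 1:2) {
    width_err <- function(aa) {
      st <- state; st$aa_mid <- aa
      pos <- positions_at(0, st)
      (pos["foot_r", "x"] - pos["foot_l", "x"]) - profile$step_width
    }
    state$aa_mid <- stats::uniroot(width_err, c(-30, 30), tol = 1e-8)$root
    if (is.null(profile$step_length)) next
    step_err <- function(a) {
      st <- state; st$a_hip <- a
      step_at(st) - profile$step_length
    }
    lo <- step_err(2); hi <- step_err(60)
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
      stop("commanded step length ", profile$step_length,
           " cm is unreachable for this profile geometry", call. = FALSE)
    }
    state$a_hip <- stats::uniroot(step_err, c(2, 60), tol = 1e-8)$root
  }

  step_length <- step_at(state)
  # a degenerate (static) profile has no forward progression; keep a
  # nominal cycle time so the capture can still be generated
  stride_time <- if (step_length > 1e-6) {
    2 * step_length / profile$gait_speed
  } else 1
  hip_range <- state$a_hip / hip_unit_rom
  knee_grid <- seq(0.5, p, length.out = 2001L)
  knee_vals <- profile$knee_min + a_knee * knee_shape(knee_grid)
  knee_range <- max(knee_vals) - min(knee_vals)

  list(curves = list(
         hip = function(phi) profile$hip_mid + state$a_hip * hip_shape(phi),
         knee = function(phi) profile$knee_min + a_knee * knee_shape(phi)),
       eulers_at = eulers_at, positions_at = positions_at,
       state = state, p = p,
       step_length = step_length, stride_time = stride_time,
       hip_fe_range = hip_range, knee_fe_range = knee_range)
}

#' Generate joint trajectories and ground truth for a walking avatar
#'
#' Produces per-frame joint angles, absolute bone rotations and joint-
#' centre positions for a capture consisting of a neutral (calibration)
#' segment, an amplitude ramp-in, `n_strides` steady strides and a short
#' tail.  Ground-truth event frames and variable values for the steady
#' strides are returned alongside.
#'
#' @param profile a [gait_profile()].
#' @param n_strides number of steady strides (>= 1).
#' @param rate sample rate in Hz (>= 20; default 60 for IMU, 120 for
#'   optical profiles).
#' @return object of class `gait_trajectories`.
#' @export
joint_trajectories <- function(profile, n_strides = 25,
                               rate = if (profile$modality == "imu") 60 else 120) {
  stopifnot(inherits(profile, "gait_profile"), n_strides >= 1)
  if (rate < 20) {
    stop("sample rate below 20 Hz would alias the gait harmonics", call. = FALSE)
  }
  skeleton <- build_skeleton(anthropometrics(profile$height), mode = "imu")
  gc <- make_gait_curves(profile, skeleton)
  Tst <- gc$stride_time
  t0 <- profile$neutral_s
  ramp_T <- profile$ramp_strides * Tst
  turn <- !is.null(profile$turn_after_strides)
  walk_T <- (profile$ramp_strides + n_strides + 1.2) * Tst +
    if (turn) profile$turn_duration_s + 0.4 * Tst else 0
  time <- seq(0, t0 + walk_T, by = 1 / rate)
  nf <- length(time)

  # optional turn: the whole-body heading ramps by turn_angle mid-capture
  # while the gait continues (ground truth assumes straight walking, so
  # turn scenarios are meant for exercising the section selection)
  heading_at <- function(t) rep(0, length(t))
  if (turn) {
    t_turn <- t0 + ramp_T + profile$turn_after_strides * Tst
    heading_at <- function(t) {
      profile$turn_angle * smoothstep((t - t_turn) / profile$turn_duration_s)
    }
  }

  angles <- array(NA_real_, c(nf, length(SIM_BONES), 3L),
                  dimnames = list(NULL, SIM_BONES, c("x", "z", "y")))
  rot <- array(NA_real_, c(nf, length(SIM_BONES), 9L),
               dimnames = list(NULL, SIM_BONES, NULL))
  pos <- array(NA_real_, c(nf, length(SIM_BONES), 3L),
               dimnames = list(NULL, SIM_BONES, c("x", "y", "z")))
  root0 <- attr(skeleton, "root_position")

  for (f in seq_len(nf)) {
    t <- time[f]
    if (t < t0) {
      eu <- lapply(SIM_BONES, function(b) c(0, 0, 0))
      names(eu) <- SIM_BONES
      r <- 0
    } else {
      phi <- (t - t0) / Tst
      r <- smoothstep(phi / profile$ramp_strides)
      eu <- gc$eulers_at(phi)
      eu <- lapply(eu, function(a) r * a)
    }
    eu$pelvis[3L] <- eu$pelvis[3L] + heading_at(t)
    rel <- lapply(eu, function(a) matrix_from_euler_rxzy(a[1L], a[2L], a[3L]))
    ab <- list(pelvis = rel$pelvis)
    ab$thorax <- ab$pelvis %*% rel$thorax
    for (s in c("r", "l")) {
      ab[[paste0("thigh_", s)]] <- ab$pelvis %*% rel[[paste0("thigh_", s)]]
      ab[[paste0("calf_", s)]] <- ab[[paste0("thigh_", s)]] %*% rel[[paste0("calf_", s)]]
      ab[[paste0("foot_", s)]] <- ab[[paste0("calf_", s)]] %*% rel[[paste0("foot_", s)]]
    }
    root <- root0
    if (!profile$treadmill && t >= t0) {
      # progression along the (possibly turned) heading
      root <- root0 + profile$gait_speed * (t - t0) *
        c(sin(heading_at(t) * pi / 180), 0, cos(heading_at(t) * pi / 180))
    }
    pk <- forward_kinematics(skeleton, ab, root_position = root,
                             missing = "inherit")
    for (b in SIM_BONES) {
      angles[f, b, ] <- eu[[b]]
      rot[f, b, ] <- as.numeric(t(ab[[b]]))
      pos[f, b, ] <- pk[b, ]
    }
  }

  # ground-truth events for the steady strides
  ev <- list()
  p <- gc$p
  offs <- c(T1 = 0, T2 = p - 0.5, T3 = p / 2, T4 = 0.5, T5 = p, T6 = 1)
  for (k in seq_len(n_strides) - 1L) {
    for (side in c("R", "L")) {
      base <- t0 + (profile$ramp_strides + k + if (side == "L") 0.5 else 0) * Tst
      tt <- base + offs * Tst
      if (max(tt) > max(time)) next
      ev[[length(ev) + 1L]] <- data.frame(
        side = side, t(round(tt * rate) + 1L), stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(side = character(), T1 = integer(), T2 = integer(),
               T3 = integer(), T4 = integer(), T5 = integer(), T6 = integer())
  if (gc$hip_fe_range == 0) events <- events[0, ]

  # frame-level ground truth: the best frame-resolution answer is the frame
  # where the sampled (noise-free) detection curve attains its extremum,
  # which can differ by one frame from rounding the continuous event time
  # on these asymmetric curves; snap each event accordingly
  if (nrow(events)) {
    if (profile$modality == "imu") {
      curve_r <- -angles[, "thigh_r", "x"]
      curve_l <- -angles[, "thigh_l", "x"]
    } else {
      curve_r <- pos[, "foot_r", "z"]
      curve_l <- pos[, "foot_l", "z"]
    }
    snap_to <- function(x, f, type, reach = 2L) {
      lo <- max(1L, f - reach); hi <- min(length(x), f + reach)
      w <- x[lo:hi]
      lo + (if (type == "max") which.max(w) else which.min(w)) - 1L
    }
    for (i in seq_len(nrow(events))) {
      ipsi <- if (events$side[i] == "R") curve_r else curve_l
      contra <- if (events$side[i] == "R") curve_l else curve_r
      events$T1[i] <- snap_to(ipsi, events$T1[i], "max")
      events$T6[i] <- snap_to(ipsi, events$T6[i], "max")
      events$T2[i] <- snap_to(contra, events$T2[i], "min")
      events$T4[i] <- snap_to(contra, events$T4[i], "max")
      events$T5[i] <- snap_to(ipsi, events$T5[i], "min")
      mid <- (contra[events$T2[i]] + contra[events$T4[i]]) / 2
      seg <- contra[events$T2[i]:events$T4[i]]
      cross <- if (seg[length(seg)] >= seg[1L]) which(seg >= mid) else which(seg <= mid)
      events$T3[i] <- events$T2[i] + (if (length(cross)) cross[1L] else 1L) - 1L
    }
  }

  # ground-truth variable values (identical for every steady stride).
  # Support percentages are frame-resolution quantities by definition, so
  # their truth is the event arithmetic on the truth frames; the analytic
  # values 100*(1-p) and 100*(2p-1) are recovered as the rate grows.
  pos_t1 <- gc$positions_at(0)
  if (nrow(events)) {
    tru_single <- mean(100 * (events$T4 - events$T2) / (events$T6 - events$T1))
    tru_double <- mean(100 * ((events$T2 - events$T1) + (events$T5 - events$T4)) /
                         (events$T6 - events$T1))
  } else {
    tru_single <- 100 * (1 - p)
    tru_double <- 100 * (2 * p - 1)
  }
  truth_vars <- data.frame(
    variable = c("step_length", "step_width", "single_support",
                 "double_support", "gait_speed", "trunk_tilt", "pelvic_tilt",
                 "hip_flexion_extension", "hip_adduction_abduction",
                 "knee_flexion_extension", "ankle_dorsi_plantar",
                 "ankle_inversion_eversion"),
    value = c(abs(pos_t1["foot_r", "z"] - pos_t1["foot_l", "z"]),
              abs(pos_t1["foot_r", "x"] - pos_t1["foot_l", "x"]),
              tru_single, tru_double,
              profile$gait_speed,
              profile$trunk_tilt_range, profile$pelvic_tilt_range,
              gc$hip_fe_range, profile$hip_aa_range,
              gc$knee_fe_range, profile$ankle_dp_range,
              profile$ankle_ie_range),
    stringsAsFactors = FALSE)

  structure(list(time = time, rate = rate, bones = SIM_BONES,
                 angles = angles, rotations = rot, positions = pos,
                 neutral_frames = which(time < t0 * 0.9),
                 profile = profile, skeleton = skeleton,
                 curves = gc,
                 truth = list(events = events, variables = truth_vars,
                              stride_time = Tst, p_toeoff = p,
                              walk_start_s = t0)),
            class = "gait_trajectories")
}

small_rotation <- function(x_deg, z_deg, y_deg) {
  matrix_from_euler_rxzy(x_deg, z_deg, y_deg)
}

# low-pass filtered white noise, unit SD, length n
lowpass_noise <- function(n, rate, cutoff_s = 0.5) {
  w <- max(3L, round(cutoff_s * rate))
  x <- stats::rnorm(n + 2L * w)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2L)
  sm <- sm[(w + 1L):(w + n)]
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) rep(0, n) else as.numeric(sm) / s
}

#' Synthesise an IMU capture from trajectories
#'
#' Each sensor stream is the bone orientation composed with a fixed
#' mounting rotation, perturbed by soft-tissue artefact and white
#' orientation noise, then expressed in the sensor's private Z-up global
#' frame with its random heading offset and drift.  A neutral-pose segment
#' precedes walking for calibration.
#'
#' @param traj a [joint_trajectories()] result.
#' @param noise a [noise_model()].
#' @return a [capture_session()] of modality `"imu"` (quaternions at the
#'   trajectory rate).
#' @export
synthesize_imu <- function(traj, noise = noise_model()) {
  stopifnot(inherits(traj, "gait_trajectories"))
  set.seed(noise$seed)
  nf <- length(traj$time)
  devs <- traj$bones
  quat <- array(NA_real_, c(nf, length(devs), 4L))
  headings <- if (isTRUE(noise$heading_offsets)) {
    stats::runif(length(devs), 0, 360)
  } else rep(0, length(devs))
  # per-sensor drift rates scattered within +-drift_dps: magnetometer-free
  # gyro integration drifts each sensor independently
  drifts <- noise$drift_dps * stats::runif(length(devs), -1, 1)
  soft <- lapply(seq_along(devs), function(i) {
    if (noise$soft_tissue_deg > 0) {
      sapply(1:3, function(j) noise$soft_tissue_deg * lowpass_noise(nf, traj$rate))
    } else matrix(0, nf, 3L)
  })
  white <- if (noise$orientation_sd_deg > 0) {
    lapply(seq_along(devs), function(i) {
      matrix(stats::rnorm(nf * 3L, sd = noise$orientation_sd_deg), nf, 3L)
    })
  } else lapply(seq_along(devs), function(i) matrix(0, nf, 3L))

  for (d in seq_along(devs)) {
    bone <- devs[d]
    mount <- SIM_MOUNTS[[bone]]
    for (f in seq_len(nf)) {
      Rb <- matrix(traj$rotations[f, bone, ], 3L, 3L, byrow = TRUE)
      pert <- small_rotation(soft[[d]][f, 1L] + white[[d]][f, 1L],
                             soft[[d]][f, 2L] + white[[d]][f, 2L],
                             soft[[d]][f, 3L] + white[[d]][f, 3L])
      RsG <- Rb %*% mount %*% pert
      psi <- headings[d] + drifts[d] * traj$time[f]
      Rgs <- world_to_sensor_frame(heading_rotation(-psi) %*% RsG)
      quat[f, d, ] <- rotation_to_quat(Rgs)
    }
  }
  capture_session("imu", traj$rate, traj$time, devs, quat = quat,
                  neutral_frames = traj$neutral_frames)
}

#' Synthesise an optical rigid-body capture from trajectories
#'
#' Rigid-body transforms in the shared world frame: rotations are the bone
#' orientation composed with the mounting rotation plus an orientation
#' jitter bounded by each cluster's maximum orientation error (derived
#' from the marker positioning noise and the cluster's minimum marker
#' distance); translations are the joint-centre positions plus marker
#' positional noise.
#'
#' @param traj a [joint_trajectories()] result.
#' @param noise a [noise_model()].
#' @return a [capture_session()] of modality `"optical"` carrying the
#'   commanded belt speed when the profile is a treadmill profile.
#' @export
synthesize_opt <- function(traj, noise = noise_model()) {
  stopifnot(inherits(traj, "gait_trajectories"))
  set.seed(noise$seed + 1L)
  nf <- length(traj$time)
  devs <- traj$bones
  rot <- array(NA_real_, c(nf, length(devs), 9L))
  trans <- array(NA_real_, c(nf, length(devs), 3L))
  rb <- default_rigid_bodies()
  rb_lab <- paste0(rb$name, ifelse(is.na(rb$side) | rb$side == "", "",
                                   paste0("_", rb$side)))
  dmin <- vapply(devs, function(b) {
    row <- match(SIM_CLUSTER[[b]], rb_lab)
    min(rb$d12[row], rb$d13[row], rb$d23[row])
  }, numeric(1))

  for (d in seq_along(devs)) {
    bone <- devs[d]
    mount <- SIM_MOUNTS[[bone]]
    eo_max <- if (noise$marker_sd_mm > 0) {
      2 * asin(min(1, noise$marker_sd_mm / dmin[d])) * 180 / pi
    } else 0
    for (f in seq_len(nf)) {
      Rb <- matrix(traj$rotations[f, bone, ], 3L, 3L, byrow = TRUE)
      if (eo_max > 0) {
        ang <- stats::runif(1, 0, eo_max)
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3L,
                    byrow = TRUE)
        a <- ang * pi / 180
        jit <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
        Rs <- Rb %*% mount %*% jit
      } else {
        Rs <- Rb %*% mount
      }
      rot[f, d, ] <- as.numeric(t(Rs))
      trans[f, d, ] <- traj$positions[f, bone, ] +
        stats::rnorm(3L, sd = noise$marker_sd_mm / 10)  # mm -> cm
    }
  }
  capture_session("optical", traj$rate, traj$time, devs, rot = rot,
                  trans = trans, neutral_frames = traj$neutral_frames,
                  belt_speed = if (traj$profile$treadmill) {
                    traj$profile$gait_speed
                  } else NA_real_)
}

#' Simulate a complete capture session
#'
#' Convenience wrapper: [joint_trajectories()] plus the modality-matched
#' synthesiser.
#'
#' @param profile a [gait_profile()].
#' @param n_strides steady strides to generate.
#' @param noise a [noise_model()].
#' @param rate sample rate override (Hz).
#' @return list with `session` (a [capture_session()]), `truth` (events
#'   and variable ground truth) and `trajectories`.
#' @export
simulate_gait_session <- function(profile = gait_profile(), n_strides = 25,
                                  noise = noise_model(),
                                  rate = if (profile$modality == "imu") 60 else 120) {
  traj <- joint_trajectories(profile, n_strides, rate)
  session <- if (profile$modality == "imu") synthesize_imu(traj, noise)
  else synthesize_opt(traj, noise)
  list(session = session, truth = traj$truth, trajectories = traj)
}

#' Simulate a test-retest cohort for the reliability statistics
#'
#' Each subject's true value per variable is drawn around the profile's
#' ground-truth variable means with SD `between_subject_sd`; each session
#' observation adds independent measurement error with SD
#' `within_subject_sd`.
#'
#' @param profile a [gait_profile()] (its ground-truth variables provide
#'   the cohort means), or a named numeric vector of means.
#' @param n_subjects number of subjects (>= 2).
#' @param between_subject_sd true between-subject SD (scalar or named per
#'   variable), > 0.
#' @param within_subject_sd measurement-error SD (scalar or named), >= 0.
#' @param seed RNG seed.
#' @return long-format data frame (`subject`, `variable`, `side`,
#'   `session`, `value`) suitable for [reliability_report()].
#' @export
simulate_test_retest <- function(profile = gait_profile(), n_subjects = 33,
                                 between_subject_sd = 4, within_subject_sd = 1,
                                 seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (any(between_subject_sd <= 0)) {
    stop("between-subject SD must be positive", call. = FALSE)
  }
  if (any(within_subject_sd < 0)) {
    stop("within-subject SD must be non-negative", call. = FALSE)
  }
  means <- if (inherits(profile, "gait_profile")) {
    skel <- build_skeleton(anthropometrics(profile$height), "imu")
    gc <- make_gait_curves(profile, skel)
    pos <- gc$positions_at(0)
    c(step_length = abs(pos["foot_r", "z"] - pos["foot_l", "z"]),
      step_width = abs(pos["foot_r", "x"] - pos["foot_l", "x"]),
      single_support = 100 * (1 - gc$p),
      double_support = 100 * (2 * gc$p - 1),
      gait_speed = profile$gait_speed,
      trunk_tilt = profile$trunk_tilt_range,
      pelvic_tilt = profile$pelvic_tilt_range,
      hip_flexion_extension = gc$hip_fe_range,
      hip_adduction_abduction = profile$hip_aa_range,
      knee_flexion_extension = gc$knee_fe_range,
      ankle_dorsi_plantar = profile$ankle_dp_range,
      ankle_inversion_eversion = profile$ankle_ie_range)
  } else profile
  sb <- rep(between_subject_sd, length.out = length(means))
  sw <- rep(within_subject_sd, length.out = length(means))
  if (!is.null(names(between_subject_sd))) {
    sb <- between_subject_sd[names(means)]
  }
  if (!is.null(names(within_subject_sd))) {
    sw <- within_subject_sd[names(means)]
  }
  set.seed(seed)
  rows <- list()
  for (v in seq_along(means)) {
    true <- means[v] + stats::rnorm(n_subjects, 0, sb[v])
    for (ses in c("test", "retest")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = seq_len(n_subjects),
        variable = names(means)[v], side = "R", session = ses,
        value = true + stats::rnorm(n_subjects, 0, sw[v]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
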