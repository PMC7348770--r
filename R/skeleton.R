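#' @title Bone hierarchy and anthropometric scaling
#'
#' @description
#' The avatar is a 20-bone skeleton of which 15 bones can carry a device
#' (IMU or optical marker cluster); the remaining 5 are static children that
#' complete the figure.  The pelvis is the root; the pelvis parents the
#' thorax and thighs, the thighs parent the calves, the calves the feet.
#' Every bone's local frame has X as the flexion axis, Z as the ab/adduction
#' axis and Y as the longitudinal axis, all aligned with the world frame in
#' the neutral (calibration) pose.  Bone origins sit on the joint centre at
#' the proximal end of the bone (the femur origin is the hip centre); the
#' pelvis origin is the geometric centre of the pelvis.
#'
#' @name skeleton
NULL

# Longitudinal segment proportions as fractions of stature, from classical
# segment-proportion tables used for scaling link models to subject height.
SEGMENT_PROPORTIONS <- c(
  hip_height     = 0.530,  # ground to hip joint centre
  thigh          = 0.245,  # hip to knee centre
  calf           = 0.246,  # knee to ankle centre
  ankle_height   = 0.039,
  foot_length    = 0.152,
  pelvis_to_hip  = 0.025,  # pelvis geometric centre sits above the hips
  pelvis_thorax  = 0.078,  # pelvis centre to thoraco-lumbar joint
  thorax_neck    = 0.210,
  neck_head      = 0.052,
  upper_arm      = 0.186,
  forearm        = 0.146,
  hand           = 0.108
)

# Fraction of the inter-iliac-crest distance spanned by the hip joint
# centres (simplified landmark-to-joint regression).
HIP_SPACING_FACTOR <- 0.70

#' Anthropometric measurements of a participant
#'
#' @param height stature in cm.
#' @param elbow_span distance between elbows with arms projected in the
#'   frontal plane, cm (used for shoulder width).
#' @param iliac_crest_width distance between the iliac crests, cm (used for
#'   hip joint spacing).
#' @param leg_length optional hip-centre to ankle-centre distance, cm;
#'   derived from height when missing.
#' @param landmarks optional named list of 3-vector landmark positions (cm,
#'   world frame) for the optical configuration: `acromion_r/l`,
#'   `trochanter_r/l`, `malleolus_r/l`, `iliac_crest_r/l`.
#' @return object of class `anthropometrics`.
#' @export
anthropometrics <- function(height,
                            elbow_span = 0.50 * height,
                            iliac_crest_width = 0.16 * height,
                            leg_length = NULL,
                            landmarks = NULL) {
  stopifnot(is.numeric(height), length(height) == 1L)
  if (!is.finite(height) || height <= 0) stop("height must be positive", call. = FALSE)
  if (elbow_span <= 0 || iliac_crest_width <= 0) {
    stop("all anthropometric measurements must be positive", call. = FALSE)
  }
  if (is.null(leg_length)) {
    leg_length <- (SEGMENT_PROPORTIONS[["thigh"]] + SEGMENT_PROPORTIONS[["calf"]]) * height
  }
  if (leg_length <= 0 || leg_length >= height) {
    stop("leg length must be positive and smaller than height", call. = FALSE)
  }
  structure(list(height = height, elbow_span = elbow_span,
                 iliac_crest_width = iliac_crest_width,
                 leg_length = leg_length, landmarks = landmarks),
            class = "anthropometrics")
}

REQUIRED_LANDMARKS <- c("acromion_r", "acromion_l", "trochanter_r", "trochanter_l",
                        "malleolus_r", "malleolus_l", "iliac_crest_r", "iliac_crest_l")

#' Build a scaled skeleton definition
#'
#' In `imu` mode every bone length scales linearly with height using fixed
#' segment-proportion ratios, and the hip spacing comes from the iliac-crest
#' width.  In `optical` mode the leg dimensions and hip spacing are taken
#' from pointer-measured landmarks (trochanter-to-malleolus distance split
#' into thigh and calf by the same proportions).
#'
#' @param anthro an [anthropometrics()] object.
#' @param mode `"imu"` or `"optical"`.
#' @return object of class `skeleton`: a data frame with one row per bone
#'   (`name`, `parent`, `instrumented`, `length`, `offset_x/y/z` giving the
#'   bone origin in its parent's frame) plus attributes `root_position` and
#'   `mode`.
#' @export
build_skeleton <- function(anthro, mode = c("imu", "optical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(anthro, "anthropometrics"))
  h <- anthro$height
  p <- SEGMENT_PROPORTIONS

  if (mode == "optical") {
    lm <- anthro$landmarks
    missing_lm <- setdiff(REQUIRED_LANDMARKS, names(lm))
    if (length(missing_lm)) {
      stop("optical mode requires landmarks: ", paste(missing_lm, collapse = ", "),
           call. = FALSE)
    }
    leg_r <- sqrt(sum((lm$trochanter_r - lm$malleolus_r)^2))
    leg_l <- sqrt(sum((lm$trochanter_l - lm$malleolus_l)^2))
    leg <- (leg_r + leg_l) / 2
    thigh <- leg * p[["thigh"]] / (p[["thigh"]] + p[["calf"]])
    calf <- leg - thigh
    hip_spacing <- sqrt(sum((lm$trochanter_r - lm$trochanter_l)^2))
  } else {
    thigh <- p[["thigh"]] * h
    calf <- p[["calf"]] * h
    leg <- thigh + calf
    hip_spacing <- HIP_SPACING_FACTOR * anthro$iliac_crest_width
  }

  shoulder_w <- max(anthro$elbow_span - 2 * p[["upper_arm"]] * h * sin(15 * pi / 180),
                    0.15 * h)
  half_hip <- hip_spacing / 2
  half_sh <- shoulder_w / 2

  bone <- function(name, parent, instrumented, length, offset) {
    data.frame(name = name, parent = parent, instrumented = instrumented,
               length = length,
               offset_x = offset[1L], offset_y = offset[2L], offset_z = offset[3L],
               stringsAsFactors = FALSE)
  }

  rows <- rbind(
    bone("pelvis", NA, TRUE,  p[["pelvis_to_hip"]] * h, c(0, 0, 0)),
    bone("thorax", "pelvis", TRUE, p[["thorax_neck"]] * h, c(0,  p[["pelvis_thorax"]] * h, 0)),
    bone("neck",   "thorax", FALSE, p[["neck_head"]] * h, c(0,  p[["thorax_neck"]] * h, 0)),
    bone("head",   "neck",   TRUE,
         (1 - p[["hip_height"]] - p[["pelvis_to_hip"]] - p[["pelvis_thorax"]] -
            p[["thorax_neck"]] - p[["neck_head"]]) * h,
         c(0, p[["neck_head"]] * h, 0)),
    bone("clavicle_r", "thorax", FALSE, half_sh, c(0, p[["thorax_neck"]] * h * 0.9, 0)),
    bone("clavicle_l", "thorax", FALSE, half_sh, c(0, p[["thorax_neck"]] * h * 0.9, 0)),
    bone("arm_r", "clavicle_r", TRUE, p[["upper_arm"]] * h, c( half_sh, 0, 0)),
    bone("arm_l", "clavicle_l", TRUE, p[["upper_arm"]] * h, c(-half_sh, 0, 0)),
    bone("forearm_r", "arm_r", TRUE, p[["forearm"]] * h, c(0, -p[["upper_arm"]] * h, 0)),
    bone("forearm_l", "arm_l", TRUE, p[["forearm"]] * h, c(0, -p[["upper_arm"]] * h, 0)),
    bone("hand_r", "forearm_r", TRUE, p[["hand"]] * h, c(0, -p[["forearm"]] * h, 0)),
    bone("hand_l", "forearm_l", TRUE, p[["hand"]] * h, c(0, -p[["forearm"]] * h, 0)),
    bone("thigh_r", "pelvis", TRUE, thigh, c( half_hip, -p[["pelvis_to_hip"]] * h, 0)),
    bone("thigh_l", "pelvis", TRUE, thigh, c(-half_hip, -p[["pelvis_to_hip"]] * h, 0)),
    bone("calf_r", "thigh_r", TRUE, calf, c(0, -thigh, 0)),
    bone("calf_l", "thigh_l", TRUE, calf, c(0, -thigh, 0)),
    bone("foot_r", "calf_r", TRUE, p[["foot_length"]] * h, c(0, -calf, 0)),
    bone("foot_l", "calf_l", TRUE, p[["foot_length"]] * h, c(0, -calf, 0)),
    bone("toes_r", "foot_r", FALSE, 0.04 * h,
         c(0, -(p[["ankle_height"]] * h), p[["foot_length"]] * h * 0.7)),
    bone("toes_l", "foot_l", FALSE, 0.04 * h,
         c(0, -(p[["ankle_height"]] * h), p[["foot_length"]] * h * 0.7))
  )
  stopifnot(all(rows$length > 0))

  root_y <- p[["hip_height"]] * h + p[["pelvis_to_hip"]] * h
  structure(rows,
            root_position = c(0, root_y, 0),
            leg_length = leg,
            hip_spacing = hip_spacing,
            mode = mode,
            anthropometrics = anthro,
            class = c("skeleton", "data.frame"))
}

#' Standing height of a skeleton
#'
#' Vertical extent from the ground to the top of the head in the neutral
#' pose; equals the subject's stature by construction in IMU mode.
#'
#' @param skeleton a [build_skeleton()] result.
#' @return height in cm.
#' @export
skeleton_height <- function(skeleton) {
  rots <- setNames(rep(list(diag(3)), sum(skeleton$instrumented)),
                   instrumented_bones(skeleton))
  pos <- forward_kinematics(skeleton, rots)
  head_len <- skeleton$length[skeleton$name == "head"]
  pos["head", "y"] + head_len
}

#' Instrumented bone names of a skeleton
#' @param skeleton a [build_skeleton()] result.
#' @return character vector of bone names that carry a device.
#' @export
instrumented_bones <- function(skeleton) skeleton$name[skeleton$instrumented]

skeleton_offset <- function(skeleton, bone) {
  i <- match(bone, skeleton$name)
  c(skeleton$offset_x[i], skeleton$offset_y[i], skeleton$offset_z[i])
}

#' Forward kinematics of the bone hierarchy
#'
#' Places every bone origin (= joint centre at the proximal end of the bone)
#' given one absolute rotation per bone.  Each origin is
#' `parent origin + parent rotation %*% offset`, where the offset is the
#' neutral-pose displacement of the bone origin in its parent's frame.
#' Uninstrumented bones missing from `rotations` inherit their parent's
#' rotation (static children); instrumented bones must be supplied.
#'
#' @param skeleton a [build_skeleton()] result.
#' @param rotations named list of 3x3 absolute (world) rotations, one per
#'   instrumented bone, including `"pelvis"`.
#' @param root_position world position (cm) of the pelvis origin; defaults
#'   to the skeleton's neutral root position.
#' @param missing `"error"` (default): a missing instrumented-bone rotation
#'   is an incomplete-chain error; `"inherit"`: uninstrumented segments of a
#'   partially instrumented capture ride along with their parent.
#' @return matrix with one row per bone (rownames = bone names) of world
#'   joint-centre positions in cm.
#' @export
forward_kinematics <- function(skeleton, rotations,
                               root_position = attr(skeleton, "root_position"),
                               missing = c("error", "inherit")) {
  missing <- match.arg(missing)
  if (!"pelvis" %in% names(rotations)) {
    stop("incomplete kinematic chain: missing rotation for bone(s) pelvis",
         call. = FALSE)
  }
  if (missing == "error") {
    need <- instrumented_bones(skeleton)
    missing_rot <- setdiff(need, names(rotations))
    if (length(missing_rot)) {
      stop("incomplete kinematic chain: missing rotation for bone(s) ",
           paste(missing_rot, collapse = ", "), call. = FALSE)
    }
  }
  pos <- matrix(NA_real_, nrow(skeleton), 3L,
                dimnames = list(skeleton$name, c("x", "y", "z")))
  rot <- vector("list", nrow(skeleton))
  names(rot) <- skeleton$name
  for (i in seq_len(nrow(skeleton))) {
    b <- skeleton$name[i]
    parent <- skeleton$parent[i]
    if (is.na(parent)) {
      pos[b, ] <- root_position
      rot[[b]] <- rotations[[b]]
    } else {
      pr <- rot[[parent]]
      pos[b, ] <- pos[parent, ] + as.numeric(pr %*% skeleton_offset(skeleton, b))
      rot[[b]] <- if (b %in% names(rotations)) rotations[[b]] else pr
    }
  }
  pos
}
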