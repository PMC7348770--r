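# Shared helpers: run the simulator through the full pipeline and match
# detected strides to the generator's ground truth.

run_sim_pipeline <- function(profile, noise, n_strides) {
  sim <- simulate_gait_session(profile, n_strides = n_strides, noise = noise)
  skeleton <- sim$trajectories$skeleton
  calibration <- calibrate(sim$session, skeleton)
  series <- track(sim$session, calibration, skeleton)
  events <- if (profile$modality == "imu") {
    detect_events_imu(hip_fe_curve(series, "R"), hip_fe_curve(series, "L"))
  } else {
    detect_events_opt(ankle_displacement_curve(series, "R"),
                      ankle_displacement_curve(series, "L"))
  }
  variables <- suppressWarnings(compute_gait_variables(series, events))
  list(sim = sim, skeleton = skeleton, calibration = calibration,
       series = series, events = events, variables = variables)
}

# one row per truth stride: frame errors of the matched detected stride
# (NA row when no valid detected stride starts within `slack` frames)
match_truth_events <- function(events, truth_events, slack = 3) {
  det <- as.data.frame(events)
  evcols <- c("T1", "T2", "T3", "T4", "T5", "T6")
  out <- matrix(NA_real_, nrow(truth_events), 6,
                dimnames = list(NULL, evcols))
  ids <- rep(NA_integer_, nrow(truth_events))
  for (i in seq_len(nrow(truth_events))) {
    cand <- det[det$side == truth_events$side[i] & det$valid, ]
    if (!nrow(cand)) next
    j <- which.min(abs(cand$T1 - truth_events$T1[i]))
    if (abs(cand$T1[j] - truth_events$T1[i]) > slack) next
    out[i, ] <- as.numeric(cand[j, evcols]) - as.numeric(truth_events[i, evcols])
    ids[i] <- cand$stride[j]
  }
  list(errors = out, stride_ids = ids)
}

# mean recovered value per variable over the matched strides, minus truth
recovery_errors <- function(variables, stride_ids, truth_variables) {
  st <- variables$strides[variables$strides$stride %in% stride_ids, ]
  vn <- setdiff(names(st), c("stride", "side"))
  tv <- stats::setNames(truth_variables$value, truth_variables$variable)
  colMeans(st[, vn]) - tv[vn]
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotation(q / sqrt(sum(q^2)))
}
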