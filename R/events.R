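#' @title Gait-event detection from kinematic curves
#'
#' @description
#' Six events are detected per stride and side: T1 initial contact, T2
#' contralateral toe-off, T3 mid-single-support reference, T4 contralateral
#' initial contact, T5 toe-off, T6 the next initial contact (T6 of one
#' stride is T1 of the next on the same side).  Detection needs no
#' instrumentation beyond the kinematics themselves: the IMU configuration
#' uses the hip flexion-extension curves of both legs, the optical
#' configuration the anteroposterior displacement curves of both ankle
#' centres.  Both pairs of curves peak at initial contact and bottom out at
#' toe-off, so the rules are shared:
#'
#' * T1 = ipsilateral curve maximum,
#' * T2 = contralateral minimum after T1,
#' * T4 = contralateral maximum after T2,
#' * T5 = ipsilateral minimum after T4,
#' * T6 = next ipsilateral maximum,
#' * T3 = frame where the contralateral curve crosses the midpoint of its
#'   T2-to-T4 excursion (approximately mid single support).
#'
#' Curves are smoothed with a short sliding window before the extremum
#' search to suppress spurious peaks; detected extrema are then refined on a
#' lightly smoothed copy so the wider window does not bias their timing.
#'
#' @name events
NULL

#' Construct an event curve
#'
#' @param values numeric frame-indexed series (degrees or cm).
#' @param rate sample rate in Hz.
#' @param kind free-text curve kind (e.g. "hip-flexion-extension").
#' @param side `"R"`, `"L"` or `NA`.
#' @return object of class `event_curve`.
#' @export
event_curve <- function(values, rate, kind = "curve", side = NA) {
  stopifnot(is.numeric(values), rate > 0)
  if (!all(is.finite(values))) stop("event curve must be finite", call. = FALSE)
  structure(list(values = as.numeric(values), rate = rate, kind = kind,
                 side = side), class = "event_curve")
}

window_weights <- function(n, shape = c("hann", "flat")) {
  shape <- match.arg(shape)
  if (n <= 1L) return(1)
  w <- if (shape == "flat") rep(1, n) else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w / sum(w)
}

#' Smooth an event curve with a sliding window
#'
#' Reflect-padded convolution with a normalised window, so the output has
#' the same length as the input and constant signals pass unchanged.
#'
#' @param curve an [event_curve()] (or bare numeric vector with `rate`).
#' @param window_s window size in seconds (default 0.2).
#' @param shape `"hann"` (default) or `"flat"`.
#' @param rate sample rate, only needed when `curve` is a bare vector.
#' @return smoothed `event_curve`.
#' @export
smooth_curve <- function(curve, window_s = 0.2, shape = c("hann", "flat"),
                         rate = NULL) {
  if (!inherits(curve, "event_curve")) {
    curve <- event_curve(curve, rate = rate %||% stop("rate required"))
  }
  n <- round(window_s * curve$rate)
  if (n %% 2L == 0L) n <- n + 1L  # odd length: exactly centred, no phase shift
  if (n <= 1L) return(curve)
  x <- curve$values
  if (length(x) < n) {
    stop("curve (", length(x), " samples) is shorter than the smoothing window (",
         n, " samples)", call. = FALSE)
  }
  w <- window_weights(n, match.arg(shape))
  half <- (n - 1L) %/% 2L
  padded <- c(rev(x[seq_len(half) + 1L]), x,
              rev(x[length(x) - seq_len(half)]))
  sm <- as.numeric(stats::filter(padded, w, method = "convolution", sides = 2L))
  curve$values <- sm[half + seq_along(x)]
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(frame = integer(), type = character()))
  d <- diff(x)
  # collapse plateaus: direction of last non-zero difference
  dir <- sign(d)
  for (i in seq_along(dir)) if (dir[i] == 0 && i > 1L) dir[i] <- dir[i - 1L]
  idx <- which(diff(dir) != 0) + 1L
  idx <- idx[dir[pmax(idx - 1L, 1L)] != 0]
  type <- ifelse(dir[idx - 1L] > 0, "max", "min")
  # ties broken to earliest frame: step back over the plateau
  for (k in seq_along(idx)) {
    i <- idx[k]
    while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
    idx[k] <- i
  }
  data.frame(frame = idx, type = type, stringsAsFactors = FALSE)
}

extrema_prominence <- function(x, ext) {
  n <- nrow(ext)
  vapply(seq_len(n), function(i) {
    v <- x[ext$frame[i]]
    # flanking references: the neighbouring extrema, or the curve endpoint
    # for a boundary extremum (a wiggle right at the edge has almost no
    # excursion towards the edge and must lose merges)
    left <- if (i > 1L) x[ext$frame[i - 1L]] else x[1L]
    right <- if (i < n) x[ext$frame[i + 1L]] else x[length(x)]
    min(abs(v - left), abs(v - right))
  }, numeric(1))
}

enforce_alternation <- function(x, ext) {
  repeat {
    if (nrow(ext) < 2L) return(ext)
    same <- which(ext$type[-1L] == ext$type[-nrow(ext)])
    if (!length(same)) return(ext)
    i <- same[1L]
    v1 <- x[ext$frame[i]]; v2 <- x[ext$frame[i + 1L]]
    drop <- if (ext$type[i] == "max") {
      if (v1 >= v2) i + 1L else i       # keep the larger maximum
    } else {
      if (v1 <= v2) i + 1L else i       # keep the smaller minimum
    }
    ext <- ext[-drop, , drop = FALSE]
  }
}

#' Find alternating maxima and minima of a curve
#'
#' Scans for local extrema, enforces strict max/min alternation (keeping
#' the more extreme of same-type neighbours) and merges extrema closer than
#' `min_separation_s`, keeping the member of the pair with the larger
#' prominence.  Ties go to the earliest frame.  A curve with no extrema
#' returns an empty table.
#'
#' @param curve an [event_curve()] (ideally smoothed).
#' @param min_separation_s minimum separation between retained extrema in
#'   seconds (default 0.4).
#' @return data frame with columns `frame` and `type` ("max"/"min").
#' @export
find_extrema <- function(curve, min_separation_s = 0.4) {
  stopifnot(inherits(curve, "event_curve"))
  x <- curve$values
  min_sep <- min_separation_s * curve$rate
  ext <- enforce_alternation(x, local_extrema(x))
  repeat {
    if (nrow(ext) < 2L) break
    gaps <- diff(ext$frame)
    close_pairs <- which(gaps < min_sep)
    if (!length(close_pairs)) break
    i <- close_pairs[1L]
    prom <- extrema_prominence(x, ext)
    drop <- if (prom[i] <= prom[i + 1L]) i else i + 1L
    ext <- enforce_alternation(x, ext[-drop, , drop = FALSE])
  }
  rownames(ext) <- NULL
  ext
}

# Refine extremum frames in two steps: anchor on a lightly smoothed copy
# of the raw curve (stable under noise), then snap to the raw extremum
# within +-2 frames of the anchor.  The snap removes the systematic
# timing bias a symmetric smoothing window leaves on asymmetric gait
# peaks, while the anchor keeps noise-induced jitter bounded.
refine_extrema <- function(raw, ext, rate, search_s, window_s, snap = 2L) {
  fine <- if (window_s > 0) smooth_curve(raw, window_s)$values else raw$values
  half <- max(1L, round(search_s * rate))
  n <- length(fine)
  pick <- function(values, f, reach, type) {
    lo <- max(1L, f - reach); hi <- min(n, f + reach)
    win <- values[lo:hi]
    j <- if (type == "max") which.max(win) else which.min(win)
    as.integer(lo + j - 1L)
  }
  ext$frame <- vapply(seq_len(nrow(ext)), function(i) {
    anchor <- pick(fine, ext$frame[i], half, ext$type[i])
    pick(raw$values, anchor, snap, ext$type[i])
  }, integer(1))
  ext
}

#' Select straight-walking sections of a capture
#'
#' Over-ground IMU captures include turns, starts and stops that must be
#' excluded before event detection.  Manual frame ranges are validated,
#' clipped and ordered.  In automatic mode, frames where the pelvis yaw
#' varies by less than `yaw_tol_deg` over a sliding `window_s` window are
#' kept, and maximal runs at least `min_section_s` long become sections.
#' An empty manual list on a treadmill capture yields one full-session
#' section.
#'
#' @param series a [track()] result.
#' @param manual list of `c(start, end)` frame ranges, or `NULL` for
#'   automatic selection.
#' @param yaw_tol_deg maximum pelvis-yaw excursion within the window
#'   (default 20).
#' @param window_s sliding window in seconds (default 2).
#' @param min_section_s minimum section duration in seconds (default 2).
#' @return data frame of class `straight_sections` with columns `start`,
#'   `end` (frames).
#' @export
select_straight_sections <- function(series, manual = NULL, yaw_tol_deg = 20,
                                     window_s = 2, min_section_s = 2) {
  nf <- length(series$time)
  if (!is.null(manual)) {
    if (!length(manual)) {
      out <- data.frame(start = 1L, end = nf)
      class(out) <- c("straight_sections", "data.frame")
      return(out)
    }
    m <- do.call(rbind, lapply(manual, function(r) {
      stopifnot(length(r) == 2L)
      c(max(1L, r[1L]), min(nf, r[2L]))
    }))
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[, 1L] > m[, 2L])) stop("empty section range", call. = FALSE)
    if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
      stop("manual sections overlap", call. = FALSE)
    }
    out <- data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
    class(out) <- c("straight_sections", "data.frame")
    return(out)
  }
  yaw <- series$angles[, "pelvis", "y"]
  # unwrap so oscillation around +-180 degrees is not read as a turn
  yaw <- cumsum(c(yaw[1L], wrap_angle(diff(yaw))))
  w <- max(2L, round(window_s * series$rate))
  ok <- rep(FALSE, nf)
  for (i in seq_len(nf)) {
    lo <- max(1L, i - w %/% 2); hi <- min(nf, i + w %/% 2)
    win <- yaw[lo:hi]
    ok[i] <- (max(win) - min(win)) < yaw_tol_deg
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_section_s * series$rate
  out <- data.frame(start = starts[keep], end = ends[keep])
  class(out) <- c("straight_sections", "data.frame")
  out
}

# Shared per-side rule engine.  ipsi / contra are smoothed+refined extrema
# tables; contra_fine the refined contralateral curve for the T3 crossing.
assemble_strides <- function(side, section_id, offset,
                             ipsi_ext, contra_ext, contra_fine) {
  t1s <- ipsi_ext$frame[ipsi_ext$type == "max"]
  rows <- list()
  if (length(t1s) < 2L) return(rows)
  for (k in seq_len(length(t1s) - 1L)) {
    T1 <- t1s[k]; T6 <- t1s[k + 1L]
    in_win <- function(f) f[f > T1 & f < T6]
    T2 <- in_win(contra_ext$frame[contra_ext$type == "min"])
    T2 <- if (length(T2)) T2[1L] else NA_integer_
    T4 <- in_win(contra_ext$frame[contra_ext$type == "max"])
    T4 <- T4[T4 > T2][1L] %||% NA_integer_
    T5 <- in_win(ipsi_ext$frame[ipsi_ext$type == "min"])
    T5 <- T5[T5 > T4][1L] %||% NA_integer_
    T3 <- NA_integer_
    if (!is.na(T2) && !is.na(T4) && T4 > T2) {
      mid <- (contra_fine[T2] + contra_fine[T4]) / 2
      seg <- contra_fine[T2:T4]
      cross <- if (seg[length(seg)] >= seg[1L]) which(seg >= mid) else which(seg <= mid)
      T3 <- T2 + (if (length(cross)) cross[1L] else 1L) - 1L
    }
    ev <- c(T1, T2, T3, T4, T5, T6)
    valid <- !anyNA(ev) && T1 < T2 && T2 <= T3 && T3 < T4 && T4 < T5 && T5 < T6
    rows[[length(rows) + 1L]] <- data.frame(
      side = side, section = section_id,
      T1 = T1 + offset, T2 = T2 + offset, T3 = T3 + offset,
      T4 = T4 + offset, T5 = T5 + offset, T6 = T6 + offset,
      valid = valid, stringsAsFactors = FALSE)
  }
  rows
}

detect_events_core <- function(curveR, curveL, sections, flat_range,
                               smooth_window_s, refine_window_s,
                               min_separation_s, shape, snap_frames = 2L) {
  stopifnot(inherits(curveR, "event_curve"), inherits(curveL, "event_curve"))
  if (length(curveR$values) != length(curveL$values) ||
      curveR$rate != curveL$rate) {
    stop("left and right curves must share length and rate", call. = FALSE)
  }
  rate <- curveR$rate
  if (is.null(sections)) {
    sections <- data.frame(start = 1L, end = length(curveR$values))
  }
  if (max(curveR$values) - min(curveR$values) < flat_range ||
      max(curveL$values) - min(curveL$values) < flat_range) {
    stop("no events: curve excursion below ", flat_range,
         " (the gait pattern must show a minimum of flexion and extension)",
         call. = FALSE)
  }
  rows <- list()
  for (s in seq_len(nrow(sections))) {
    rng <- sections$start[s]:sections$end[s]
    segR <- event_curve(curveR$values[rng], rate)
    segL <- event_curve(curveL$values[rng], rate)
    smR <- smooth_curve(segR, smooth_window_s, shape)
    smL <- smooth_curve(segL, smooth_window_s, shape)
    extR <- find_extrema(smR, min_separation_s)
    extL <- find_extrema(smL, min_separation_s)
    extR <- refine_extrema(segR, extR, rate, smooth_window_s / 2,
                           refine_window_s, snap_frames)
    extL <- refine_extrema(segL, extL, rate, smooth_window_s / 2,
                           refine_window_s, snap_frames)
    fineR <- smooth_curve(segR, refine_window_s)$values
    fineL <- smooth_curve(segL, refine_window_s)$values
    off <- rng[1L] - 1L
    rows <- c(rows,
              assemble_strides("R", s, off, extR, extL, fineL),
              assemble_strides("L", s, off, extL, extR, fineR))
  }
  if (!length(rows)) {
    tab <- data.frame(side = character(), section = integer(),
                      T1 = integer(), T2 = integer(), T3 = integer(),
                      T4 = integer(), T5 = integer(), T6 = integer(),
                      valid = logical())
  } else {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$T1, tab$side), ]
    rownames(tab) <- NULL
  }
  tab <- cbind(stride = seq_len(nrow(tab)), tab)
  attr(tab, "rate") <- rate
  class(tab) <- c("gait_event_table", "data.frame")
  tab
}

#' Detect gait events from hip flexion-extension curves (IMU configuration)
#'
#' @param hipR,hipL [event_curve()]s of right and left hip
#'   flexion-extension (flexion positive), same length and rate.
#' @param sections optional [select_straight_sections()] table restricting
#'   the search (over-ground captures); `NULL` uses the full capture.
#' @param smooth_window_s detection smoothing window (s), default 0.2.
#' @param refine_window_s refinement smoothing window (s), default 0.1.
#' @param min_separation_s minimum extremum separation (s), default 0.25
#'   (comfortably below the toe-off-to-contact gap of a slow stride).
#' @param shape smoothing window shape, `"hann"` or `"flat"`.
#' @param snap_frames reach (frames) of the final snap to the raw-curve
#'   extremum around the smoothed anchor.
#' @param flat_range_deg minimum hip excursion (degrees) below which no
#'   events can be detected, default 2.
#' @return a `gait_event_table`: one row per stride and side with frame
#'   indices `T1..T6`, the section id and a validity flag (event ordering
#'   `T1 < T2 <= T3 < T4 < T5 < T6` enforced, never silently reordered).
#' @export
detect_events_imu <- function(hipR, hipL, sections = NULL,
                              smooth_window_s = 0.2, refine_window_s = 0.1,
                              min_separation_s = 0.25,
                              shape = c("hann", "flat"), snap_frames = 2L,
                              flat_range_deg = 2) {
  detect_events_core(hipR, hipL, sections, flat_range_deg,
                     smooth_window_s, refine_window_s, min_separation_s,
                     match.arg(shape), snap_frames)
}

#' Detect gait events from ankle displacement curves (optical configuration)
#'
#' @param ankleR,ankleL [event_curve()]s of the right and left ankle-centre
#'   anteroposterior displacement (cm), same length and rate.
#' @inheritParams detect_events_imu
#' @param flat_range_cm minimum ankle excursion (cm) below which no events
#'   can be detected, default 2.
#' @return a `gait_event_table` (see [detect_events_imu()]).
#' @export
detect_events_opt <- function(ankleR, ankleL, sections = NULL,
                              smooth_window_s = 0.2, refine_window_s = 0.1,
                              min_separation_s = 0.25,
                              shape = c("hann", "flat"), snap_frames = 2L,
                              flat_range_cm = 2) {
  detect_events_core(ankleR, ankleL, sections, flat_range_cm,
                     smooth_window_s, refine_window_s, min_separation_s,
                     match.arg(shape), snap_frames)
}

#' Resample a stride to 101 points (0-100% of the gait cycle)
#'
#' Linear-interpolation resampling of a series between T1 and T6; the
#' endpoint values are preserved exactly.
#'
#' @param values numeric frame series.
#' @param t1,t6 stride start and end frames.
#' @return numeric length-101 vector.
#' @export
normalize_stride <- function(values, t1, t6) {
  if (t6 - t1 < 2L) stop("stride shorter than 3 frames", call. = FALSE)
  if (t1 < 1L || t6 > length(values)) stop("stride outside the series", call. = FALSE)
  stats::approx(x = t1:t6, y = values[t1:t6],
                xout = seq(t1, t6, length.out = 101L))$y
}
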