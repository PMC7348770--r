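#' @title Optical marker-cluster (rigid-body) geometry checks
#'
#' @description
#' Each optical rigid body (RB) is a cluster of three reflective markers
#' with fixed mutual distances.  Two geometric properties matter: the
#' maximum orientation error induced by the camera system's marker
#' positioning error, `Eo = 2 * asin(Ep / Dmin) * 180 / pi` degrees, where
#' `Dmin` is the smallest marker-to-marker distance; and distinguishability
#' -- every cluster must have a unique distance triple so the tracking
#' software can tell the RBs apart.
#'
#' @name rb_geometry
NULL

#' Construct a rigid-body cluster geometry
#'
#' @param name body part the cluster is mounted on.
#' @param side `"R"`, `"L"` or `NA`.
#' @param d12,d13,d23 marker-to-marker distances in mm.
#' @param ep marker positioning error of the camera setup in mm.
#' @return object of class `rigid_body_geometry`.
#' @export
rigid_body_geometry <- function(name, side = NA, d12, d13, d23, ep = 0.34) {
  d <- c(d12, d13, d23)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("marker distances must be positive", call. = FALSE)
  }
  ds <- sort(d)
  if (ds[3L] >= ds[1L] + ds[2L]) {
    stop("marker distances violate the triangle inequality", call. = FALSE)
  }
  structure(list(name = name, side = side, d12 = d12, d13 = d13, d23 = d23,
                 ep = ep), class = "rigid_body_geometry")
}

#' Maximum orientation error of a rigid body
#'
#' `Eo = 2 * asin(Ep / Dmin) * 180 / pi` degrees, with `Dmin` the minimum
#' of the three marker-to-marker distances.  The arcsine is kept exact (no
#' small-angle linearisation).
#'
#' @param geometry a [rigid_body_geometry()], or a numeric vector of the
#'   three distances (mm).
#' @param ep positioning error in mm; defaults to the geometry's own.
#' @return orientation error in degrees.
#' @export
orientation_error <- function(geometry, ep = NULL) {
  if (inherits(geometry, "rigid_body_geometry")) {
    d <- c(geometry$d12, geometry$d13, geometry$d23)
    ep <- ep %||% geometry$ep
  } else {
    d <- geometry
    stopifnot(length(d) == 3L, !is.null(ep))
  }
  dmin <- min(d)
  if (ep < 0) stop("Ep must be non-negative", call. = FALSE)
  if (ep >= dmin) {
    stop("invalid geometry: Ep (", ep, " mm) must be smaller than Dmin (",
         dmin, " mm)", call. = FALSE)
  }
  2 * asin(ep / dmin) * 180 / pi
}

#' Check that rigid-body clusters are mutually distinguishable
#'
#' Two clusters conflict when their sorted marker-distance triples agree
#' pairwise within `tol_mm`.
#'
#' @param geometries data frame with columns `name`, `side`, `d12`, `d13`,
#'   `d23` (e.g. [default_rigid_bodies()]), or a list of
#'   [rigid_body_geometry()] objects.
#' @param tol_mm distance tolerance in mm (default 5).
#' @return data frame of conflicting pairs (zero rows when all clusters
#'   are distinguishable).
#' @export
check_uniqueness <- function(geometries, tol_mm = 5) {
  if (is.data.frame(geometries)) {
    labs <- paste0(geometries$name,
                   ifelse(is.na(geometries$side) | geometries$side == "", "",
                          paste0("_", geometries$side)))
    trip <- t(apply(geometries[, c("d12", "d13", "d23")], 1L, sort))
  } else {
    labs <- vapply(geometries, function(g) {
      paste0(g$name, if (is.na(g$side)) "" else paste0("_", g$side))
    }, "")
    trip <- t(vapply(geometries, function(g) sort(c(g$d12, g$d13, g$d23)),
                     numeric(3)))
  }
  n <- nrow(trip)
  if (n < 2L) stop("need at least 2 clusters to compare", call. = FALSE)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (all(abs(trip[i, ] - trip[j, ]) <= tol_mm)) {
        pairs[[length(pairs) + 1L]] <- data.frame(a = labs[i], b = labs[j])
      }
    }
  }
  if (length(pairs)) do.call(rbind, pairs)
  else data.frame(a = character(), b = character())
}

#' Bundled rigid-body cluster set
#'
#' The 15 marker-cluster geometries of the full-body optical configuration
#' this package models (distances in mm), with the camera setup's marker
#' positioning error `Ep = 0.34` mm.
#'
#' @return data frame with columns `name`, `side`, `d12`, `d13`, `d23`.
#' @export
default_rigid_bodies <- function() {
  path <- system.file("extdata", "rigid_bodies.csv",
                      package = "gaitmocap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
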