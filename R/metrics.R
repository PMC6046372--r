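# Quantitative descriptors of thresholded maps: area of the projection to the
# POI, volume under the surface, centers of gravity, hotspots, overlap maps
# and the active area used for EMD normalization.

active_cells <- function(map) {
  stopifnot(inherits(map, "motor_map"))
  map$geometry$grid$cells[map$active, , drop = FALSE]
}

#' Map area
#'
#' Area of the projection of the thresholded map onto the POI: the sum of the
#' spherical cell areas over suprathreshold cells.
#'
#' @param map a `motor_map` (thresholded; a raw map counts all its cells).
#' @return area in mm^2.
#' @export
map_area <- function(map) {
  sum(active_cells(map)$area)
}

#' Map volume
#'
#' Volume under the thresholded surface, measured from the zero level (the
#' sphere surface): `sum(h_i * s_i)` over suprathreshold cells.
#'
#' @param map a `motor_map`.
#' @return volume in response units times mm^2 (uV*mm^2 for MEP amplitudes).
#' @export
map_volume <- function(map) {
  sum(map$heights[map$active] * active_cells(map)$area)
}

project_to_sphere_surface <- function(p, sph) {
  rel <- p - sph$center
  sph$center + sph$radius * rel / sqrt(sum(rel^2))
}

#' Center of gravity of the raw merged data
#'
#' Response-weighted mean of the merged point coordinates (componentwise),
#' projected radially back to the sphere surface. The unprojected Cartesian
#' mean is kept in `attr(, "unprojected")`.
#'
#' @param map a `motor_map`, or a `merged_points` data frame (then `sph` and
#'   `frame` are required).
#' @param sph,frame sphere and patch frame when `map` is a `merged_points`.
#' @return 3-vector on the sphere (mm).
#' @export
cog_raw <- function(map, sph = NULL, frame = NULL) {
  if (inherits(map, "motor_map")) {
    merged <- map$merged
    sph <- map$geometry$sphere
    frame <- map$geometry$frame
  } else {
    merged <- map
    if (is.null(sph) || is.null(frame)) stop("sph and frame are required")
  }
  if (nrow(merged) == 0L || sum(merged$h) <= 0)
    stop("undefined CoG: no merged points with positive response")
  w <- angular_to_world(cbind(merged$alpha, merged$beta), sph, frame)
  mean_pt <- colSums(w * merged$h) / sum(merged$h)
  out <- project_to_sphere_surface(mean_pt, sph)
  attr(out, "unprojected") <- mean_pt
  out
}

#' Center of gravity of a thresholded map
#'
#' Cell-area-and-height weighted mean of the suprathreshold cell centers,
#' projected radially to the sphere. The unprojected mean is kept in
#' `attr(, "unprojected")`.
#'
#' @param map a `motor_map` with at least one active cell.
#' @return 3-vector on the sphere (mm).
#' @export
cog_map <- function(map) {
  cells <- active_cells(map)
  if (nrow(cells) == 0L) stop("undefined CoG: empty thresholded map")
  wgt <- map$heights[map$active] * cells$area
  if (sum(wgt) <= 0) stop("undefined CoG: zero total weight")
  mean_pt <- c(sum(cells$wx * wgt), sum(cells$wy * wgt), sum(cells$wz * wgt)) / sum(wgt)
  out <- project_to_sphere_surface(mean_pt, map$geometry$sphere)
  attr(out, "unprojected") <- mean_pt
  out
}

#' Hotspots of a map
#'
#' The raw hotspot is the merged point with the maximal response; the map
#' hotspot is the grid cell with the maximal surface height. Ties are broken
#' by the smaller geodesic distance to the corresponding CoG, then by the
#' first identifier / lowest cell index.
#'
#' @param map a `motor_map` with merged points and at least one active cell.
#' @return list with `raw` (row of merged points plus `world`) and `map`
#'   (row of the cell table plus `world` and `height`).
#' @export
find_hotspot <- function(map) {
  merged <- map$merged
  cells <- active_cells(map)
  if (nrow(merged) == 0L || nrow(cells) == 0L) stop("no hotspot: empty input")
  sph <- map$geometry$sphere
  frame <- map$geometry$frame

  pick <- function(values, ab, cog) {
    best <- which(values >= max(values) - 1e-12 * max(values, 1))
    if (length(best) > 1L) {
      cg <- project_point(matrix(cog, 1), sph, frame = frame)
      d <- geodesic_distance(ab[best, , drop = FALSE], cg, sph)
      best <- best[order(d, best)]
    }
    best[1L]
  }

  i_raw <- pick(merged$h, cbind(merged$alpha, merged$beta), cog_raw(map))
  raw <- merged[i_raw, , drop = FALSE]
  raw_world <- angular_to_world(cbind(raw$alpha, raw$beta), sph, frame)[1, ]

  i_map <- pick(map$heights[map$active], cbind(cells$alpha, cells$beta), cog_map(map))
  cell <- cells[i_map, , drop = FALSE]
  list(
    raw = list(point = raw, world = raw_world, h = raw$h),
    map = list(cell = cell, world = c(cell$wx, cell$wy, cell$wz),
               height = map$heights[map$active][i_map])
  )
}

#' Overlap map of two thresholded maps
#'
#' The overlap occupies the intersection of the two suprathreshold cell sets;
#' its height is the cellwise minimum of the two surfaces, so the overlap of a
#' map with itself is the map and all overlap statistics are bounded by either
#' map's. The result supports area, volume, CoG and EMD like any map.
#'
#' @param a,b `motor_map`s of kind `th_map` built on the same shared geometry.
#' @return a `motor_map` of kind `overlap`.
#' @export
overlap_maps <- function(a, b) {
  stopifnot(inherits(a, "motor_map"), inherits(b, "motor_map"))
  if (!same_geometry(a$geometry, b$geometry))
    stop("incompatible maps: overlap requires maps on one shared sphere, POI and grid")
  if (a$kind == "r_map" || b$kind == "r_map")
    stop("overlap is defined on thresholded maps; apply threshold_map() first")
  out <- a
  out$kind <- "overlap"
  out$channel <- paste(a$channel, b$channel, sep = " & ")
  out$heights <- pmin(a$heights, b$heights)
  out$field <- pmin(a$field, b$field)
  out$active <- a$active & b$active
  out$threshold <- max(a$threshold, b$threshold)
  out$merged <- rbind(a$merged, b$merged)
  out
}

#' Active area of a subject
#'
#' Collects every stimulated point where at least one channel in at least one
#' session had a response above the threshold, and its diameter: the maximal
#' pairwise geodesic distance `d_max`, the subject-level constant normalizing
#' relative EMD.
#'
#' @param sessions a `tms_session` or list of them (all sessions of one
#'   subject).
#' @param geometry shared [map_geometry()] (or a [sphere()]); required so that
#'   projections match the maps being compared.
#' @param threshold response threshold (strictly exceeded to qualify).
#' @return object of class `active_area` with `ab`, `dirs`, `d_max`, `n`.
#' @export
active_area <- function(sessions, geometry, threshold = 50) {
  if (inherits(sessions, "tms_session")) sessions <- list(sessions)
  sph <- if (inherits(geometry, "tms_sphere")) geometry else geometry$sphere
  frame <- if (inherits(geometry, "map_geometry")) geometry$frame else NULL
  loc <- NULL
  for (s in sessions) {
    s <- as_session(s)
    resp <- as.matrix(s$points[, s$channels, drop = FALSE])
    qual <- s$points$valid &
      apply(resp, 1, function(r) any(!is.na(r) & r > threshold))
    if (any(qual)) loc <- rbind(loc, session_locations(s)[qual, , drop = FALSE])
  }
  if (is.null(loc) || nrow(loc) < 2L)
    stop("degenerate active area: fewer than 2 points exceed the threshold")
  ab <- project_point(loc, sph, frame = frame)
  dirs <- angular_to_direction(ab)
  d <- geodesic_cross(dirs, dirs, sph$radius)
  structure(list(ab = ab, dirs = dirs, d_max = max(d), n = nrow(ab),
                 threshold = threshold),
            class = "active_area")
}

#' @export
print.active_area <- function(x, ...) {
  cat(sprintf("Active area: %d points above %.1f, diameter d_max = %.2f mm\n",
              x$n, x$threshold, x$d_max))
  invisible(x)
}
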