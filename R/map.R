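# The fitting surface of the package: motor_map() turns one session's
# stimulation records into a response surface over a spherical patch, and the
# classed result supports the usual model verbs.

#' Map construction settings
#'
#' Bundles the construction parameters with the published defaults: smooth
#' approach, 50 uV threshold, kernel a = 0.05 and b = 2 mm, influence radius
#' 5 mm.
#'
#' @param approach `"smooth"` (exact smooth interpolation, default) or
#'   `"kernel"` (maximum of exponential kernels).
#' @param threshold minimum signal level in response units (uV for MEPs).
#' @param kernel_a fraction of a single kernel's volume beyond `kernel_b`.
#' @param kernel_b kernel radius in mm (navigation accuracy).
#' @param influence_radius geodesic distance (mm) at which the smooth surface
#'   reaches zero.
#' @param merge_radius geodesic radius (mm) for spatial merging of repeated
#'   stimuli.
#' @param merge_stat merged response statistic, `"mean"` or `"max"`.
#' @param min_repetitions minimum repetitions a merged point needs to be used.
#' @return a `map_config` list.
#' @export
map_config <- function(approach = c("smooth", "kernel"), threshold = 50,
                       kernel_a = 0.05, kernel_b = 2, influence_radius = 5,
                       merge_radius = 2, merge_stat = c("mean", "max"),
                       min_repetitions = 1) {
  approach <- match.arg(approach)
  merge_stat <- match.arg(merge_stat)
  if (threshold < 0) stop("threshold must be nonnegative")
  if (influence_radius <= 0) stop("influence_radius must be positive")
  if (kernel_a <= 0 || kernel_a >= 1) stop("kernel_a must lie in (0, 1)")
  if (kernel_b <= 0) stop("kernel_b must be positive")
  structure(list(approach = approach, threshold = threshold,
                 kernel_a = kernel_a, kernel_b = kernel_b,
                 influence_radius = influence_radius,
                 merge_radius = merge_radius, merge_stat = merge_stat,
                 min_repetitions = min_repetitions),
            class = "map_config")
}

#' Shared analysis geometry for one or more sessions
#'
#' Fits (or accepts) the sphere, builds the patch of interest around all
#' supplied stimulation locations and lays the analysis grid. Maps that are to
#' be compared (overlap, EMD) must be constructed on one shared geometry so
#' that their grids coincide; build it from the union of the sessions'
#' stimulation points.
#'
#' @param points n x 3 matrix of stimulation locations (mm), or a list of such
#'   matrices / `tms_session` objects whose locations are pooled.
#' @param sph optional [sphere()]; fitted to the pooled points when `NULL`.
#' @param config a [map_config()] (sets the POI margin from the influence
#'   radius).
#' @param spacing grid spacing override (internal; `NULL` = fixed 1 mm).
#' @return an object of class `map_geometry` with `sphere`, `frame`, `poi`,
#'   `grid`.
#' @export
map_geometry <- function(points, sph = NULL, config = map_config(),
                         spacing = NULL) {
  if (inherits(points, "tms_session")) {
    points <- session_locations(points)
  } else if (is.list(points) && !is.matrix(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, function(p) {
      if (inherits(p, "tms_session")) session_locations(p) else as_points3(p)
    }))
  }
  pts <- as_points3(points)
  if (is.null(sph)) sph <- fit_sphere(pts)
  ab <- project_point(pts, sph)
  frame <- attr(ab, "frame")
  sp <- if (is.null(spacing)) GRID_SPACING else spacing
  margin <- config$influence_radius + 2 * sp
  poi <- build_poi(ab, sph, frame, margin = margin)
  grid <- build_grid(poi, spacing = spacing)
  structure(list(sphere = sph, frame = frame, poi = poi, grid = grid),
            class = "map_geometry")
}

#' @export
print.map_geometry <- function(x, ...) {
  cat(sprintf("Map geometry: sphere R %.1f mm, %d grid cells, POI margin %.1f mm\n",
              x$sphere$radius, nrow(x$grid$cells), x$poi$margin))
  invisible(x)
}

#' Construct a motor map from a stimulation session
#'
#' The central fitting function: projects one channel's stimulation points
#' onto the fitted sphere, merges repeated stimuli, and interpolates the
#' responses into a raw response surface (`r_map`) over the patch of interest,
#' using either the smooth (exact interpolation, zero beyond the influence
#' radius) or the kernel construction.
#'
#' @param session a `tms_session` (see [read_session()]), or a data frame with
#'   the same `points` layout.
#' @param channel name of the response channel to map.
#' @param config a [map_config()].
#' @param geometry optional shared [map_geometry()] or [sphere()]. Maps meant
#'   for comparison must share one `map_geometry` built from all sessions'
#'   points; with a bare sphere the patch is rebuilt from this session, and
#'   with `NULL` both sphere and patch come from this session alone.
#' @return an object of class `motor_map` (kind `r_map`).
#' @seealso [threshold_map()], [summary.motor_map()], [overlap_maps()],
#'   [emd_relative()]
#' @export
motor_map <- function(session, channel, config = map_config(), geometry = NULL) {
  session <- as_session(session)
  if (!channel %in% session$channels)
    stop(sprintf("channel '%s' not present in session", channel))
  loc <- session_locations(session)
  resp <- session$points[[channel]]
  valid <- session$points$valid & !is.na(resp)
  if (!any(valid)) stop(sprintf("empty channel: no valid responses on '%s'", channel))
  loc <- loc[valid, , drop = FALSE]
  resp <- resp[valid]
  ids <- as.character(session$points$id[valid])

  if (is.null(geometry)) {
    geometry <- map_geometry(loc, config = config)
  } else if (inherits(geometry, "tms_sphere")) {
    geometry <- map_geometry(loc, sph = geometry, config = config)
  } else if (!inherits(geometry, "map_geometry")) {
    stop("geometry must be NULL, a sphere, or a map_geometry")
  }

  ab <- project_point(loc, geometry$sphere, frame = geometry$frame)
  merged <- merge_points(ab, resp, geometry$sphere,
                         merge_radius = config$merge_radius,
                         merge_stat = config$merge_stat,
                         min_repetitions = config$min_repetitions,
                         ids = ids)
  if (nrow(merged) == 0L)
    stop("no merged points left after repetition filtering")

  field <- if (config$approach == "kernel") {
    kernel_field(merged, geometry$grid, a = config$kernel_a, b = config$kernel_b)
  } else {
    smooth_field(merged, geometry$grid, influence_radius = config$influence_radius)
  }
  heights <- field[geometry$grid$cells$idx]

  structure(list(
    heights = heights, field = field, geometry = geometry, merged = merged,
    channel = channel, subject = session$subject, session = session$session,
    config = config, kind = "r_map", threshold = NULL,
    active = rep(TRUE, length(heights)), call = match.call()
  ), class = "motor_map")
}

#' Apply the minimum signal level to a map
#'
#' Removes grid cells whose surface height falls below the threshold; the
#' remaining heights are unchanged. The result (`th_map`) is what areas,
#' volumes, map CoGs, overlaps and EMD are computed on.
#'
#' @param map a `motor_map`.
#' @param threshold response threshold; defaults to the construction config.
#' @return a `motor_map` of kind `th_map` (possibly with no active cells).
#' @export
threshold_map <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "motor_map"))
  if (is.null(threshold)) threshold <- map$config$threshold
  map$active <- map$active & (map$heights >= threshold)
  map$threshold <- threshold
  map$kind <- "th_map"
  map
}

n_active <- function(map) sum(map$active)

#' @export
print.motor_map <- function(x, ...) {
  cat(sprintf("Motor map (%s) for channel '%s'\n", x$kind, x$channel))
  cat(sprintf("  sphere R %.1f mm; %d grid cells, %d active; %d merged points\n",
              x$geometry$sphere$radius, length(x$heights), n_active(x),
              nrow(x$merged)))
  if (n_active(x) > 0L)
    cat(sprintf("  height range %.1f .. %.1f over active cells\n",
                min(x$heights[x$active]), max(x$heights[x$active])))
  if (!is.null(x$threshold)) cat(sprintf("  threshold %.1f\n", x$threshold))
  invisible(x)
}

#' Map statistics: area, volume, CoGs, hotspots
#'
#' Computes the standard descriptors of a (thresholded) map: area of the
#' projection to the POI, volume under the surface, centers of gravity of the
#' raw merged data and of the thresholded surface, and both hotspots.
#'
#' @param object a `motor_map`.
#' @param threshold threshold applied if `object` is still a raw map.
#' @param ... unused.
#' @return `motor_map_summary` with fields `area`, `volume`, `cog_raw`,
#'   `cog_map`, `hotspot_raw`, `hotspot_map`, `n_active`, `threshold`.
#' @export
summary.motor_map <- function(object, threshold = NULL, ...) {
  m <- if (object$kind == "r_map") threshold_map(object, threshold) else object
  hs <- if (n_active(m) > 0L && nrow(m$merged) > 0L) find_hotspot(m) else NULL
  structure(list(
    channel = m$channel, subject = m$subject, session = m$session,
    kind = m$kind, threshold = m$threshold,
    area = map_area(m), volume = map_volume(m),
    cog_raw = if (nrow(m$merged) > 0L && sum(m$merged$h) > 0) cog_raw(m) else NULL,
    cog_map = if (n_active(m) > 0L) cog_map(m) else NULL,
    hotspot_raw = hs$raw, hotspot_map = hs$map,
    n_active = n_active(m)
  ), class = "motor_map_summary")
}

#' @export
print.motor_map_summary <- function(x, ...) {
  cat(sprintf("Motor map statistics, channel '%s' (threshold %.1f)\n",
              x$channel, x$threshold))
  cat(sprintf("  area   %10.1f mm^2\n", x$area))
  cat(sprintf("  volume %10.1f response*mm^2\n", x$volume))
  fmt3 <- function(v) sprintf("(%.2f, %.2f, %.2f)", v[1], v[2], v[3])
  if (!is.null(x$cog_raw)) cat("  CoG raw    ", fmt3(x$cog_raw), "mm\n")
  if (!is.null(x$cog_map)) cat("  CoG map    ", fmt3(x$cog_map), "mm\n")
  if (!is.null(x$hotspot_map)) cat("  hotspot map", fmt3(x$hotspot_map$world), "mm\n")
  invisible(x)
}

#' Evaluate a map surface at new locations
#'
#' Bilinear interpolation of the surface in the unwrapped plane. `newdata` may
#' be 3D world points (projected to the sphere first) or planar coordinates.
#'
#' @param object a `motor_map`.
#' @param newdata n x 3 world coordinates (mm) or n x 2 planar coordinates.
#' @param ... unused.
#' @return numeric vector of surface heights.
#' @export
predict.motor_map <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  geo <- object$geometry
  xy <- if (ncol(nd) == 3L) {
    unwrap_to_plane(project_point(nd, geo$sphere, frame = geo$frame), geo$sphere)
  } else if (ncol(nd) == 2L) nd else stop("newdata must have 2 or 3 columns")
  as.numeric(bilinear_weights(xy, geo$grid) %*% object$field)
}

#' Interpolation residuals at the merged points
#'
#' @param object a `motor_map`.
#' @param ... unused.
#' @return surface height at each merged point minus its merged response
#'   (near zero for the smooth construction by contract).
#' @export
residuals.motor_map <- function(object, ...) {
  geo <- object$geometry
  xy <- unwrap_to_plane(cbind(object$merged$alpha, object$merged$beta), geo$sphere)
  as.numeric(bilinear_weights(xy, geo$grid) %*% object$field) - object$merged$h
}

#' Plot a motor map in the unwrapped plane
#'
#' Displays the height field with the blue-to-red response scale and overlays
#' the merged stimulation points.
#'
#' @param x a `motor_map`.
#' @param points overlay merged points?
#' @param ... passed to [graphics::image()].
#' @export
plot.motor_map <- function(x, points = TRUE, ...) {
  geo <- x$geometry
  z <- matrix(NA_real_, geo$grid$nx, geo$grid$ny)
  z[geo$grid$cells$idx] <- ifelse(x$active, x$heights, NA_real_)
  graphics::image(geo$grid$xs, geo$grid$ys, z, col = response_palette(256),
                  xlab = "x (mm, unwrapped plane)", ylab = "y (mm)",
                  main = sprintf("%s (%s)", x$channel, x$kind), asp = 1, ...)
  if (points && nrow(x$merged) > 0L) {
    xy <- unwrap_to_plane(cbind(x$merged$alpha, x$merged$beta), geo$sphere)
    graphics::points(xy, pch = 21, bg = "white")
  }
  invisible(x)
}

as_session <- function(x) {
  if (inherits(x, "tms_session")) return(x)
  if (is.data.frame(x)) return(new_session(x))
  stop("expected a tms_session or a points data frame")
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$sphere$center, b$sphere$center, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$sphere$radius, b$sphere$radius, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$frame, b$frame, tolerance = 1e-9)) &&
    a$grid$nx == b$grid$nx && a$grid$ny == b$grid$ny &&
    isTRUE(all.equal(a$grid$xs, b$grid$xs, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$grid$ys, b$grid$ys, tolerance = 1e-9)) &&
    identical(a$grid$cells$idx, b$grid$cells$idx)
}
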