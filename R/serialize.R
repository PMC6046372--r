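# Portable map persistence: a self-describing JSON container holding the
# sphere, patch frame, POI boundary, grid layout, surface heights and the
# construction parameters, at full numeric precision.

#' Write a motor map to a portable JSON container
#'
#' @param map a `motor_map`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "motor_map"))
  geo <- map$geometry
  obj <- list(
    format = "motormap-map", version = 1L,
    channel = map$channel, subject = map$subject, session = map$session,
    kind = map$kind, threshold = map$threshold,
    config = unclass(map$config),
    sphere = list(center = geo$sphere$center, radius = geo$sphere$radius),
    frame = as.numeric(geo$frame),
    poi = list(hull = unname(as.matrix(geo$poi$hull)), margin = geo$poi$margin),
    grid = list(xs = geo$grid$xs, ys = geo$grid$ys, spacing = geo$grid$spacing,
                cell_idx = geo$grid$cells$idx),
    field = map$field, active = which(map$active),
    merged = list(alpha = map$merged$alpha, beta = map$merged$beta,
                  h = map$merged$h, repetitions = map$merged$repetitions)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a motor map written by [write_map()]
#'
#' @param path a `.json` file.
#' @return a `motor_map`.
#' @export
read_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "motormap-map"))
    stop("not a motormap map container")
  sph <- sphere(obj$sphere$center, obj$sphere$radius)
  frame <- matrix(obj$frame, 3, 3, dimnames = list(NULL, c("ex", "ey", "ez")))
  hull <- matrix(obj$poi$hull, ncol = 2,
                 dimnames = list(NULL, c("x", "y")))
  poi <- structure(list(
    sphere = sph, frame = frame, center_direction = frame[, 3],
    hull = hull, margin = obj$poi$margin,
    boundary_xy = offset_polygon(ensure_ccw(hull), obj$poi$margin)
  ), class = "tms_poi")
  poi$boundary <- wrap_to_sphere(poi$boundary_xy, sph)
  grid <- list(xs = obj$grid$xs, ys = obj$grid$ys,
               nx = length(obj$grid$xs), ny = length(obj$grid$ys),
               spacing = obj$grid$spacing, poi = poi)
  grid$inside <- logical(grid$nx * grid$ny)
  grid$inside[obj$grid$cell_idx] <- TRUE
  xy <- lattice_xy(grid)[obj$grid$cell_idx, , drop = FALSE]
  s <- sqrt(rowSums(xy^2))
  ab <- wrap_to_sphere(xy, sph)
  w <- angular_to_world(ab, sph, frame)
  grid$cells <- data.frame(idx = obj$grid$cell_idx, x = xy[, 1], y = xy[, 2],
                           s = s, alpha = ab[, 1], beta = ab[, 2],
                           wx = w[, 1], wy = w[, 2], wz = w[, 3],
                           area = grid$spacing^2 * ae_area_factor(s, sph$radius))
  class(grid) <- "tms_grid"
  geometry <- structure(list(sphere = sph, frame = frame, poi = poi, grid = grid),
                        class = "map_geometry")
  merged <- data.frame(alpha = obj$merged$alpha, beta = obj$merged$beta,
                       h = obj$merged$h, repetitions = obj$merged$repetitions)
  class(merged) <- c("merged_points", "data.frame")
  active <- logical(nrow(grid$cells))
  active[obj$active] <- TRUE
  cfg <- do.call(map_config, obj$config[c("approach", "threshold", "kernel_a",
                                          "kernel_b", "influence_radius",
                                          "merge_radius", "merge_stat",
                                          "min_repetitions")])
  structure(list(
    heights = obj$field[obj$grid$cell_idx], field = obj$field,
    geometry = geometry, merged = merged, channel = obj$channel,
    subject = obj$subject, session = obj$session, config = cfg,
    kind = obj$kind,
    threshold = if (is.null(obj$threshold)) NULL else obj$threshold,
    active = active, call = NULL
  ), class = "motor_map")
}
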