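# Patch of interest: the part of the fitted sphere that carries the analysis.
# The patch is the geodesic convex hull of the projected stimulation points
# dilated outward by a margin, computed in the azimuthal-equidistant plane
# around the patch center.

#' Build the patch of interest (POI)
#'
#' The POI boundary is the convex hull of the projected stimulation points,
#' dilated outward by `margin`. By default the margin is the influence radius
#' plus two grid spacings, the smallest patch on which a map can decay to zero.
#' The hull and its dilation are computed in the unwrapped plane, where radial
#' distances from the patch center are exactly geodesic.
#'
#' @param ab n x 2 matrix of projected angular coordinates.
#' @param sph a [sphere()].
#' @param frame patch frame from [patch_frame()] (+z = patch center direction).
#' @param margin dilation in mm (default 7 = influence radius 5 + 2 x 1 mm grid).
#' @return an object of class `tms_poi` with the planar hull, margin and a
#'   sampled boundary polyline in planar and angular coordinates.
#' @export
build_poi <- function(ab, sph, frame, margin = 7) {
  ab <- as_angular(ab)
  if (nrow(ab) < 1L) stop("POI needs at least one projected point")
  if (margin < 0) stop("margin must be nonnegative")
  xy <- unwrap_to_plane(ab, sph)
  smax <- max(sqrt(rowSums(xy^2)))
  if (smax + margin >= pi * sph$radius / 2)
    stop("patch too large: points plus margin span a hemisphere or more")
  uxy <- unique(round(xy * 1e9) / 1e9)
  idx <- grDevices::chull(uxy[, 1], uxy[, 2])
  hull <- uxy[idx, , drop = FALSE]
  hull <- ensure_ccw(hull)
  boundary <- offset_polygon(hull, margin)
  structure(list(
    sphere = sph,
    frame = frame,
    center_direction = frame[, 3],
    hull = hull,
    margin = margin,
    boundary_xy = boundary,
    boundary = wrap_to_sphere(boundary, sph)
  ), class = "tms_poi")
}

#' @export
print.tms_poi <- function(x, ...) {
  cat(sprintf("Patch of interest: %d hull vertices, margin %.1f mm, sphere R %.1f mm\n",
              nrow(x$hull), x$margin, x$sphere$radius))
  invisible(x)
}

# orient a convex polygon counter-clockwise
ensure_ccw <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(poly)
  x <- poly[, 1]; y <- poly[, 2]
  a2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  if (a2 < 0) poly[n:1, , drop = FALSE] else poly
}

# sampled outward offset of a convex polygon (or point / segment) at distance
# margin; returns a closed-curve polyline (last point != first)
offset_polygon <- function(hull, margin, step = pi / 24) {
  n <- nrow(hull)
  if (margin == 0 && n >= 3L) return(hull)
  if (n == 1L) {
    phi <- seq(0, 2 * pi, by = step)
    phi <- phi[-length(phi)]
    return(cbind(x = hull[1, 1] + margin * cos(phi),
                 y = hull[1, 2] + margin * sin(phi)))
  }
  if (n == 2L) {
    d <- normalize2(hull[2, ] - hull[1, ])
    a0 <- atan2(d[2], d[1])
    arc1 <- a0 + pi / 2 + seq(0, pi, by = step)        # around hull[1]
    arc2 <- a0 - pi / 2 + seq(0, pi, by = step)        # around hull[2]
    return(rbind(
      cbind(hull[1, 1] + margin * cos(arc1), hull[1, 2] + margin * sin(arc1)),
      cbind(hull[2, 1] + margin * cos(arc2), hull[2, 2] + margin * sin(arc2))
    ))
  }
  out <- NULL
  for (i in seq_len(n)) {
    prev <- hull[if (i == 1L) n else i - 1L, ]
    cur <- hull[i, ]
    nxt <- hull[if (i == n) 1L else i + 1L, ]
    n1 <- edge_normal(prev, cur)  # outward normal of incoming edge
    n2 <- edge_normal(cur, nxt)   # outward normal of outgoing edge
    a1 <- atan2(n1[2], n1[1])
    a2 <- atan2(n2[2], n2[1])
    sweep_ang <- (a2 - a1) %% (2 * pi)
    ang <- a1 + seq(0, sweep_ang, length.out = max(2L, ceiling(sweep_ang / step) + 1L))
    out <- rbind(out, cbind(cur[1] + margin * cos(ang), cur[2] + margin * sin(ang)))
  }
  colnames(out) <- c("x", "y")
  out
}

normalize2 <- function(v) v / sqrt(sum(v^2))

# outward (right-hand) normal of edge a -> b of a ccw polygon
edge_normal <- function(a, b) {
  d <- normalize2(b - a)
  c(d[2], -d[1])
}

# Euclidean distance from planar points to the convex hull region (0 inside)
dist_to_hull <- function(pts, hull) {
  pts <- if (is.null(dim(pts))) matrix(as.numeric(pts), ncol = 2L) else as.matrix(pts)
  n <- nrow(hull)
  if (n == 1L) {
    return(sqrt((pts[, 1] - hull[1, 1])^2 + (pts[, 2] - hull[1, 2])^2))
  }
  if (n == 2L) {
    return(dist_to_segment(pts, hull[1, ], hull[2, ]))
  }
  m <- nrow(pts)
  inside <- rep(TRUE, m)
  dmin <- rep(Inf, m)
  for (i in seq_len(n)) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cr >= -1e-12)
    dmin <- pmin(dmin, dist_to_segment(pts, a, b))
  }
  ifelse(inside, 0, dmin)
}

dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Membership test for planar points in a POI
#'
#' @param xy n x 2 planar coordinates in the POI's unwrapped plane.
#' @param poi a `tms_poi`.
#' @return logical vector.
#' @export
point_in_poi <- function(xy, poi) {
  dist_to_hull(xy, poi$hull) <= poi$margin + 1e-9
}

#' Area of a POI by fine quadrature
#'
#' Integrates the spherical area of the patch on a fine planar lattice with
#' the azimuthal-equidistant area correction.
#'
#' @param poi a `tms_poi`.
#' @param resolution quadrature spacing in mm.
#' @return area in mm^2.
#' @export
poi_area <- function(poi, resolution = 0.25) {
  bb <- apply(poi$boundary_xy, 2, range)
  xs <- seq(bb[1, 1] - resolution, bb[2, 1] + resolution, by = resolution)
  ys <- seq(bb[1, 2] - resolution, bb[2, 2] + resolution, by = resolution)
  g <- expand.grid(x = xs, y = ys)
  inside <- point_in_poi(as.matrix(g), poi)
  s <- sqrt(g$x[inside]^2 + g$y[inside]^2)
  sum(resolution^2 * ae_area_factor(s, poi$sphere$radius))
}
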