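# Sphere fitting, angular coordinates, geodesics and the azimuthal-equidistant
# unwrap/wrap transforms that carry all map construction between the sphere and
# the plane.

#' Construct a sphere
#'
#' A sphere is described by its center (mm) and radius (mm). All stimulation
#' points are projected onto one fitted sphere and every map lives on a patch
#' of that sphere.
#'
#' @param center numeric length-3, center in mm.
#' @param radius positive scalar, radius in mm.
#' @return an object of class `tms_sphere`.
#' @export
sphere <- function(center, radius) {
  center <- as.numeric(center)
  radius <- as.numeric(radius)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("sphere center must be a finite 3-vector")
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("sphere radius must be a positive scalar")
  structure(list(center = center, radius = radius), class = "tms_sphere")
}

#' @export
print.tms_sphere <- function(x, ...) {
  cat(sprintf("Sphere: center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

as_points3 <- function(points) {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 3L)
    pts <- matrix(as.numeric(pts), ncol = 3L, byrow = TRUE)
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("point coordinates must be finite")
  pts
}

#' Fit a sphere to 3D points by least squares
#'
#' Fits the closest spherical surface to a point cloud: an algebraic
#' (linearized) fit provides the initializer, which is then refined by
#' geometric least squares minimizing `sum((||p_i - c|| - R)^2)`.
#'
#' @param points n x 3 matrix of coordinates in mm, n >= 4, not coplanar.
#' @return a [sphere()].
#' @examples
#' u <- matrix(rnorm(60), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' fit_sphere(sweep(85 * u, 2, c(10, -5, 40), "+"))
#' @export
fit_sphere <- function(points) {
  pts <- as_points3(points)
  if (nrow(pts) < 4L)
    stop("degenerate geometry: sphere fitting needs at least 4 points")
  # algebraic fit: |p|^2 = 2 p.c + (R^2 - |c|^2), linear in (c, R^2 - |c|^2)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qa <- qr(A)
  if (qa$rank < 4L)
    stop("degenerate geometry: points are coplanar or collinear; cannot fit a sphere")
  sol <- qr.coef(qa, b)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate geometry: algebraic sphere fit failed")
  resid_fun <- function(par) {
    sqrt(rowSums((pts - matrix(par[1:3], nrow(pts), 3L, byrow = TRUE))^2)) - par[4]
  }
  fit <- minpack.lm::nls.lm(
    par = c(ctr, sqrt(r2)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 500)
  )
  par <- fit$par
  if (par[4] <= 0) stop("degenerate geometry: sphere fit collapsed")
  sphere(par[1:3], par[4])
}

normalize3 <- function(v) {
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Orthonormal frame of a spherical patch
#'
#' Builds the patch-centered frame whose +z axis is the patch center direction.
#' Angular coordinates (alpha, beta) of a surface point are defined by its
#' direction being proportional to `(tan(alpha), tan(beta), 1)` in this frame,
#' which makes the unwrap radial coordinate equal the geodesic distance from
#' the patch center. The in-patch x-axis is the projection of the world +x axis
#' (falling back to +y when degenerate); the choice only rotates the unwrapped
#' plane and affects no metric.
#'
#' @param center_direction unit 3-vector from the sphere center to the patch center.
#' @return 3 x 3 matrix with columns ex, ey, ez.
#' @export
patch_frame <- function(center_direction) {
  ez <- normalize3(as.numeric(center_direction))
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * ez) * ez
  if (sum(ex^2) < 1e-12) ex <- c(0, 1, 0) - sum(c(0, 1, 0) * ez) * ez
  ex <- normalize3(ex)
  ey <- cross3(ez, ex)
  cbind(ex = ex, ey = ey, ez = ez)
}

as_angular <- function(a) {
  ab <- if (is.null(dim(a))) matrix(as.numeric(a), ncol = 2L) else as.matrix(a)
  if (ncol(ab) != 2L) stop("angular coordinates must have two columns (alpha, beta)")
  storage.mode(ab) <- "double"
  colnames(ab) <- c("alpha", "beta")
  ab
}

#' Unit directions of angular coordinates
#'
#' Direction of (alpha, beta) is proportional to `(tan(alpha), tan(beta), 1)`
#' in the patch frame.
#'
#' @param ab matrix (or length-2 vector) of angular coordinates in radians.
#' @return n x 3 matrix of unit vectors in patch-frame coordinates.
#' @export
angular_to_direction <- function(ab) {
  ab <- as_angular(ab)
  if (any(abs(ab) >= pi / 2)) stop("angular coordinates must satisfy |alpha|, |beta| < pi/2")
  d <- cbind(tan(ab[, 1]), tan(ab[, 2]), 1)
  d / sqrt(rowSums(d^2))
}

#' @rdname angular_to_direction
#' @param dirs n x 3 matrix of direction vectors in patch-frame coordinates
#'   with positive z component (open hemisphere around the patch center).
#' @export
direction_to_angular <- function(dirs) {
  dirs <- as_points3(dirs)
  if (any(dirs[, 3] <= 0))
    stop("direction outside the open hemisphere around the patch center")
  cbind(alpha = atan2(dirs[, 1], dirs[, 3]), beta = atan2(dirs[, 2], dirs[, 3]))
}

#' Project points radially onto a sphere
#'
#' Each point is replaced by the sphere point on the ray from the sphere
#' center through it, expressed in the angular frame of a patch.
#'
#' @param p n x 3 matrix of points (mm), none equal to the sphere center.
#' @param sph a [sphere()].
#' @param frame patch frame from [patch_frame()]; when `NULL`, the frame of the
#'   spherical centroid of the projected directions is used.
#' @return n x 2 matrix of angular coordinates with the frame in
#'   `attr(, "frame")`.
#' @export
project_point <- function(p, sph, frame = NULL) {
  pts <- as_points3(p)
  rel <- sweep(pts, 2, sph$center)
  nrm <- sqrt(rowSums(rel^2))
  if (any(nrm < 1e-12)) stop("undefined projection: point coincides with the sphere center")
  dirs <- rel / nrm
  if (is.null(frame)) frame <- patch_frame(colSums(dirs))
  ab <- direction_to_angular(dirs %*% frame)
  attr(ab, "frame") <- frame
  ab
}

#' World coordinates of angular points
#'
#' @inheritParams angular_to_direction
#' @param sph a [sphere()].
#' @param frame patch frame.
#' @return n x 3 matrix of points on the sphere surface in world mm.
#' @export
angular_to_world <- function(ab, sph, frame) {
  d <- angular_to_direction(ab) %*% t(frame)
  sweep(sph$radius * d, 2, sph$center, "+")
}

#' Geodesic (great-circle) distance between surface points
#'
#' @param a,b angular coordinates (recycled row-wise when one has a single row).
#' @param sph a [sphere()].
#' @return geodesic distances in mm, `R * gamma` with `gamma` the central angle.
#' @export
geodesic_distance <- function(a, b, sph) {
  u <- angular_to_direction(a)
  v <- angular_to_direction(b)
  if (nrow(u) == 1L && nrow(v) > 1L) u <- u[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(u) > 1L) v <- v[rep(1L, nrow(u)), , drop = FALSE]
  chord <- sqrt(rowSums((u - v)^2))
  sph$radius * 2 * asin(pmin(1, chord / 2))
}

# n x m matrix of geodesic distances between two direction sets (patch frame
# or world frame, as long as both use the same one)
geodesic_cross <- function(dirs_a, dirs_b, radius) {
  # central angle via the chord length, exact down to zero separation
  d2 <- outer(dirs_a[, 1], dirs_b[, 1], "-")^2 +
    outer(dirs_a[, 2], dirs_b[, 2], "-")^2 +
    outer(dirs_a[, 3], dirs_b[, 3], "-")^2
  half <- sqrt(d2) / 2
  half[half > 1] <- 1
  radius * 2 * asin(half)
}

#' Unwrap a spherical patch point to the plane
#'
#' Azimuthal-equidistant image of an angular point: the planar radial distance
#' from the origin equals the geodesic distance from the patch center, and the
#' azimuth is computed quadrant-safely as `atan2(tan(beta), tan(alpha))` so
#' that [wrap_to_sphere()] is its exact inverse.
#'
#' @inheritParams angular_to_direction
#' @param sph a [sphere()].
#' @return n x 2 matrix of planar coordinates (mm).
#' @export
unwrap_to_plane <- function(ab, sph) {
  ab <- as_angular(ab)
  if (any(abs(ab) >= pi / 2)) stop("angular coordinates must satisfy |alpha|, |beta| < pi/2")
  ta <- tan(ab[, 1])
  tb <- tan(ab[, 2])
  rho <- sqrt(ta^2 + tb^2)
  gam <- atan(rho)               # central angle from patch center
  k <- sph$radius * gam
  theta <- atan2(tb, ta)         # 0 at the origin where atan2(0, 0) = 0
  cbind(x = k * cos(theta), y = k * sin(theta))
}

#' Wrap a planar point back onto the sphere
#'
#' Exact inverse of [unwrap_to_plane()] on the open hemisphere: a planar point
#' at radial distance `s` maps to the surface point at geodesic distance `s`
#' from the patch center along the same azimuth.
#'
#' @param xy n x 2 matrix of planar coordinates (mm) with `sqrt(x^2+y^2) < pi*R/2`.
#' @param sph a [sphere()].
#' @return n x 2 matrix of angular coordinates.
#' @export
wrap_to_sphere <- function(xy, sph) {
  xy <- if (is.null(dim(xy))) matrix(as.numeric(xy), ncol = 2L) else as.matrix(xy)
  if (ncol(xy) != 2L) stop("planar coordinates must have two columns")
  s <- sqrt(rowSums(xy^2))
  if (any(s >= pi * sph$radius / 2))
    stop("planar point outside the open hemisphere (s >= pi*R/2)")
  gam <- s / sph$radius
  scale <- ifelse(s > 0, sin(gam) / s, 0)
  dirs <- cbind(xy[, 1] * scale, xy[, 2] * scale, cos(gam))
  direction_to_angular(dirs)
}

# area-distortion factor of the azimuthal-equidistant map at planar radius s:
# a planar area element dA maps to a spherical element dA * sinc(s/R)
ae_area_factor <- function(s, radius) {
  t <- s / radius
  ifelse(t > 0, sin(t) / t, 1)
}
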