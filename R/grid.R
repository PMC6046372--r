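# Quasi-regular grid on the POI: a regular 1 mm lattice in the unwrapped plane,
# clipped to the POI and wrapped back to the sphere. Each cell carries its
# spherical center and spherical area (planar area times the distortion factor
# sin(s/R)/(s/R) of the azimuthal-equidistant map).

# Grid spacing is fixed and not user-facing; exposed as an internal constant
# so tests and the acceptance script can build finer grids.
GRID_SPACING <- 1

#' Build the analysis grid inside a POI
#'
#' Lays a regular square lattice of fixed spacing over the unwrapped POI,
#' keeps cells whose centers fall inside the patch boundary, and wraps them
#' back to the sphere.
#'
#' @param poi a `tms_poi` from [build_poi()].
#' @param spacing lattice spacing in mm; `NULL` uses the fixed internal 1 mm.
#' @return an object of class `tms_grid`: full lattice axes `xs`, `ys`, the
#'   logical `inside` raster, and `cells`, a data frame over inside cells with
#'   planar coordinates, angular coordinates, world coordinates, and spherical
#'   area `area` (mm^2).
#' @export
build_grid <- function(poi, spacing = NULL) {
  if (is.null(spacing)) spacing <- GRID_SPACING
  bb <- apply(poi$boundary_xy, 2, range)
  # cell centers on a lattice anchored at the plane origin (patch center)
  xs <- (seq(floor(bb[1, 1] / spacing) - 1L, ceiling(bb[2, 1] / spacing) + 1L) + 0.5) * spacing
  ys <- (seq(floor(bb[1, 2] / spacing) - 1L, ceiling(bb[2, 2] / spacing) + 1L) + 0.5) * spacing
  nx <- length(xs)
  ny <- length(ys)
  cx <- rep(xs, times = ny)
  cy <- rep(ys, each = nx)
  inside <- point_in_poi(cbind(cx, cy), poi)
  idx <- which(inside)
  x <- cx[idx]
  y <- cy[idx]
  s <- sqrt(x^2 + y^2)
  ab <- wrap_to_sphere(cbind(x, y), poi$sphere)
  w <- angular_to_world(ab, poi$sphere, poi$frame)
  cells <- data.frame(
    idx = idx, x = x, y = y, s = s,
    alpha = ab[, 1], beta = ab[, 2],
    wx = w[, 1], wy = w[, 2], wz = w[, 3],
    area = spacing^2 * ae_area_factor(s, poi$sphere$radius)
  )
  structure(list(
    xs = xs, ys = ys, nx = nx, ny = ny, spacing = spacing,
    inside = inside, cells = cells, poi = poi
  ), class = "tms_grid")
}

#' @export
print.tms_grid <- function(x, ...) {
  cat(sprintf("Spherical grid: %d cells (%.1f mm spacing), total area %.1f mm^2\n",
              nrow(x$cells), x$spacing, sum(x$cells$area)))
  invisible(x)
}

# patch-frame unit directions of the grid cell centers
grid_cell_directions <- function(grid) {
  angular_to_direction(cbind(grid$cells$alpha, grid$cells$beta))
}

# planar coordinates of all lattice nodes (column-major: x fastest)
lattice_xy <- function(grid) {
  cbind(rep(grid$xs, times = grid$ny), rep(grid$ys, each = grid$nx))
}

# patch-frame unit directions of all lattice nodes
lattice_directions <- function(grid) {
  xy <- lattice_xy(grid)
  s <- sqrt(rowSums(xy^2))
  gam <- s / grid$poi$sphere$radius
  scale <- ifelse(s > 0, sin(gam) / s, 0)
  cbind(xy[, 1] * scale, xy[, 2] * scale, cos(gam))
}

# bilinear interpolation weights of planar points in the full lattice;
# returns a sparse matrix (n points x nx*ny)
bilinear_weights <- function(xy, grid) {
  xy <- as.matrix(xy)
  h <- grid$spacing
  ix <- findInterval(xy[, 1], grid$xs)
  iy <- findInterval(xy[, 2], grid$ys)
  if (any(ix < 1L | ix >= grid$nx | iy < 1L | iy >= grid$ny))
    stop("point outside the lattice")
  tx <- (xy[, 1] - grid$xs[ix]) / h
  ty <- (xy[, 2] - grid$ys[iy]) / h
  n <- nrow(xy)
  node <- function(dx, dy) (iy + dy - 1L) * grid$nx + (ix + dx)
  i <- rep(seq_len(n), 4L)
  j <- c(node(0L, 0L), node(1L, 0L), node(0L, 1L), node(1L, 1L))
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, grid$nx * grid$ny))
}
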