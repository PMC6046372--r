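# Earth Mover's Distance between excitability profiles. Maps are normalized
# by volume to unit mass, the ground distance is the geodesic distance on the
# shared sphere, and the optimal transport cost is reported relative to the
# cost between two extreme single-peak maps separated by the active-area
# diameter d_max. The exact transportation problem is solved with a
# least-cost-initialized transportation simplex (MODI method).

#' Exact solution of the balanced transportation problem
#'
#' Minimizes `sum(F * cost)` over nonnegative flows `F` with row sums `supply`
#' and column sums `demand` (scaled to balance). Least-cost initial basis,
#' then MODI (u-v) pivots on the basis tree.
#'
#' @param supply,demand positive mass vectors.
#' @param cost m x n ground-distance matrix.
#' @return list with `cost` (optimal total cost per unit total mass of
#'   `supply`), `flows`, `arcs` (basis arc indices as an (m+n-1) x 2 matrix).
#' @export
solve_transport <- function(supply, demand, cost) {
  s0 <- as.numeric(supply)
  d0 <- as.numeric(demand)
  cost <- as.matrix(cost)
  m <- length(s0)
  n <- length(d0)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  if (any(s0 <= 0) || any(d0 <= 0)) stop("masses must be positive")
  tot <- sum(s0)
  d0 <- d0 * (tot / sum(d0))

  if (m == 1L || n == 1L) {
    # single source or sink: flow pattern is forced
    fl <- if (m == 1L) matrix(d0, 1L) else matrix(s0, ncol = 1L)
    return(list(cost = sum(fl * cost) / tot, flows = fl,
                arcs = which(fl >= 0, arr.ind = TRUE)))
  }

  # least-cost initial basic solution; ties close the row, leaving a
  # degenerate (zero) allocation on the column side
  nb <- m + n - 1L
  bi <- integer(nb); bj <- integer(nb); bf <- numeric(nb)
  nba <- 0L
  rs <- s0; rd <- d0
  open_r <- rep(TRUE, m); open_c <- rep(TRUE, n)
  ord <- order(cost)
  for (idx in ord) {
    i <- (idx - 1L) %% m + 1L
    j <- (idx - 1L) %/% m + 1L
    if (!open_r[i] || !open_c[j]) next
    f <- min(rs[i], rd[j])
    nba <- nba + 1L
    bi[nba] <- i; bj[nba] <- j; bf[nba] <- f
    if (nba == nb) { open_r[i] <- FALSE; open_c[j] <- FALSE; break }
    if (rs[i] <= rd[j]) { open_r[i] <- FALSE; rd[j] <- rd[j] - f } else {
      open_c[j] <- FALSE; rs[i] <- rs[i] - f
    }
  }
  if (nba < nb) {
    # repair a collapsed (degenerate) start: connect remaining components
    # with zero-flow arcs, keeping the basis acyclic
    parent <- seq_len(m + n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (t in seq_len(nba)) {
      a <- find(bi[t]); b <- find(m + bj[t]); if (a != b) parent[a] <- b
    }
    for (i in seq_len(m)) for (j in seq_len(n)) {
      if (nba == nb) break
      a <- find(i); b <- find(m + j)
      if (a != b) { parent[a] <- b; nba <- nba + 1L; bi[nba] <- i; bj[nba] <- j; bf[nba] <- 0 }
    }
  }

  tol <- 1e-12 * max(abs(cost), 1)
  max_iter <- 200L * (m + n)
  for (iter in seq_len(max_iter)) {
    # duals by traversal of the basis tree (nodes: rows 1..m, cols m+1..m+n)
    arcs_at <- vector("list", m + n)
    for (t in seq_len(nb)) {
      arcs_at[[bi[t]]] <- c(arcs_at[[bi[t]]], t)
      arcs_at[[m + bj[t]]] <- c(arcs_at[[m + bj[t]]], t)
    }
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    stack <- 1L
    while (length(stack)) {
      node <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (t in arcs_at[[node]]) {
        i <- bi[t]; j <- bj[t]
        if (node <= m) {
          if (is.na(v[j])) { v[j] <- cost[i, j] - u[i]; stack <- c(stack, m + j) }
        } else {
          if (is.na(u[i])) { u[i] <- cost[i, j] - v[j]; stack <- c(stack, i) }
        }
      }
    }
    red <- cost - outer(u, v, "+")
    red[cbind(bi, bj)] <- 0
    ent <- which.min(red)
    if (red[ent] >= -tol) break
    ei <- (ent - 1L) %% m + 1L
    ej <- (ent - 1L) %/% m + 1L

    # cycle: tree path from row node ei to col node ej
    par_arc <- integer(m + n); par_node <- integer(m + n)
    seen <- logical(m + n); seen[ei] <- TRUE
    stack <- ei
    while (length(stack) && !seen[m + ej]) {
      node <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (t in arcs_at[[node]]) {
        other <- if (node <= m) m + bj[t] else bi[t]
        if (!seen[other]) {
          seen[other] <- TRUE; par_arc[other] <- t; par_node[other] <- node
          stack <- c(stack, other)
        }
      }
    }
    path <- integer(0)
    node <- m + ej
    while (node != ei) { path <- c(par_arc[node], path); node <- par_node[node] }
    dec <- path[seq(1L, length(path), by = 2L)]   # arcs leaving row ei side alternate
    inc <- if (length(path) > 1L) path[seq(2L, length(path), by = 2L)] else integer(0)
    theta <- min(bf[dec])
    leave <- dec[which.min(bf[dec])]
    bf[dec] <- bf[dec] - theta
    bf[inc] <- bf[inc] + theta
    bi[leave] <- ei; bj[leave] <- ej; bf[leave] <- theta
    if (iter == max_iter) stop("transportation simplex failed to converge")
  }

  flow <- pmax(bf, 0)
  list(cost = sum(flow * cost[cbind(bi, bj)]) / tot,
       flows = { F <- matrix(0, m, n); F[cbind(bi, bj)] <- flow; F },
       arcs = cbind(bi, bj))
}

# weighted signature (mass + world-frame unit directions) of a thresholded map
map_signature <- function(map, max_bins = 300L, mode = c("cells", "points")) {
  mode <- match.arg(mode)
  sph <- map$geometry$sphere
  if (mode == "cells") {
    cells <- active_cells(map)
    if (nrow(cells) == 0L) stop("undefined EMD: empty thresholded map")
    mass <- map$heights[map$active] * cells$area
    dirs <- sweep(cbind(cells$wx, cells$wy, cells$wz), 2, sph$center)
  } else {
    if (nrow(map$merged) == 0L) stop("undefined EMD: no merged points")
    mass <- map$merged$h
    w <- angular_to_world(cbind(map$merged$alpha, map$merged$beta), sph,
                          map$geometry$frame)
    dirs <- sweep(w, 2, sph$center)
  }
  keep <- mass > 0
  mass <- mass[keep]
  dirs <- dirs[keep, , drop = FALSE]
  if (length(mass) == 0L) stop("undefined EMD: map has zero volume")
  dirs <- dirs / sqrt(rowSums(dirs^2))
  mass <- mass / sum(mass)
  if (length(mass) > max_bins) {
    agg <- aggregate_signature(dirs, mass, max_bins)
    dirs <- agg$dirs
    mass <- agg$mass
  }
  list(mass = mass, dirs = dirs)
}

# deterministic Lloyd clustering of a weighted signature on the sphere
aggregate_signature <- function(dirs, mass, k, iter = 30L) {
  n <- nrow(dirs)
  centers <- dirs[unique(round(seq(1L, n, length.out = k))), , drop = FALSE]
  assign <- NULL
  for (it in seq_len(iter)) {
    sim <- dirs %*% t(centers)
    new_assign <- max.col(sim, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (c in unique(assign)) {
      g <- assign == c
      ctr <- colSums(dirs[g, , drop = FALSE] * mass[g])
      nrm <- sqrt(sum(ctr^2))
      if (nrm > 0) centers[c, ] <- ctr / nrm
    }
  }
  used <- sort(unique(assign))
  list(
    dirs = centers[used, , drop = FALSE],
    mass = vapply(used, function(c) sum(mass[assign == c]), numeric(1))
  )
}

#' Relative Earth Mover's Distance between two maps
#'
#' Both maps are normalized by volume to unit mass; the transport cost with a
#' geodesic ground distance is computed exactly and expressed as a percentage
#' of the cost between two extreme single-peak maps at the ends of the active
#' area (`raw_emd / d_max * 100`). Maps with more than `max_bins`
#' suprathreshold cells are first aggregated into `max_bins` weighted clusters
#' on the sphere.
#'
#' @param a,b thresholded `motor_map`s on one shared geometry.
#' @param active an [active_area()] (or a positive `d_max` in mm).
#' @param mode `"cells"` (default, transport between suprathreshold cells) or
#'   `"points"` (between the raw merged response distributions).
#' @param max_bins signature size cap for the exact solve.
#' @return object of class `tms_emd` with `raw_emd` (mm), `d_max` (mm) and
#'   `relative` (percent).
#' @export
emd_relative <- function(a, b, active, mode = c("cells", "points"),
                         max_bins = 300L) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "motor_map"), inherits(b, "motor_map"))
  if (!same_geometry(a$geometry, b$geometry))
    stop("incompatible maps: EMD requires maps on one shared sphere and grid")
  d_max <- if (inherits(active, "active_area")) active$d_max else as.numeric(active)
  if (!is.finite(d_max) || d_max <= 0)
    stop("degenerate active area: d_max must be positive")
  sa <- map_signature(a, max_bins = max_bins, mode = mode)
  sb <- map_signature(b, max_bins = max_bins, mode = mode)
  cost <- geodesic_cross(sa$dirs, sb$dirs, a$geometry$sphere$radius)
  raw <- solve_transport(sa$mass, sb$mass, cost)$cost
  structure(list(raw_emd = raw, d_max = d_max, relative = 100 * raw / d_max,
                 mode = mode),
            class = "tms_emd")
}

#' @export
print.tms_emd <- function(x, ...) {
  cat(sprintf("EMD (%s mode): %.3f mm raw, d_max %.2f mm, relative %.2f%%\n",
              x$mode, x$raw_emd, x$d_max, x$relative))
  invisible(x)
}
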