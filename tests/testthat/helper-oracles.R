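# Shared fixtures and independent oracles used across the suite.

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

# points sampled exactly on a sphere
sphere_samples <- function(n, center = c(0, 0, 0), radius = 85, seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    sweep(radius * u, 2, center, "+")
  })
}

# independent sphere-fit oracle: grid-search initialization + Nelder-Mead on
# the geometric objective (no shared code with fit_sphere)
oracle_fit_sphere <- function(pts) {
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(pts, 2, p[1:3])^2))
    sum((d - p[4])^2)
  }
  ctr0 <- colMeans(pts)
  r0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr0)^2)))
  best <- NULL
  for (dx in c(-r0 / 2, 0, r0 / 2)) for (dy in c(-r0 / 2, 0, r0 / 2)) {
    start <- c(ctr0 + c(dx, dy, 0), r0)
    fit <- stats::optim(start, obj, control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(center = best$par[1:3], radius = best$par[4])
}

# thin-plate RBF exact interpolant in the plane (reference for the smooth
# surface): nodes n x 2, values length n
tps_interpolant <- function(nodes, values) {
  phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  A <- phi(as.matrix(stats::dist(nodes)))
  P <- cbind(1, nodes)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(M, c(values, 0, 0, 0))
  function(pts) {
    D <- sqrt(outer(pts[, 1], nodes[, 1], "-")^2 +
                outer(pts[, 2], nodes[, 2], "-")^2)
    as.numeric(phi(D) %*% coef[seq_len(nrow(nodes))] +
                 cbind(1, pts) %*% coef[nrow(nodes) + 1:3])
  }
}

# brute-force transportation LP via boot::simplex (exact oracle, small m*n)
lp_transport_oracle <- function(s, d, C) {
  m <- length(s)
  n <- length(d)
  A3 <- NULL
  for (i in seq_len(m)) {
    r <- matrix(0, m, n); r[i, ] <- 1; A3 <- rbind(A3, as.vector(r))
  }
  for (j in seq_len(n - 1L)) {
    r <- matrix(0, m, n); r[, j] <- 1; A3 <- rbind(A3, as.vector(r))
  }
  unname(boot::simplex(a = as.vector(C), A3 = A3, b3 = c(s, d[seq_len(n - 1L)]),
                       maxi = FALSE)$value)
}

# quick noiseless single-bump session for pipeline tests
quick_bump_session <- function(seed = 7, amplitude = 500, sigma = 6,
                               jitter = 0, noise_sdlog = 0, noise_floor = 0,
                               patch_radius = 16, node_spacing = 5,
                               offset = c(0, 0)) {
  proto <- protocol_spec(node_spacing = node_spacing,
                         patch_radius = patch_radius,
                         jitter = jitter, noise_sdlog = noise_sdlog,
                         noise_floor = noise_floor, seed = seed)
  bumps <- list(bump_at_offset(proto, offset, amplitude, sigma, "APB"))
  generate_session(proto, bumps)
}

# geodesic distance between two world points on a sphere (independent direct
# formula used by metric tests)
world_geodesic <- function(p, q, sph) {
  u <- (p - sph$center) / sqrt(sum((p - sph$center)^2))
  v <- (q - sph$center) / sqrt(sum((q - sph$center)^2))
  sph$radius * acos(min(1, max(-1, sum(u * v))))
}
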