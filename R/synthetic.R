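# Synthetic stimulation sessions with analytic ground truth. The generator
# emulates a standard motor-mapping protocol: a virtual grid of stimulation
# nodes on a spherical patch, each node visited several times in a
# pseudo-random order with a small navigation error, and spatially smooth
# nonnegative response fields (Gaussian excitability bumps) per channel with
# multiplicative lognormal amplitude variability plus an additive noise floor.

#' Stimulation protocol specification
#'
#' Defaults reflect a typical navigated motor-mapping session: a 5 mm virtual
#' grid covering a patch of about 2 cm radius on an 85 mm head sphere, five
#' pseudo-randomly ordered visits per node, and a navigation error kept below
#' 2 mm.
#'
#' @param sph the head [sphere()].
#' @param center_direction unit vector from sphere center to the patch center.
#' @param node_spacing grid step between stimulation nodes, mm.
#' @param patch_radius geodesic radius of the stimulated patch, mm.
#' @param n_repetitions stimuli per node.
#' @param jitter maximal navigation error per stimulus, mm (tangential,
#'   truncated Gaussian with sd `jitter/2`).
#' @param noise_sdlog sdlog of the multiplicative lognormal amplitude noise
#'   (mean 1); 0 disables it.
#' @param noise_floor sd of the additive baseline noise in response units;
#'   responses are floored at 0.
#' @param seed integer seed; the generator is fully deterministic given the
#'   protocol.
#' @return a `protocol_spec` list.
#' @export
protocol_spec <- function(sph = sphere(c(0, 0, 0), 85),
                          center_direction = c(0, 0, 1),
                          node_spacing = 5, patch_radius = 21,
                          n_repetitions = 5, jitter = 2,
                          noise_sdlog = 0.2, noise_floor = 2, seed = 1L) {
  stopifnot(node_spacing > 0, n_repetitions >= 1, patch_radius > 0,
            jitter >= 0, noise_sdlog >= 0, noise_floor >= 0)
  if (patch_radius >= pi * sph$radius / 2)
    stop("patch larger than a hemisphere")
  structure(list(sphere = sph, center_direction = normalize3(center_direction),
                 node_spacing = node_spacing, patch_radius = patch_radius,
                 n_repetitions = n_repetitions, jitter = jitter,
                 noise_sdlog = noise_sdlog, noise_floor = noise_floor,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Gaussian excitability bump specification
#'
#' @param center_direction unit vector (world frame) to the bump center on the
#'   sphere.
#' @param amplitude peak response (e.g. uV).
#' @param sigma geodesic width of the bump, mm.
#' @param channel response channel the bump contributes to.
#' @return a `bump_spec` list.
#' @export
bump_spec <- function(center_direction, amplitude, sigma, channel) {
  stopifnot(amplitude >= 0, sigma > 0)
  structure(list(center_direction = normalize3(center_direction),
                 amplitude = amplitude, sigma = sigma, channel = channel),
            class = "bump_spec")
}

#' Bump placed at a planar offset from the protocol patch center
#'
#' @param protocol a [protocol_spec()].
#' @param offset length-2 planar offset (mm) in the patch's unwrapped plane.
#' @inheritParams bump_spec
#' @return a [bump_spec()].
#' @export
bump_at_offset <- function(protocol, offset, amplitude, sigma, channel) {
  frame <- patch_frame(protocol$center_direction)
  ab <- wrap_to_sphere(matrix(offset, 1), protocol$sphere)
  dir <- (angular_to_direction(ab) %*% t(frame))[1, ]
  bump_spec(dir, amplitude, sigma, channel)
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# node lattice of a protocol in its unwrapped plane
protocol_nodes <- function(protocol) {
  sp <- protocol$node_spacing
  half <- floor(protocol$patch_radius / sp) * sp
  ax <- seq(-half, half, by = sp)
  g <- as.matrix(expand.grid(x = ax, y = ax))
  g[sqrt(rowSums(g^2)) <= protocol$patch_radius, , drop = FALSE]
}

# noiseless response field of the bumps at world points on the sphere
bump_field <- function(bumps, world_dirs, radius, channel) {
  total <- numeric(nrow(world_dirs))
  for (b in bumps) {
    if (b$channel != channel) next
    r <- radius * acos(pmin(1, pmax(-1, world_dirs %*% b$center_direction)))
    total <- total + b$amplitude * exp(-r^2 / (2 * b$sigma^2))
  }
  total
}

#' Generate a synthetic stimulation session with ground truth
#'
#' Builds the node grid, visits every node `n_repetitions` times in a seeded
#' pseudo-random order with a bounded tangential navigation error, evaluates
#' the bump response fields at the true stimulated locations, applies the
#' noise model, and returns the session together with the generator truth
#' (bump parameters and fine-quadrature areas, volumes and CoGs of the
#' thresholded true fields).
#'
#' @param protocol a [protocol_spec()].
#' @param bumps list of [bump_spec()]s.
#' @param threshold threshold at which ground-truth areas/volumes are computed.
#' @param subject,session metadata tokens.
#' @return list with `session` (a `tms_session`), `truth` (per-channel list),
#'   `protocol`, `bumps`.
#' @export
generate_session <- function(protocol, bumps, threshold = 50,
                             subject = "synthetic", session = "session1") {
  stopifnot(inherits(protocol, "protocol_spec"))
  sph <- protocol$sphere
  frame <- patch_frame(protocol$center_direction)
  nodes <- protocol_nodes(protocol)
  nn <- nrow(nodes)
  channels <- unique(vapply(bumps, function(b) b$channel, character(1)))
  if (length(channels) == 0L) stop("at least one bump (channel) is required")

  df <- with_seed(protocol$seed, {
    order_idx <- unlist(lapply(seq_len(protocol$n_repetitions),
                               function(r) sample.int(nn)))
    pos <- nodes[order_idx, , drop = FALSE]
    ns <- nrow(pos)
    if (protocol$jitter > 0) {
      jx <- stats::rnorm(ns, 0, protocol$jitter / 2)
      jy <- stats::rnorm(ns, 0, protocol$jitter / 2)
      jn <- sqrt(jx^2 + jy^2)
      over <- jn > protocol$jitter
      shrink <- ifelse(over, protocol$jitter / jn, 1)
      pos <- pos + cbind(jx * shrink, jy * shrink)
    }
    ab <- wrap_to_sphere(pos, sph)
    world <- angular_to_world(ab, sph, frame)
    wdirs <- sweep(world, 2, sph$center)
    wdirs <- wdirs / sqrt(rowSums(wdirs^2))
    out <- data.frame(id = sprintf("s%04d", seq_len(ns)),
                      coil_x = world[, 1], coil_y = world[, 2],
                      coil_z = world[, 3], stringsAsFactors = FALSE)
    for (ch in channels) {
      signal <- bump_field(bumps, wdirs, sph$radius, ch)
      if (protocol$noise_sdlog > 0)
        signal <- signal * stats::rlnorm(ns, -protocol$noise_sdlog^2 / 2,
                                         protocol$noise_sdlog)
      if (protocol$noise_floor > 0)
        signal <- signal + stats::rnorm(ns, 0, protocol$noise_floor)
      out[[ch]] <- pmax(signal, 0)
    }
    out
  })

  truth <- lapply(channels, function(ch) {
    ground_truth_quadrature(protocol, bumps, ch, threshold)
  })
  names(truth) <- channels
  list(session = new_session(df, subject = subject, session = session),
       truth = truth, protocol = protocol, bumps = bumps)
}

#' Fine-quadrature ground truth of a bump field
#'
#' Integrates the true (noiseless) response field on a fine planar lattice
#' (default 0.25 mm, four times finer than the analysis grid) with the
#' spherical area correction: suprathreshold area, volume under the
#' thresholded field, CoG and hotspot of the field.
#'
#' @param protocol a [protocol_spec()].
#' @param bumps list of [bump_spec()]s.
#' @param channel channel to evaluate.
#' @param threshold threshold level.
#' @param resolution quadrature spacing, mm.
#' @return list with `area`, `volume`, `cog`, `hotspot`, `max`.
#' @export
ground_truth_quadrature <- function(protocol, bumps, channel, threshold = 50,
                                    resolution = 0.25) {
  sph <- protocol$sphere
  frame <- patch_frame(protocol$center_direction)
  extent <- protocol$patch_radius + 15
  ax <- seq(-extent, extent, by = resolution)
  g <- as.matrix(expand.grid(x = ax, y = ax))
  s <- sqrt(rowSums(g^2))
  keep <- s < pi * sph$radius / 2 - 1e-6
  g <- g[keep, , drop = FALSE]
  s <- s[keep]
  ab <- wrap_to_sphere(g, sph)
  world <- angular_to_world(ab, sph, frame)
  wdirs <- sweep(world, 2, sph$center)
  wdirs <- wdirs / sqrt(rowSums(wdirs^2))
  h <- bump_field(bumps, wdirs, sph$radius, channel)
  dA <- resolution^2 * ae_area_factor(s, sph$radius)
  supra <- h >= threshold
  vol <- sum(h[supra] * dA[supra])
  cog <- if (vol > 0) {
    w <- h[supra] * dA[supra]
    project_to_sphere_surface(colSums(world[supra, , drop = FALSE] * w) / sum(w), sph)
  } else NULL
  list(area = sum(dA[supra]), volume = vol, cog = cog,
       hotspot = world[which.max(h), ], max = max(h))
}

#' Generate a matched pair of sessions with displaced representations
#'
#' The second session uses the same protocol (with a derived seed) but every
#' bump center shifted geodesically by `displacement` mm along the patch
#' x-axis, emulating a test-retest pair with a true map shift.
#'
#' @param protocol a [protocol_spec()].
#' @param bumps list of [bump_spec()]s.
#' @param displacement geodesic shift, mm (must be smaller than the patch
#'   radius).
#' @param threshold ground-truth threshold.
#' @return list with `a`, `b` (each as returned by [generate_session()]).
#' @export
generate_two_session_pair <- function(protocol, bumps, displacement,
                                      threshold = 50) {
  if (displacement >= protocol$patch_radius)
    stop("displacement must be smaller than the patch radius")
  frame <- patch_frame(protocol$center_direction)
  axis <- frame[, 2]   # rotation about the patch y-axis shifts along +x
  ang <- displacement / protocol$sphere$radius
  shifted <- lapply(bumps, function(b) {
    b$center_direction <- rotate_about_axis(b$center_direction, axis, ang)
    b
  })
  proto_b <- protocol
  proto_b$seed <- protocol$seed + 1L
  list(
    a = generate_session(protocol, bumps, threshold, session = "day1"),
    b = generate_session(proto_b, shifted, threshold, session = "day2")
  )
}

# Rodrigues rotation of v about unit axis k by angle ang
rotate_about_axis <- function(v, k, ang) {
  k <- normalize3(k)
  v * cos(ang) + cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
}
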