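sph85 <- sphere(c(0, 0, 0), 85)
frame_z <- patch_frame(c(0, 0, 1))

# a constant-height map over a geodesic disc, built directly on a grid
disc_map <- function(radius_mm, height = 100, sph = sph85, spacing = NULL) {
  poi <- build_poi(matrix(c(0, 0), 1), sph, frame_z, margin = radius_mm)
  grid <- build_grid(poi, spacing = spacing)
  merged <- structure(data.frame(alpha = 0, beta = 0, h = height,
                                 repetitions = 1),
                      class = c("merged_points", "data.frame"))
  geometry <- structure(list(sphere = sph, frame = frame_z, poi = poi,
                             grid = grid), class = "map_geometry")
  structure(list(
    heights = rep(height, nrow(grid$cells)),
    field = rep(height, grid$nx * grid$ny),
    geometry = geometry, merged = merged, channel = "X",
    subject = "t", session = "t",
    config = map_config(), kind = "th_map", threshold = 0,
    active = rep(TRUE, nrow(grid$cells)), call = NULL
  ), class = "motor_map")
}

test_that("area is the spherical cell-area sum and is rotation invariant", {
  m <- disc_map(15)
  cap <- 2 * pi * 85^2 * (1 - cos(15 / 85))
  expect_equal(map_area(m), cap, tolerance = 0.01 * cap)

  empty <- m
  empty$active <- rep(FALSE, length(m$active))
  expect_equal(map_area(empty), 0)

  # rotating the whole dataset leaves the area unchanged (within 1%)
  gs <- quick_bump_session(seed = 13)
  th <- threshold_map(motor_map(gs$session, "APB"))
  rot <- gs$session
  theta <- 0.6
  R <- rbind(c(1, 0, 0),
             c(0, cos(theta), -sin(theta)),
             c(0, sin(theta), cos(theta)))
  xyz <- as.matrix(rot$points[c("coil_x", "coil_y", "coil_z")]) %*% t(R)
  rot$points[c("coil_x", "coil_y", "coil_z")] <- xyz
  th_rot <- threshold_map(motor_map(rot, "APB"))
  expect_equal(map_area(th_rot), map_area(th), tolerance = 0.01)
})

test_that("volume integrates height times spherical cell area", {
  m <- disc_map(15, height = 100)
  expect_equal(map_volume(m), 100 * map_area(m), tolerance = 1e-3)

  empty <- m
  empty$active <- rep(FALSE, length(m$active))
  expect_equal(map_volume(empty), 0)

  # planar-limit Gaussian bump: volume ~ 2 pi sigma^2 A at threshold 0
  sph_flat <- sphere(c(0, 0, 0), 2000)
  poi <- build_poi(matrix(c(0, 0), 1), sph_flat, frame_z, margin = 40)
  grid <- build_grid(poi)
  r <- sqrt(grid$cells$x^2 + grid$cells$y^2)
  A <- 300; sig <- 6
  gm <- disc_map(15)
  gm$geometry <- structure(list(sphere = sph_flat, frame = frame_z, poi = poi,
                                grid = grid), class = "map_geometry")
  gm$heights <- A * exp(-r^2 / (2 * sig^2))
  gm$active <- rep(TRUE, nrow(grid$cells))
  expect_equal(map_volume(gm), 2 * pi * sig^2 * A,
               tolerance = 0.03 * 2 * pi * sig^2 * A)
})

test_that("raw CoG follows the printed weighted-mean equation", {
  # single point: its own location
  m1 <- structure(data.frame(alpha = 0.1, beta = -0.05, h = 80,
                             repetitions = 1),
                  class = c("merged_points", "data.frame"))
  cg1 <- cog_raw(m1, sph = sph85, frame = frame_z)
  expect_equal(as.numeric(cg1),
               as.numeric(angular_to_world(c(0.1, -0.05), sph85, frame_z)),
               tolerance = 1e-9)

  # two equal-response points: projected Euclidean midpoint
  ab2 <- wrap_to_sphere(rbind(c(-6, 0), c(6, 0)), sph85)
  m2 <- structure(data.frame(alpha = ab2[, 1], beta = ab2[, 2],
                             h = c(100, 100), repetitions = 1),
                  class = c("merged_points", "data.frame"))
  cg2 <- cog_raw(m2, sph = sph85, frame = frame_z)
  w2 <- angular_to_world(ab2, sph85, frame_z)
  mid <- colMeans(w2)
  expect_equal(as.numeric(cg2),
               as.numeric(85 * mid / sqrt(sum(mid^2))), tolerance = 1e-9)

  # weighted x before projection: (0*100 + 10*300) / 400 = 7.5
  p <- rbind(c(0, 20, 82.6), c(10, 20, 82.6))
  sphx <- sphere(c(0, 0, 0), sqrt(sum(p[2, ]^2)))
  abx <- project_point(p, sphx)
  mx <- structure(data.frame(alpha = abx[, 1], beta = abx[, 2],
                             h = c(100, 300), repetitions = 1),
                  class = c("merged_points", "data.frame"))
  cgx <- cog_raw(mx, sph = sphx, frame = attr(abx, "frame"))
  wx <- angular_to_world(abx, sphx, attr(abx, "frame"))
  expect_equal(attr(cgx, "unprojected")[1],
               sum(wx[, 1] * c(100, 300)) / 400, tolerance = 1e-9)

  m0 <- m1; m0$h <- 0
  expect_error(cog_raw(m0, sph = sph85, frame = frame_z), "undefined CoG")
})

test_that("map CoG sits at the bump center and matches raw CoG for a point-like bump", {
  gs <- quick_bump_session(seed = 17)
  th <- threshold_map(motor_map(gs$session, "APB"))
  cg <- cog_map(th)
  expect_lt(sqrt(sum((cg - gs$truth$APB$cog)^2)), 1)

  # single active cell: its own center
  one <- th
  keep <- which(one$active)[1]
  one$active <- rep(FALSE, length(one$active))
  one$active[keep] <- TRUE
  cells <- one$geometry$grid$cells[keep, ]
  expect_equal(as.numeric(cog_map(one)),
               as.numeric(85 * normalize_rows(matrix(c(cells$wx, cells$wy, cells$wz), 1))),
               tolerance = 1e-6)

  # delta-like bump: map CoG within one grid spacing of raw CoG
  gs2 <- quick_bump_session(seed = 19, sigma = 2, amplitude = 400,
                            patch_radius = 10)
  th2 <- threshold_map(motor_map(gs2$session, "APB"))
  expect_lt(sqrt(sum((cog_map(th2) - cog_raw(th2))^2)), 1)

  expect_error(cog_map(threshold_map(motor_map(gs$session, "APB"), 1e6)),
               "undefined CoG")
})

test_that("hotspots pick the maxima with the documented tie-breaks", {
  gs <- quick_bump_session(seed = 23)
  th <- threshold_map(motor_map(gs$session, "APB"))
  hs <- find_hotspot(th)
  expect_lt(sqrt(sum((hs$map$world - gs$truth$APB$hotspot)^2)), 1)
  expect_equal(hs$raw$h, max(th$merged$h))

  # tie: two merged maxima; the one nearer the CoG wins. Build three points
  # with the CoG pulled toward the third (low) point near the second maximum.
  ab <- wrap_to_sphere(rbind(c(-10, 0), c(10, 0), c(7, 2)), sph85)
  merged <- structure(data.frame(alpha = ab[, 1], beta = ab[, 2],
                                 h = c(200, 200, 150), repetitions = 1),
                      class = c("merged_points", "data.frame"))
  m <- disc_map(15)
  m$merged <- merged
  hs2 <- find_hotspot(m)
  expect_equal(as.numeric(hs2$raw$point$alpha), as.numeric(ab[2, 1]),
               tolerance = 1e-9)
})

test_that("overlap obeys idempotence, disjointness and monotone bounds", {
  gs <- quick_bump_session(seed = 27)
  proto <- protocol_spec(node_spacing = 5, patch_radius = 16, jitter = 0,
                         noise_sdlog = 0, noise_floor = 0, seed = 27)
  two <- generate_session(proto, list(
    bump_at_offset(proto, c(-6, 0), 500, 5, "APB"),
    bump_at_offset(proto, c(6, 0), 400, 4, "ADM")))
  geo <- map_geometry(two$session)
  a <- threshold_map(motor_map(two$session, "APB", geometry = geo))
  b <- threshold_map(motor_map(two$session, "ADM", geometry = geo))

  self <- overlap_maps(a, a)
  expect_equal(self$heights[self$active], a$heights[a$active])
  expect_equal(which(self$active), which(a$active))
  expect_equal(map_area(self), map_area(a))

  ov <- overlap_maps(a, b)
  expect_lte(map_area(ov), min(map_area(a), map_area(b)))
  expect_lte(map_volume(ov), min(map_volume(a), map_volume(b)))
  # cellwise brute force
  expect_equal(which(ov$active), intersect(which(a$active), which(b$active)))
  expect_equal(ov$heights, pmin(a$heights, b$heights))

  # nested maps: overlap equals the smaller map
  hi <- threshold_map(motor_map(two$session, "APB", geometry = geo), 200)
  ov2 <- overlap_maps(a, hi)
  expect_equal(map_area(ov2), map_area(hi))
  expect_equal(map_volume(ov2), map_volume(hi))

  # disjoint thresholded supports give an empty overlap
  tight_a <- threshold_map(motor_map(two$session, "APB", geometry = geo), 450)
  tight_b <- threshold_map(motor_map(two$session, "ADM", geometry = geo), 350)
  expect_equal(sum(overlap_maps(tight_a, tight_b)$active), 0L)

  # maps on different geometries are rejected
  other <- threshold_map(motor_map(quick_bump_session(seed = 29,
                                                      patch_radius = 11)$session,
                                   "APB"))
  expect_error(overlap_maps(a, other), "incompatible")
  expect_error(overlap_maps(motor_map(two$session, "APB", geometry = geo), b),
               "thresholded")
})

test_that("active area collects suprathreshold points and their diameter", {
  df <- data.frame(id = as.character(1:4),
                   coil_x = c(0, 40, 10, 20), coil_y = c(0, 0, 5, 2),
                   coil_z = sqrt(85^2 - c(0, 40^2, 125, 404)),
                   APB = c(100, 80, 30, NA),
                   ADM = c(10, 20, 20, 60))
  sess <- motormap:::new_session(df)
  geo_sph <- sphere(c(0, 0, 0), 85)
  act <- active_area(sess, geo_sph, threshold = 50)
  expect_equal(act$n, 3L)   # points 1, 2 (APB) and 4 (ADM)
  # d_max equals the brute-force pairwise maximum
  loc <- motormap:::session_locations(sess)[c(1, 2, 4), ]
  dd <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
    world_geodesic(loc[i, ], loc[j, ], geo_sph)))
  expect_equal(act$d_max, max(dd), tolerance = 1e-9)

  # subthreshold-only extra point changes nothing
  df2 <- rbind(df, data.frame(id = "5", coil_x = -30, coil_y = 0,
                              coil_z = sqrt(85^2 - 900), APB = 20, ADM = 5))
  act2 <- active_area(motormap:::new_session(df2), geo_sph, threshold = 50)
  expect_equal(act2$d_max, act$d_max)
  expect_equal(act2$n, act$n)

  df3 <- df; df3$APB <- c(100, 10, 10, NA); df3$ADM <- c(10, 20, 20, 10)
  expect_error(active_area(motormap:::new_session(df3), geo_sph, 50),
               "degenerate active area")
})
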