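sph85 <- sphere(c(0, 0, 0), 85)
frame_z <- patch_frame(c(0, 0, 1))

test_that("merging averages coincident stimuli and respects the linkage radius", {
  ab0 <- matrix(rep(c(0.01, -0.02), each = 5), ncol = 2)
  h <- c(100, 120, 80, 110, 90)
  m_mean <- merge_points(ab0, h, sph85, merge_radius = 1)
  expect_equal(nrow(m_mean), 1L)
  expect_equal(m_mean$h, 100)
  expect_equal(m_mean$repetitions, 5L)

  m_max <- merge_points(ab0, h, sph85, merge_radius = 1, merge_stat = "max")
  expect_equal(m_max$h, 120)

  # two points 10 mm apart stay unmerged at a 3 mm radius
  xy <- rbind(c(0, 0), c(10, 0))
  ab2 <- wrap_to_sphere(xy, sph85)
  m2 <- merge_points(ab2, c(50, 70), sph85, merge_radius = 3)
  expect_equal(nrow(m2), 2L)

  # repetition filtering drops sparse groups
  ab3 <- rbind(ab0, ab2)
  m3 <- merge_points(ab3, c(h, 50, 70), sph85, merge_radius = 1,
                     min_repetitions = 2)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$repetitions, 5L)
})

test_that("kernel surface matches the closed form and a brute-force oracle", {
  expect_equal(kernel_weight(0), 1)
  expect_equal(kernel_weight(2, a = 0.05, b = 2), 0.05)

  # single point: value at its own cell ~ h, exactly a*h at r = b
  poi <- build_poi(matrix(c(0, 0), 1), sph85, frame_z, margin = 7)
  grid <- build_grid(poi)
  merged1 <- structure(data.frame(alpha = 0, beta = 0, h = 100, repetitions = 1),
                       class = c("merged_points", "data.frame"))
  hts <- motormap:::kernel_field(merged1, grid)[grid$cells$idx]
  r <- geodesic_distance(cbind(grid$cells$alpha, grid$cells$beta), c(0, 0), sph85)
  expect_equal(hts, 100 * 0.05^(r^2 / 4), tolerance = 1e-9)

  # three points, random geometry: cellwise equality with max-over-points
  withr::with_seed(31, xy <- cbind(runif(3, -8, 8), runif(3, -8, 8)))
  ab <- wrap_to_sphere(xy, sph85)
  h3 <- c(120, 300, 80)
  poi3 <- build_poi(ab, sph85, frame_z, margin = 7)
  grid3 <- build_grid(poi3)
  merged3 <- structure(data.frame(alpha = ab[, 1], beta = ab[, 2], h = h3,
                                  repetitions = 1),
                       class = c("merged_points", "data.frame"))
  hts3 <- motormap:::kernel_field(merged3, grid3)[grid3$cells$idx]
  oracle <- apply(vapply(1:3, function(i) {
    ri <- geodesic_distance(cbind(grid3$cells$alpha, grid3$cells$beta),
                            ab[i, ], sph85)
    h3[i] * 0.05^(ri^2 / 4)
  }, numeric(nrow(grid3$cells))), 1, max)
  expect_equal(hts3, oracle, tolerance = 1e-9)

  # monotonicity: raising one input response never lowers any cell
  merged_up <- merged3
  merged_up$h[2] <- merged_up$h[2] + 50
  hts_up <- motormap:::kernel_field(merged_up, grid3)[grid3$cells$idx]
  expect_true(all(hts_up >= hts3 - 1e-12))
})

test_that("smooth surface interpolates exactly, decays to zero, and has no spurious dips", {
  # single point: max 100 at the point, zero at every cell >= 5 mm away
  poi1 <- build_poi(matrix(c(0, 0), 1), sph85, frame_z, margin = 7)
  grid1 <- build_grid(poi1)
  merged1 <- data.frame(alpha = 0, beta = 0, h = 100, repetitions = 1)
  z1 <- motormap:::smooth_field(merged1, grid1, 5)
  hts1 <- z1[grid1$cells$idx]
  expect_equal(max(hts1), 100, tolerance = 1e-4)
  r1 <- geodesic_distance(cbind(grid1$cells$alpha, grid1$cells$beta),
                          c(0, 0), sph85)
  expect_true(all(hts1[r1 >= 5] == 0))
  expect_true(all(hts1 >= 0))

  # equal plateau: cells well inside the data hull stay at the plateau and
  # agree with a thin-plate RBF reference on the same nodes
  ax <- seq(-12, 12, by = 3)
  gxy <- as.matrix(expand.grid(ax, ax))
  gxy <- gxy[sqrt(rowSums(gxy^2)) <= 12, ]
  ab <- wrap_to_sphere(gxy, sph85)
  poi <- build_poi(ab, sph85, frame_z, margin = 7)
  grid <- build_grid(poi)
  merged <- data.frame(alpha = ab[, 1], beta = ab[, 2], h = 100, repetitions = 1)
  z <- motormap:::smooth_field(merged, grid, 5)
  hts <- z[grid$cells$idx]
  rr <- sqrt(grid$cells$x^2 + grid$cells$y^2)
  interior <- rr <= 6   # two node spacings inside the outermost data ring
  expect_true(all(hts[interior] >= 99))

  ring <- t(vapply(seq(0, 2 * pi, length.out = 49)[-49],
                   function(t) 17 * c(cos(t), sin(t)), numeric(2)))
  rbf <- tps_interpolant(rbind(gxy, ring), c(rep(100, nrow(gxy)), rep(0, nrow(ring))))
  ref <- rbf(cbind(grid$cells$x, grid$cells$y)[interior, , drop = FALSE])
  expect_lt(max(abs(hts[interior] - ref)), 1.5)

  # interpolation contract on a random 30-point set (points separated by at
  # least the merge radius, as after spatial filtering)
  rxy <- withr::with_seed(32, {
    acc <- matrix(numeric(0), 0, 2)
    while (nrow(acc) < 30) {
      cand <- cbind(runif(1, -10, 10), runif(1, -10, 10))
      if (nrow(acc) == 0 ||
          min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) > 2)
        acc <- rbind(acc, cand)
    }
    acc
  })
  rh <- withr::with_seed(35, runif(30, 10, 500))
  rab <- wrap_to_sphere(rxy, sph85)
  rpoi <- build_poi(rab, sph85, frame_z, margin = 7)
  rgrid <- build_grid(rpoi)
  rmerged <- data.frame(alpha = rab[, 1], beta = rab[, 2], h = rh,
                        repetitions = 1)
  rz <- motormap:::smooth_field(rmerged, rgrid, 5)
  fitted <- as.numeric(motormap:::bilinear_weights(
    unwrap_to_plane(rab, sph85), rgrid) %*% rz)
  expect_lt(max(abs(fitted - rh)), 0.005 * max(rh))
  expect_true(all(rz >= 0))

  # duplicate locations with conflicting heights are rejected
  dup <- data.frame(alpha = c(0, 0), beta = c(0, 0), h = c(100, 200),
                    repetitions = 1)
  expect_error(motormap:::smooth_field(dup, grid1, 5), "inconsistent")
})

test_that("construct_map recovers a synthetic bump and is order/geometry stable", {
  gs <- quick_bump_session(seed = 7)
  m <- motor_map(gs$session, "APB")
  expect_s3_class(m, "motor_map")
  expect_lt(abs(max(m$heights) - 500) / 500, 0.05)

  # permutation of stimulation order leaves the map unchanged
  sess2 <- gs$session
  perm <- withr::with_seed(33, sample.int(nrow(sess2$points)))
  sess2$points <- sess2$points[perm, ]
  m2 <- motor_map(sess2, "APB")
  expect_equal(m2$heights, m$heights, tolerance = 1e-6)

  # an explicitly shared sphere reproduces the independent fit on same points
  sph_fit <- m$geometry$sphere
  m3 <- motor_map(gs$session, "APB", geometry = sph_fit)
  expect_equal(m3$heights, m$heights, tolerance = 1e-6)

  # all-zero responses give an identically zero map
  sess0 <- gs$session
  sess0$points$APB <- 0
  m0 <- motor_map(sess0, "APB")
  expect_true(all(m0$heights == 0))

  # unknown or empty channels error
  expect_error(motor_map(gs$session, "FDI"), "not present")
  sess_na <- gs$session
  sess_na$points$APB <- NA_real_
  expect_error(motor_map(sess_na, "APB"), "empty channel")
})

test_that("thresholding removes only subthreshold cells and nests monotonically", {
  gs <- quick_bump_session(seed = 9)
  m <- motor_map(gs$session, "APB")

  th_all <- threshold_map(m, 0)
  expect_equal(sum(th_all$active), sum(m$heights >= 0))

  th150 <- threshold_map(m, 1e5)
  expect_equal(sum(th150$active), 0L)
  expect_equal(map_area(th150), 0)

  th50 <- threshold_map(m, 50)
  th100 <- threshold_map(m, 100)
  expect_true(all(m$heights[th50$active] >= 50))
  expect_equal(m$heights[th50$active], th50$heights[th50$active])
  expect_true(all(which(th100$active) %in% which(th50$active)))
  expect_lte(map_area(th100), map_area(th50))
})
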