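test_that("sphere fit recovers exact spherical samples and is rigid-motion invariant", {
  pts <- sphere_samples(20, center = c(0, 0, 0), radius = 85, seed = 3)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(fit$radius, 85, tolerance = 1e-6)

  # rigid rotation + translation of the inputs moves the estimate rigidly
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(12, -30, 5)
  fit2 <- fit_sphere(sweep(pts %*% t(R), 2, shift, "+"))
  expect_equal(fit2$center, as.numeric(R %*% c(0, 0, 0)) + shift, tolerance = 1e-6)
  expect_equal(fit2$radius, 85, tolerance = 1e-6)
})

test_that("sphere fit under noise matches an independent NLS oracle within 0.5 mm", {
  pts <- sphere_samples(60, center = c(5, -8, 20), radius = 85, seed = 11)
  noisy <- pts + withr::with_seed(12, matrix(stats::rnorm(length(pts), 0, 0.5),
                                             ncol = 3))
  fit <- fit_sphere(noisy)
  oracle <- oracle_fit_sphere(noisy)
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 0.05)
  expect_lt(abs(fit$radius - oracle$radius), 0.05)
  expect_lt(sqrt(sum((fit$center - c(5, -8, 20))^2)), 0.5)
  expect_lt(abs(fit$radius - 85), 0.5)
})

test_that("degenerate configurations are rejected", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), "at least 4")
  coplanar <- cbind(matrix(runif(20), ncol = 2), 0)
  coplanar <- cbind(coplanar[, 1], coplanar[, 2], 0)
  expect_error(fit_sphere(coplanar), "coplanar")
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_sphere(collinear), "coplanar|collinear")
})

test_that("radial projection lands on the sphere along the original ray", {
  sph <- sphere(c(1, 2, 3), 70)
  withr::with_seed(4, {
    p <- sweep(matrix(rnorm(30, sd = 40), ncol = 3), 2, sph$center + c(0, 0, 60), "+")
  })
  frame <- patch_frame(c(0, 0, 1))
  ab <- project_point(p, sph, frame = frame)
  q <- angular_to_world(ab, sph, frame)
  expect_equal(sqrt(rowSums(sweep(q, 2, sph$center)^2)), rep(70, nrow(q)),
               tolerance = 1e-9)
  # q parallel to p - center
  rel_p <- sweep(p, 2, sph$center)
  rel_q <- sweep(q, 2, sph$center)
  cosang <- rowSums(rel_p * rel_q) /
    sqrt(rowSums(rel_p^2) * rowSums(rel_q^2))
  expect_equal(cosang, rep(1, nrow(p)), tolerance = 1e-12)

  # a point already on the sphere projects to itself
  on_sph <- sph$center + 70 * normalize_rows(matrix(c(0.1, 0.2, 1), 1))
  ab1 <- project_point(on_sph, sph, frame = frame)
  expect_equal(angular_to_world(ab1, sph, frame), on_sph, tolerance = 1e-9)

  # axis case: point above the patch center maps to the angular origin
  sph0 <- sphere(c(0, 0, 0), 100)
  ab0 <- project_point(matrix(c(0, 0, 250), 1), sph0, frame = frame)
  expect_equal(as.numeric(ab0), c(0, 0), tolerance = 1e-12)
  expect_error(project_point(matrix(sph$center, 1), sph, frame = frame),
               "undefined projection")
})

test_that("geodesic distance matches the dot-product closed form and is a metric", {
  sph <- sphere(c(0, 0, 0), 100)
  expect_equal(geodesic_distance(c(0.3, -0.2), c(0.3, -0.2), sph), 0)
  withr::with_seed(5, {
    ab1 <- cbind(runif(50, -1, 1), runif(50, -1, 1))
    ab2 <- cbind(runif(50, -1, 1), runif(50, -1, 1))
    ab3 <- cbind(runif(50, -1, 1), runif(50, -1, 1))
  })
  d12 <- geodesic_distance(ab1, ab2, sph)
  u <- angular_to_direction(ab1)
  v <- angular_to_direction(ab2)
  expect_equal(d12, 100 * acos(pmin(1, pmax(-1, rowSums(u * v)))),
               tolerance = 1e-9)
  # metric axioms
  expect_true(all(d12 >= 0))
  expect_equal(d12, geodesic_distance(ab2, ab1, sph), tolerance = 1e-12)
  d13 <- geodesic_distance(ab1, ab3, sph)
  d23 <- geodesic_distance(ab2, ab3, sph)
  expect_true(all(d12 + d23 >= d13 - 1e-9))
})

test_that("unwrap matches the printed closed forms", {
  sph <- sphere(c(0, 0, 0), 100)
  expect_equal(as.numeric(unwrap_to_plane(c(0, 0), sph)), c(0, 0))

  # alpha = pi/6, beta = 0: radial distance R*pi/6 on the alpha axis
  xy <- unwrap_to_plane(c(pi / 6, 0), sph)
  expect_equal(as.numeric(xy), c(100 * pi / 6, 0), tolerance = 1e-9)

  # alpha = beta = pi/4: k = R*arccos(1/sqrt(3)), theta = pi/4
  k_printed <- function(a, b, R) {
    R * acos(cos(a) * cos(b) / sqrt(1 - sin(a)^2 * sin(b)^2))
  }
  xy2 <- unwrap_to_plane(c(pi / 4, pi / 4), sph)
  k <- k_printed(pi / 4, pi / 4, 100)
  expect_equal(k, 100 * acos(1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(as.numeric(xy2), c(k * cos(pi / 4), k * sin(pi / 4)),
               tolerance = 1e-9)

  # the radial closed form holds everywhere
  withr::with_seed(6, ab <- cbind(runif(200, -1.2, 1.2), runif(200, -1.2, 1.2)))
  xy <- unwrap_to_plane(ab, sph)
  expect_equal(sqrt(rowSums(xy^2)), k_printed(ab[, 1], ab[, 2], 100),
               tolerance = 1e-9)
})

test_that("wrap is the exact inverse of unwrap on the open hemisphere", {
  sph <- sphere(c(4, 4, 4), 85)
  expect_equal(as.numeric(wrap_to_sphere(c(0, 0), sph)), c(0, 0))
  withr::with_seed(7, ab <- cbind(runif(1000, -1.2, 1.2), runif(1000, -1.2, 1.2)))
  rt <- wrap_to_sphere(unwrap_to_plane(ab, sph), sph)
  expect_lt(max(abs(rt - ab)), 1e-9)

  # inverse of the printed example
  ab2 <- wrap_to_sphere(85 * acos(1 / sqrt(3)) * c(cos(pi / 4), sin(pi / 4)), sph)
  expect_equal(as.numeric(ab2), c(pi / 4, pi / 4), tolerance = 1e-9)

  expect_error(wrap_to_sphere(c(85 * pi / 2, 0), sph), "hemisphere")
})

test_that("unwrap preserves geodesic distance from the patch center exactly", {
  sph <- sphere(c(0, 0, 0), 85)
  withr::with_seed(8, ab <- cbind(runif(300, -1.2, 1.2), runif(300, -1.2, 1.2)))
  xy <- unwrap_to_plane(ab, sph)
  d_center <- geodesic_distance(ab, c(0, 0), sph)
  expect_equal(sqrt(rowSums(xy^2)), d_center, tolerance = 1e-9 * 85)
})

test_that("antipodal-limit geodesic equals pi*R", {
  sph <- sphere(c(0, 0, 0), 100)
  u <- angular_to_direction(c(0.4, -0.3))
  d <- motormap:::geodesic_cross(u, -u, 100)
  expect_equal(as.numeric(d), 100 * pi, tolerance = 1e-6)
})
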