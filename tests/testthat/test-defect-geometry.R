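test_that("the direct ellipse fit is exact on noise-free contours", {
  pts <- ellipse_points(3, -2, 5, 2.5, 25)
  fit <- fit_ellipse(pts)
  expect_equal(fit$center, c(3, -2), tolerance = 1e-8)
  expect_equal(fit$semi_major, 5, tolerance = 1e-8)
  expect_equal(fit$semi_minor, 2.5, tolerance = 1e-8)
  expect_equal(fit$angle, 25, tolerance = 1e-6)

  expect_error(fit_ellipse(pts[1:4, ]), "at least 5")
  line <- cbind(1:6, 2 * (1:6) + 1)
  expect_error(fit_ellipse(line), "degenerate|ellipse")
})

test_that("the ellipse fit is robust to point noise", {
  # 100 seeded trials at 0.2 nm point noise on a 5 x 2.5 nm defect
  set.seed(77)
  res <- t(replicate(100, {
    pts <- ellipse_points(0, 0, 5, 2.5, 10, n = 32)
    pts <- pts + matrix(rnorm(length(pts), 0, 0.2), ncol = 2)
    f <- fit_ellipse(pts)
    c(f$semi_major, f$semi_minor)
  }))
  expect_lt(abs(mean(res[, 1]) - 5) / 5, 0.05)
  expect_lt(abs(mean(res[, 2]) - 2.5) / 2.5, 0.05)
})

test_that("the ellipse fit is equivariant under rigid motions", {
  pts <- ellipse_points(1, 2, 4, 1.5, 20, n = 40)
  f0 <- fit_ellipse(pts)
  set.seed(11)
  for (k in 1:5) {
    ang <- runif(1, -80, 80)
    shift <- runif(2, -50, 50)
    th <- ang * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- sweep(pts %*% t(R), 2, -shift)
    f1 <- fit_ellipse(moved)
    expect_equal(f1$center, drop(R %*% f0$center) + shift, tolerance = 1e-6)
    expect_equal(f1$semi_major, f0$semi_major, tolerance = 1e-6)
    d_ang <- (f1$angle - (f0$angle + ang) + 90) %% 180 - 90
    expect_lt(abs(d_ang), 1e-4)
  }
})

test_that("population summaries aggregate fits and contours", {
  # single fit: sd flagged NA
  f <- fit_ellipse(ellipse_points(0, 0, 5, 2.5, 0))
  s1 <- population_summary(list(f))
  expect_equal(s1$semi_major_mean, 5, tolerance = 1e-8)
  expect_true(is.na(s1$semi_major_sd))

  # mirror-image pair: mean orientation zero
  fits <- list(fit_ellipse(ellipse_points(0, 0, 5, 2.5, 18)),
               fit_ellipse(ellipse_points(0, 0, 5, 2.5, -18)))
  expect_equal(population_summary(fits)$angle_mean, 0, tolerance = 1e-6)

  # mean contour of identical ellipses equals the single-contour profile
  # exactly, and tracks the analytic polar radius of the ellipse
  pts <- ellipse_points(2, 1, 5, 2.5, 0, n = 64)
  fits3 <- lapply(1:4, function(i) fit_ellipse(pts))
  s3 <- population_summary(fits3, contours = rep(list(pts), 4), n_angles = 64)
  s_one <- population_summary(fits3[1], contours = list(pts), n_angles = 64)
  expect_equal(s3$mean_profile$radius, s_one$mean_profile$radius, tolerance = 1e-12)
  phi <- s3$mean_profile$angle * pi / 180
  r_true <- 5 * 2.5 / sqrt((2.5 * cos(phi))^2 + (5 * sin(phi))^2)
  expect_equal(s3$mean_profile$radius, r_true, tolerance = 5e-3)

  # a generated population recovers the nominal 10 x 5 nm defect geometry
  fld <- generate_defect_field(field_spec(domain = c(200, 200)), seed = 21)
  fits4 <- lapply(fld$contours[1:200], fit_ellipse)
  s4 <- population_summary(fits4)
  expect_equal(s4$semi_major_mean, 5, tolerance = 0.05)
  expect_equal(s4$semi_minor_mean, 2.5, tolerance = 0.05)
})

test_that("nearest-neighbour spacing on lattices and point processes", {
  # square lattice of pitch 32
  g <- expand.grid(x = seq(0, 320, 32), y = seq(0, 320, 32))
  nn <- nearest_neighbor_spacing(as.matrix(g))
  expect_equal(nn$mean, 32, tolerance = 1e-12)
  expect_equal(nn$sd, 0)

  # scale equivariance
  nn3 <- nearest_neighbor_spacing(3 * as.matrix(g))
  expect_equal(nn3$mean, 3 * nn$mean, tolerance = 1e-12)

  # 2D Poisson process: mean nearest-neighbour distance ~ 0.5/sqrt(rho)
  set.seed(5)
  side <- 450
  n <- 2025  # rho = 0.01
  pts <- cbind(runif(n, 0, side), runif(n, 0, side))
  d_all <- nearest_neighbor_spacing(pts)
  inner <- pts[, 1] > 15 & pts[, 1] < side - 15 & pts[, 2] > 15 & pts[, 2] < side - 15
  d_inner <- mean(attr(d_all, "distances")$all[inner])
  expect_equal(d_inner, 0.5 / sqrt(n / side^2), tolerance = 0.05)

  expect_error(nearest_neighbor_spacing(matrix(c(1, 2), ncol = 2)), "at least two")

  # edge-to-edge option subtracts the defect radii
  two <- rbind(c(0, 0), c(10, 0))
  nn_e <- nearest_neighbor_spacing(two, method = "edge", radii = c(2, 3))
  expect_equal(nn_e$mean, 5, tolerance = 1e-12)
})

test_that("orientation profiles recover a programmed tilt law", {
  # uniform zero tilt: flat profile at zero
  set.seed(3)
  pts <- cbind(runif(300, 0, 300), runif(300, 0, 300))
  bnd <- cbind(c(0, 0), c(0, 300))
  p0 <- orientation_profile(pts, theta = rep(0, 300), boundary = bnd)
  expect_true(all(p0$profile$mean_theta == 0))

  # exponential decay law recovered within binning error
  d <- pts[, 1]
  theta <- 35 * exp(-d / 50)
  p1 <- orientation_profile(pts, theta = theta, boundary = bnd, bin_width = 10)
  pred <- 35 * exp(-p1$profile$distance / 50)
  big <- p1$profile$n >= 5 & pred > 1
  expect_lt(max(abs(p1$profile$mean_theta[big] - pred[big]) / pred[big]), 0.25)
  expect_lt(p1$rho, -0.9)  # monotone decay away from the boundary

  expect_error(orientation_profile(pts, theta = theta), "boundary")
})

test_that("density classing splits a two-density field", {
  set.seed(9)
  dense <- cbind(runif(200, 0, 50), runif(200, 0, 100))
  sparse <- cbind(runif(200, 150, 500), runif(200, 0, 100))
  cls <- classify_density(rbind(dense, sparse), radius = 25)
  expect_true(mean(cls[1:200] == "high") > 0.9)
  expect_true(mean(cls[201:400] == "low") > 0.9)
})
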