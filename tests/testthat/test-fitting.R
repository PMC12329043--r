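test_that("plane fits recover exact and noisy planes", {
  set.seed(51)
  X <- cbind(runif(200, -5, 5), runif(200, -5, 5), 2)
  f <- fit_plane(X)
  expect_equal(abs(f$normal[3]), 1, tolerance = 1e-12)
  expect_equal(f$offset * sign(f$normal[3]), 2, tolerance = 1e-12)
  expect_lt(f$std, 1e-12)

  # Gaussian z-noise: std recovered (population convention)
  n <- 1e5
  Z <- cbind(runif(n, -5, 5), runif(n, -5, 5), rnorm(n, sd = 0.005))
  fn <- fit_plane(Z)
  expect_equal(fn$std, 0.005, tolerance = 0.04)

  expect_error(fit_plane(cbind(1:3, 2 * (1:3), 3 * (1:3))), "collinear")
  expect_error(fit_plane(X[1:2, ]), "at least 3")
})

test_that("sphere fits recover exact spheres, caps and fixed radii", {
  set.seed(53)
  P <- matrix(rnorm(900), 300, 3)
  P <- P / sqrt(rowSums(P^2))
  S <- sweep(P * 2.5, 2, c(1, 2, 3), "+")
  f <- fit_sphere(S)
  expect_equal(f$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(f$radius, 2.5, tolerance = 1e-9)
  expect_lt(f$std, 1e-9)

  # 60-degree cap with isotropic noise, free radius
  n <- 1e4
  z <- runif(n, cos(pi / 3), 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cap <- cbind(r * cos(phi), r * sin(phi), z) * 2.5
  cap <- cap + matrix(rnorm(3 * n, sd = 0.01 / sqrt(3)), n, 3)
  fc <- fit_sphere(cap)
  expect_equal(fc$radius, 2.5, tolerance = 0.01 * 2.5)
  # residual std ~ injected radial noise component
  expect_equal(fc$std, 0.01 / sqrt(3), tolerance = 0.1)

  # fixed radius on exact data: same centre, zero std
  ff <- fit_sphere(S, fixed_radius = 2.5)
  expect_true(ff$radius_fixed)
  expect_equal(ff$center, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(ff$std, 1e-9)

  # coplanar points cannot constrain a free radius
  flat <- cbind(runif(50), runif(50), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("score filtering is exact and monotone", {
  cl <- point_cloud(1:3, 1:3, 1:3, score = c(0.95, 0.85, 0.91))
  expect_identical(filter_by_score(cl, -1), cl)
  kept <- filter_by_score(cl, 0.9)
  expect_equal(kept$x, c(1, 3))
  set.seed(59)
  for (i in 1:20) {
    cl <- point_cloud(rnorm(50), rnorm(50), rnorm(50),
                      score = runif(50, -1, 1))
    expect_lte(nrow(filter_by_score(cl, 0.9)),
               nrow(filter_by_score(cl, 0.3)))
  }
})

test_that("central patch keeps the stated area fraction of a uniform disc", {
  set.seed(61)
  n <- 2e4
  r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  cl <- point_cloud(r * cos(phi), r * sin(phi), rnorm(n, sd = 0.01))
  expect_identical(nrow(central_patch(cl, fraction = 1)), as.integer(n))
  kept <- central_patch(cl, fraction = 0.485)
  expect_equal(nrow(kept), ceiling(0.485 * n))
  rmax <- sqrt(max(kept$x^2 + kept$y^2))
  expect_equal(rmax, sqrt(0.485), tolerance = 0.02)
  expect_error(central_patch(cl[0, ], fraction = 0.5), "empty")
})

test_that("residual statistics report population std and conserving histograms", {
  f <- structure(list(model = "plane", residuals = c(-1, 1),
                      std = 1, n = 2), class = "shape_fit")
  rs <- residual_stats(f, bin_width = 5)
  expect_equal(rs$std, 1)
  expect_equal(sum(rs$histogram$count), 2)

  set.seed(67)
  res <- rnorm(1e5, sd = 0.00446)
  f2 <- structure(list(model = "plane", residuals = res,
                       std = sqrt(mean(res^2)), n = 1e5),
                  class = "shape_fit")
  expect_equal(f2$std, 0.00446, tolerance = 3e-5 / 0.00446)
  rs2 <- residual_stats(f2)
  expect_equal(sum(rs2$histogram$count), 1e5)
  expect_equal(rs2$histogram$bin_right[1] - rs2$histogram$bin_left[1],
               f2$std / 10, tolerance = 1e-12)
})

test_that("polyline lengths follow Euclidean geometry and projection shortening", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 0))
  expect_equal(polyline_length(square), 4)
  expect_error(polyline_length(rbind(c(0, 0, 0))), "at least 2")
  # an orthogonal projection of a curve is never longer than the curve
  set.seed(71)
  for (i in 1:25) {
    V <- apply(matrix(rnorm(30), 10, 3), 2, cumsum)
    P <- V
    P[, 3] <- 0                      # project onto z = 0
    expect_lte(polyline_length(P), polyline_length(V) + 1e-12)
  }
})

test_that("fit statistics are rigid-invariant and scale-equivariant", {
  set.seed(73)
  P <- matrix(rnorm(600), 200, 3)
  P <- P / sqrt(rowSums(P^2))
  S <- P * 2.5 + matrix(rnorm(600, sd = 0.01), 200, 3)
  f0 <- fit_sphere(S)
  Rr <- random_rotation(); tr <- rnorm(3)
  f1 <- fit_sphere(sweep(S %*% t(Rr), 2, tr, "+"))
  expect_lt(abs(f1$std - f0$std), 1e-9)
  p0 <- fit_plane(S[, ] * c(1, 1, 0.01))   # flattened cloud as plane data
  p1 <- fit_plane(sweep((S * c(1, 1, 0.01)) %*% t(Rr), 2, tr, "+"))
  expect_lt(abs(p1$std - p0$std), 1e-9)
  # exact scale equivariance
  s <- 3.25
  f2 <- fit_sphere(S * s)
  expect_equal(f2$std, s * f0$std, tolerance = 1e-9)
  expect_equal(polyline_length(S[1:10, ] * s),
               s * polyline_length(S[1:10, ]), tolerance = 1e-12)
})

test_that("central-patch residuals beat the full cap on noisy spheres", {
  # measurement error grows with the surface slope against the viewing
  # direction (pattern foreshortening degrades the correlation peak), so the
  # central patch shows a smaller residual spread — for every seed
  for (seed in 1:20) {
    set.seed(seed)
    n <- 3000
    z <- runif(n, cos(70 * pi / 180), 1)
    phi <- runif(n, 0, 2 * pi)
    rr <- sqrt(1 - z^2)
    S <- cbind(rr * cos(phi), rr * sin(phi), z) * 2.5
    # slope-dependent depth noise: sd ~ 1/cos^2(slope). Projected on the
    # local normal (factor cos), the residual spread still grows with
    # slope, the empirical error law of correlation-based reconstruction
    S[, 3] <- S[, 3] + rnorm(n, sd = 0.01 / z^2)
    cl <- point_cloud(S[, 1], S[, 2], S[, 3])
    full <- fit_sphere(cl)
    cen <- fit_sphere(central_patch(cl, viewing_axis = c(0, 0, 1),
                                    fraction = 0.5))
    expect_lte(cen$std, full$std)
  }
})

test_that("crop box removes fixture points", {
  cl <- point_cloud(c(0, 1, 2), c(0, 0, 0), c(-3, 0.2, 0.1))
  kept <- crop_box(cl, zlim = c(-1, 1))
  expect_equal(kept$x, c(1, 2))
  kept2 <- crop_box(cl, xlim = c(0.5, 2.5), zlim = c(-1, 1))
  expect_equal(nrow(kept2), 2L)
})

test_that("tidy, glance and autoplot summarise fits", {
  set.seed(79)
  P <- matrix(rnorm(300), 100, 3); P <- P / sqrt(rowSums(P^2))
  f <- fit_sphere(sweep(P * 2, 2, c(0, 0, 1), "+"))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "radius"], 2, tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$model, "sphere")
  expect_equal(gl$radius_mm, 2, tolerance = 1e-6)
  pl <- autoplot(f)
  expect_s3_class(pl, "ggplot")
  cl <- point_cloud(P[, 1], P[, 2], P[, 3], score = runif(100))
  expect_s3_class(autoplot(cl, colour = "score"), "ggplot")
})
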