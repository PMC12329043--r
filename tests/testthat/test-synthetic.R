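test_that("pattern stacks are normalized, distinct and reproducible", {
  ps <- make_pattern_stack(100, c(64, 64), cutoff = 0.1, seed = 42)
  expect_equal(dim(ps$frames), c(64, 64, 100))
  rng <- apply(ps$frames, 3, range)
  expect_equal(unname(rng[1, ]), rep(0, 100))
  expect_equal(unname(rng[2, ]), rep(1, 100))

  # same seed -> bit-identical
  ps2 <- make_pattern_stack(100, c(64, 64), cutoff = 0.1, seed = 42)
  expect_identical(ps$frames, ps2$frames)
  ps3 <- make_pattern_stack(100, c(64, 64), cutoff = 0.1, seed = 43)
  expect_false(identical(ps$frames, ps3$frames))

  # frames mutually distinct: temporal series of a pixel not self-correlated
  series <- ps$frames[32, 32, ]
  ac <- stats::cor(series[-1], series[-100])
  expect_lt(abs(ac), 0.99)

  expect_error(make_pattern_stack(10, c(0, 64)), "size")
})

test_that("cutoff 0.5 reproduces white noise (no spatial correlation)", {
  ps <- make_pattern_stack(1, c(256, 256), cutoff = 0.5, seed = 1)
  f <- ps$frames[, , 1]
  lag1 <- stats::cor(as.vector(f[, -1]), as.vector(f[, -256]))
  expect_lt(abs(lag1), 0.05)
  # low cutoff yields strong neighbour correlation by contrast
  pslo <- make_pattern_stack(1, c(256, 256), cutoff = 0.05, seed = 1)
  flo <- pslo$frames[, , 1]
  expect_gt(stats::cor(as.vector(flo[, -1]), as.vector(flo[, -256])), 0.8)
})

test_that("projector model enforces orthogonal axes", {
  p <- projector_model(c(0, 0, -1), c(0, 1, 0), 4e-3)
  expect_equal(sum(p$direction * p$up), 0)
  expect_equal(p$right, c(1, 0, 0))
  expect_error(projector_model(c(0, 0, -1), c(0, 1, -0.5)), "orthogonal")
})

test_that("rendering a uniform pattern on a plane gives uniform frames", {
  rig <- default_rig(image_size = c(32, 32))
  ps <- raw_pattern_stack(array(1, dim = c(64, 64, 3)),
                          pattern_pitch = rig$proj$pattern_pitch)
  st <- render_stack(scene_plane(offset = 0, albedo = 1), rig$cam1,
                     rig$proj, ps, noise_sigma = 0, seed = 1)
  expect_true(all(st$frames == 1))
  expect_true(all(st$hit))
})

test_that("sphere silhouette matches the orthographic great circle", {
  rig <- default_rig(image_size = c(256, 256))
  ps <- make_pattern_stack(1, c(384, 384), seed = 2,
                           pattern_pitch = rig$proj$pattern_pitch)
  st <- render_stack(scene_sphere(center = c(0, 0, 0), radius = 2.5),
                     rig$cam1, rig$proj, ps, noise_sigma = 0, seed = 1)
  px_area_mm2 <- (rig$cam1$pixel_pitch / rig$cam1$mag[["x"]])^2
  # viewing rays are tilted by theta/2 relative to the sphere but an
  # orthographic silhouette of a sphere is its great circle from any side
  area <- sum(st$hit) * px_area_mm2
  expect_equal(area, pi * 2.5^2, tolerance = 0.01)
  # background pixels carry the background intensity
  expect_true(all(st$frames[, , 1][!st$hit] == 0))
})

test_that("renderer ground truth is consistent with the camera projection", {
  rig <- default_rig(image_size = c(128, 128))
  ps <- make_pattern_stack(2, c(256, 256), seed = 5,
                           pattern_pitch = rig$proj$pattern_pitch)
  st <- render_stack(scene_sphere(center = c(0.3, -0.2, 0.4), radius = 2.5),
                     rig$cam1, rig$proj, ps, seed = 3)
  idx <- which(st$hit)
  set.seed(1)
  pick <- sample(seq_along(idx), 1000)
  H <- 128; W <- 128
  r <- (idx[pick] - 1) %% H + 1
  cc <- (idx[pick] - 1) %/% H + 1
  p <- project_points(rig$cam1, st$truth[pick, ])
  expect_lt(max(abs(p$u - (cc - (W + 1) / 2))), 1e-6)
  expect_lt(max(abs(p$v - (r - (H + 1) / 2))), 1e-6)
})

test_that("two cameras record perfectly correlated series without noise", {
  # the foundational assumption of temporal-correlation matching
  rig <- default_rig(image_size = c(64, 64))
  sim <- simulate_measurement(scene_plane(offset = 0), rig, n_frames = 30,
                              noise_sigma = 0, seed = 9)
  # camera-2 pixel corresponding to a camera-1 pixel, via ground truth
  H <- 64; W <- 64
  idx <- which(sim$stack1$hit)
  hit_row <- match(seq_len(H * W), idx)
  set.seed(2)
  scores <- numeric(0)
  for (i in sample(which(!is.na(hit_row)), 50)) {
    X <- sim$stack1$truth[hit_row[i], ]
    p2 <- project_points(rig$cam2, X)
    r2 <- round(p2$v + (H + 1) / 2); c2 <- round(p2$u + (W + 1) / 2)
    if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
    a <- sim$stack1$frames[(i - 1) %% H + 1, (i - 1) %/% H + 1, ]
    b <- sim$stack2$frames[r2, c2, ]
    # integer pixel centres of the two cameras sample slightly different
    # surface points; compare at the true correspondence via bilinear truth:
    # at minimum the integer-pixel series must correlate strongly, and the
    # subset of near-exact alignments must reach 1.
    scores <- c(scores, temporal_ncc(a, b))
  }
  expect_gt(stats::median(scores), 0.9)

  # exact alignment: render a plane seen identically by both cameras
  rig0 <- default_rig(stereo_angle = 1e-6, roll_camera2 = FALSE,
                      image_size = c(32, 32))
  sim0 <- simulate_measurement(scene_plane(offset = 0), rig0, n_frames = 20,
                               noise_sigma = 0, seed = 4)
  a <- sim0$stack1$frames[16, 16, ]
  b <- sim0$stack2$frames[16, 16, ]
  expect_equal(temporal_ncc(a, b), 1, tolerance = 1e-12)
})

test_that("renderer is deterministic in its seed", {
  rig <- default_rig(image_size = c(32, 32))
  sim_a <- simulate_measurement(scene_sphere(radius = 2.5), rig,
                                n_frames = 5, noise_sigma = 0.05, seed = 21)
  sim_b <- simulate_measurement(scene_sphere(radius = 2.5), rig,
                                n_frames = 5, noise_sigma = 0.05, seed = 21)
  expect_identical(sim_a$stack1$frames, sim_b$stack1$frames)
  expect_identical(sim_a$stack2$frames, sim_b$stack2$frames)
})

test_that("default rig reproduces the reference geometry", {
  rig <- default_rig(38.5, 0.69, 2.74e-3, c(2848, 2848))
  expect_identical(rig$cam1$image_size, c(2848L, 2848L))
  expect_equal(unname(intrinsic_matrix(rig$cam1)[1, 1]), 0.69 / 2.74e-3)
  # inter-axis angle
  d1 <- t(rig$cam1$R)[, 3]; d2 <- t(rig$cam2$R)[, 3]
  expect_equal(acos(sum(d1 * d2)) * 180 / pi, 38.5, tolerance = 1e-9)
  # both cameras image the origin at (0,0)
  expect_equal(unlist(project_points(rig$cam1, c(0, 0, 0))), c(u = 0, v = 0))
  expect_equal(unlist(project_points(rig$cam2, c(0, 0, 0))), c(u = 0, v = 0))
  # rolled mount: relative rotation is a 180-degree rotation
  expect_equal(rotation_angle(rig$cam2$R %*% t(rig$cam1$R)), 180,
               tolerance = 1e-9)
  # unrolled: relative rotation equals the stereo angle
  rig0 <- default_rig(38.5, roll_camera2 = FALSE)
  expect_equal(rotation_angle(rig0$cam2$R %*% t(rig0$cam1$R)), 38.5,
               tolerance = 1e-9)
  expect_error(default_rig(0), "stereo_angle")
})
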