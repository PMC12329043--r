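# Shared fixtures: rigs, analytic correspondences, small linear-algebra helpers.

skew3 <- function(t) {
  matrix(c(0, -t[3], t[2], t[3], 0, -t[1], -t[2], t[1], 0), 3, 3,
         byrow = TRUE)
}

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 180))
}

# A paper-like rig with arbitrary world orientation: stereo angle `theta`
# (deg), camera 2 rolled 180 deg about its axis plus a small mount
# perturbation (deg). Translations optional.
paper_like_rig <- function(theta, world = diag(3), perturb = 0,
                           t1 = c(0, 0, 0), t2 = c(0, 0, 0),
                           mag = 0.69, pitch = 0.0305,
                           image_size = c(256L, 256L)) {
  R1 <- rotation_about_axis(c(0, 1, 0), -theta / 2) %*% world
  R2 <- rotation_about_axis(c(0, 0, 1), 180) %*%
    rotation_about_axis(c(0, 1, 0), theta / 2) %*% world
  if (perturb > 0) {
    R2 <- rotation_about_axis(stats::rnorm(3),
                              stats::runif(1, 0, perturb)) %*% R2
  }
  list(cam1 = telecentric_camera(mag, mag, pitch, R = R1, t = t1,
                                 image_size = image_size),
       cam2 = telecentric_camera(mag, mag, pitch, R = R2, t = t2,
                                 image_size = image_size))
}

# Physically induced baseline direction of a rig whose cameras sit at
# working distances d1, d2 along their own axes: t ~ d2 e3 - d1 R e3.
physical_baseline <- function(Rrel, d1 = 1, d2 = 1) {
  tt <- d2 * c(0, 0, 1) - d1 * as.vector(Rrel %*% c(0, 0, 1))
  tt / sqrt(sum(tt^2))
}

# Points on the spherical cap of `radius` facing camera 1.
sphere_cap_points <- function(cam1, n = 400, radius = 2.5,
                              center = c(0.2, -0.3, 0.1), min_facing = 0.35) {
  P <- matrix(stats::rnorm(3 * n), n, 3)
  P <- P / sqrt(rowSums(P^2))
  d1w <- t(cam1$R)[, 3]
  P <- P[(P %*% d1w) < -min_facing, , drop = FALSE]
  sweep(P * radius, 2, center, "+")
}

# Noise-free analytic correspondences of world points X.
analytic_pairs <- function(cam1, cam2, X) {
  p1 <- project_points(cam1, X)
  p2 <- project_points(cam2, X)
  tibble::tibble(u1 = p1$u, v1 = p1$v, u2 = p2$u, v2 = p2$v, score = 1)
}

# Build a pattern_stack object directly from a frames array (for controlled
# matcher inputs).
raw_pattern_stack <- function(frames, pattern_pitch = 4e-3) {
  structure(list(frames = frames, pattern_pitch = pattern_pitch, seed = 0L),
            class = "pattern_stack")
}

# Build an image_stack object directly from a frames array.
raw_image_stack <- function(frames, camera_id = "cam") {
  structure(list(frames = frames, n_frames = dim(frames)[3],
                 camera_id = camera_id),
            class = "image_stack")
}

# Shift a stack by integer pixels: out(row, col) = in(row - dv, col - du),
# filling uncovered borders with white noise so shifted content remains
# matchable in the interior.
shift_stack <- function(frames, du, dv, fill_seed = 99L) {
  d <- dim(frames)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(fill_seed)
  out <- array(stats::runif(prod(d)), dim = d)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  src_r <- seq_len(d[1]) - dv
  src_c <- seq_len(d[2]) - du
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c, ] <- frames[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  out
}

# Bilinear subpixel shift of each frame (constant shift), interior-valid.
shift_stack_subpixel <- function(frames, du, dv) {
  d <- dim(frames)
  r0 <- floor(dv); c0 <- floor(du)
  fr <- dv - r0; fc <- du - c0
  out <- frames
  rows <- seq_len(d[1]); cols <- seq_len(d[2])
  sr <- rows - r0; sc <- cols - c0
  ok_r <- sr >= 2 & sr <= d[1]; ok_c <- sc >= 2 & sc <= d[2]
  for (k in seq_len(d[3])) {
    f <- frames[, , k]
    g <- matrix(0.5, d[1], d[2])
    g[ok_r, ok_c] <-
      (1 - fr) * (1 - fc) * f[sr[ok_r], sc[ok_c]] +
      (1 - fr) * fc       * f[sr[ok_r], sc[ok_c] - 1] +
      fr       * (1 - fc) * f[sr[ok_r] - 1, sc[ok_c]] +
      fr       * fc       * f[sr[ok_r] - 1, sc[ok_c] - 1]
    out[, , k] <- g
  }
  out
}
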