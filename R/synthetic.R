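#' Band-limited pseudo-random illumination patterns
#'
#' Generates the temporal sequence of structured-illumination patterns the
#' projector displays: each frame is white noise low-pass filtered in the
#' frequency domain and affinely rescaled to `[0, 1]`. Band-limited noise is
#' a canonical choice for temporal-correlation stereo; the cutoff controls
#' the spatial feature size (lower cutoff = smoother, broader speckles).
#'
#' The low-pass mask is separable (`max(|fx|, |fy|) <= cutoff` in cycles/px),
#' so `cutoff = 0.5` reproduces unfiltered white noise exactly.
#'
#' @param n_frames Number of frames (the reference rig uses 100).
#' @param size `c(H, W)` pattern size in pattern pixels.
#' @param cutoff Low-pass cutoff in cycles/px, in `(0, 0.5]`.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param pattern_pitch Physical size of one pattern pixel on the projection
#'   plane, mm/px.
#' @return A `pattern_stack` object: list with `frames`
#'   (H x W x n_frames array in `[0, 1]`), `pattern_pitch` and `seed`.
#' @export
make_pattern_stack <- function(n_frames, size = c(256L, 256L), cutoff = 0.1,
                               seed = 1L, pattern_pitch = 4e-3) {
  stopifnot(n_frames >= 1, length(size) == 2, all(size >= 1),
            cutoff > 0, cutoff <= 0.5, pattern_pitch > 0)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fy <- fft_freq(H); fx <- fft_freq(W)
  mask <- outer(abs(fy) <= cutoff, abs(fx) <= cutoff, "&")
  frames <- array(0, dim = c(H, W, n_frames))
  for (k in seq_len(n_frames)) {
    z <- matrix(stats::rnorm(H * W), H, W)
    if (!all(mask)) {
      z <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / (H * W)
    }
    rng <- range(z)
    frames[, , k] <- if (rng[2] > rng[1]) (z - rng[1]) / (rng[2] - rng[1]) else 0.5
  }
  structure(list(frames = frames, pattern_pitch = pattern_pitch,
                 seed = as.integer(seed)),
            class = "pattern_stack")
}

fft_freq <- function(n) {
  # frequency (cycles per sample) of each DFT bin
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k[seq_len(n)] / n
}

#' Parallel projector model
#'
#' The structured-illumination projector is modeled as a parallel projector:
#' a pattern plane through the world origin, spanned by
#' `right = direction x up` and `up`, projected along `direction`. This keeps
#' the pattern value seen at a surface point analytic (it depends only on the
#' point's position across the projection axis), which is what a heavily
#' stopped-down projection lens approximates.
#'
#' @param direction Unit projection axis (default `-z`).
#' @param up Unit up-vector of the pattern plane, orthogonal to `direction`.
#' @param pattern_pitch Pattern pixel size on the projection plane, mm/px.
#' @return A `projector` object.
#' @export
projector_model <- function(direction = c(0, 0, -1), up = c(0, 1, 0),
                            pattern_pitch = 4e-3) {
  direction <- direction / sqrt(sum(direction^2))
  up <- up / sqrt(sum(up^2))
  if (abs(sum(direction * up)) > 1e-10) {
    stop("projector 'direction' and 'up' must be orthogonal")
  }
  right <- c(direction[2] * up[3] - direction[3] * up[2],
             direction[3] * up[1] - direction[1] * up[3],
             direction[1] * up[2] - direction[2] * up[1])
  structure(list(direction = direction, up = up, right = right,
                 pattern_pitch = pattern_pitch),
            class = "projector")
}

#' Analytic scene descriptions
#'
#' Scenes are single analytic surfaces with an albedo map, measured front-on:
#' * `scene_plane()`: plane `normal . X = offset`, optional i.i.d. Gaussian
#'   height roughness (mm) emulating a reference plane of sub-micrometre
#'   flatness when `roughness_sigma` is small.
#' * `scene_sphere()`: sphere of given centre and radius (the reference
#'   artefacts are resin / metrology spheres of radius 2.5 and 5 mm).
#' * `scene_grid_plane()`: plane `z = offset` carrying a square grid of
#'   bright circular dots (albedo `albedo_bright`) on a dark background
#'   (`albedo_dark`), emulating a calibration plate with circles at known
#'   spacing used to establish metric scale.
#'
#' @param normal Plane normal (world frame).
#' @param offset Plane offset: the plane is `normal . X = offset` (mm).
#' @param roughness_sigma Gaussian height roughness, mm.
#' @param albedo Constant surface albedo in `[0, 1]`.
#' @param center Sphere centre (mm).
#' @param radius Sphere radius (mm), > 0.
#' @param spacing Dot-grid spacing (mm), > 0.
#' @param line_width Dot diameter (mm).
#' @param albedo_bright,albedo_dark Albedo of dots and background.
#' @param background Image intensity where no surface is hit, in `[0, 1]`.
#' @return A `scene` object.
#' @export
scene_plane <- function(normal = c(0, 0, 1), offset = 0, roughness_sigma = 0,
                        albedo = 1, background = 0) {
  stopifnot(roughness_sigma >= 0)
  normal <- normal / sqrt(sum(normal^2))
  structure(list(type = "plane", normal = normal, offset = offset,
                 roughness_sigma = roughness_sigma, albedo = albedo,
                 background = background),
            class = "scene")
}

#' @rdname scene_plane
#' @export
scene_sphere <- function(center = c(0, 0, 0), radius = 2.5, albedo = 1,
                         background = 0) {
  stopifnot(radius > 0, length(center) == 3)
  structure(list(type = "sphere", center = as.numeric(center), radius = radius,
                 albedo = albedo, background = background),
            class = "scene")
}

#' @rdname scene_plane
#' @export
scene_grid_plane <- function(spacing = 1, line_width = 0.3, offset = 0,
                             albedo_bright = 0.9, albedo_dark = 0.05,
                             background = 0) {
  stopifnot(spacing > 0, line_width > 0, line_width < spacing)
  structure(list(type = "grid_plane", normal = c(0, 0, 1), offset = offset,
                 spacing = spacing, line_width = line_width,
                 albedo_bright = albedo_bright, albedo_dark = albedo_dark,
                 roughness_sigma = 0, background = background),
            class = "scene")
}

#' Render a structured-illumination image stack
#'
#' Simulates the acquisition: for every pixel the camera viewing ray is
#' intersected with the analytic surface (nearest intersection along the
#' viewing direction); the surface point is projected along the projector
#' axis onto the pattern plane, the pattern is sampled bilinearly, and the
#' recorded intensity is `albedo x pattern + noise`, clipped to `[0, 1]`.
#' Rays that miss the surface (or leave the pattern) record the scene
#' background plus noise. The per-pixel hit mask and true 3D intersection
#' points are returned as ground truth.
#'
#' Single convex surfaces viewed front-on are assumed: no cast shadows or
#' inter-reflections (occlusion is ray miss only), matching single-view
#' measurements of near-convex objects.
#'
#' @param scene A `scene` object.
#' @param cam A [telecentric_camera()].
#' @param proj A [projector_model()].
#' @param patterns A [make_pattern_stack()].
#' @param noise_sigma Gaussian intensity noise (image units).
#' @param seed Integer seed for noise and surface roughness.
#' @param camera_id Label stored with the stack.
#' @return An `image_stack`: list with `frames` (H x W x n_frames), `hit`
#'   (H x W logical), `truth` (n_hit x 3 matrix of true surface points, mm,
#'   rows aligned with `which(hit)`), `camera_id`, and the generating camera.
#' @export
render_stack <- function(scene, cam, proj, patterns, noise_sigma = 0,
                         seed = 1L, camera_id = "cam") {
  stopifnot(inherits(scene, "scene"), inherits(cam, "telecam"),
            inherits(proj, "projector"), inherits(patterns, "pattern_stack"),
            noise_sigma >= 0)
  W <- cam$image_size[1]; H <- cam$image_size[2]
  n_frames <- dim(patterns$frames)[3]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # viewing rays for the full pixel grid (column-major pixel order)
  uv <- cbind(u = rep(seq_len(W) - (W + 1) / 2, each = H),
              v = rep(seq_len(H) - (H + 1) / 2, times = W))
  rays <- backproject_ray(cam, uv)
  hitres <- intersect_scene(scene, rays$origin, rays$direction)
  hit <- hitres$hit
  X <- hitres$points           # n_hit x 3
  albedo <- hitres$albedo

  # pattern-plane coordinates of the hit points (parallel projection)
  Hp <- dim(patterns$frames)[1]; Wp <- dim(patterns$frames)[2]
  if (abs(sum(proj$direction * scene_normal_hint(scene))) < 1e-12) {
    stop("degenerate projector: direction is parallel to the surface plane")
  }
  pc <- X %*% proj$right / patterns$pattern_pitch + (Wp + 1) / 2
  pr <- X %*% proj$up / patterns$pattern_pitch + (Hp + 1) / 2
  bl <- bilinear_weights(pr, pc, Hp, Wp)   # handles out-of-pattern -> NA

  frames <- array(scene$background, dim = c(H, W, n_frames))
  idx_hit <- which(hit)
  for (k in seq_len(n_frames)) {
    pk <- patterns$frames[, , k]
    val <- bilinear_apply(bl, pk)
    val[is.na(val)] <- scene$background   # outside the pattern -> background
    fr <- rep(scene$background, H * W)
    fr[idx_hit] <- albedo * val
    if (noise_sigma > 0) {
      fr <- fr + stats::rnorm(H * W, sd = noise_sigma)
      fr <- pmin(1, pmax(0, fr))
    }
    frames[, , k] <- fr
  }
  structure(list(frames = frames,
                 hit = matrix(hit, H, W),
                 truth = X,
                 camera_id = camera_id,
                 camera = cam,
                 n_frames = n_frames),
            class = "image_stack")
}

scene_normal_hint <- function(scene) {
  if (scene$type %in% c("plane", "grid_plane")) scene$normal else c(0, 0, 1)
}

# Intersect parallel rays with the analytic surface. Returns hit mask,
# hit points (rows for hits only) and per-hit albedo.
intersect_scene <- function(scene, origin, direction) {
  n <- nrow(origin)
  if (scene$type %in% c("plane", "grid_plane")) {
    nd <- sum(scene$normal * direction)
    if (abs(nd) < 1e-12) stop("viewing direction parallel to scene plane")
    lam <- (scene$offset - origin %*% scene$normal) / nd
    X <- origin + as.vector(lam) %o% direction
    if (scene$roughness_sigma > 0) {
      X <- X + stats::rnorm(n, sd = scene$roughness_sigma) %o% scene$normal
    }
    hit <- rep(TRUE, n)
    albedo <- scene_albedo(scene, X)
    list(hit = hit, points = X, albedo = albedo)
  } else if (scene$type == "sphere") {
    oc <- sweep(origin, 2, scene$center)
    b <- as.vector(oc %*% direction)              # |direction| = 1
    cc <- rowSums(oc^2) - scene$radius^2
    disc <- b^2 - cc
    hit <- disc >= 0
    lam <- -b[hit] - sqrt(disc[hit])              # nearest along the ray
    X <- origin[hit, , drop = FALSE] + lam %o% direction
    list(hit = hit, points = X,
         albedo = rep(scene$albedo, sum(hit)))
  } else {
    stop("unknown scene type: ", scene$type)
  }
}

scene_albedo <- function(scene, X) {
  if (scene$type == "plane") {
    rep(scene$albedo, nrow(X))
  } else {
    # grid of circular dots: bright within line_width/2 of the nearest node
    gx <- X[, 1] / scene$spacing
    gy <- X[, 2] / scene$spacing
    dx <- (gx - round(gx)) * scene$spacing
    dy <- (gy - round(gy)) * scene$spacing
    ifelse(dx^2 + dy^2 <= (scene$line_width / 2)^2,
           scene$albedo_bright, scene$albedo_dark)
  }
}

# Bilinear sampling helpers: weights fixed once per geometry, reused per frame.
bilinear_weights <- function(r, c, H, W) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
  idx00 <- (c0 - 1) * H + r0
  list(ok = ok, H = H,
       i00 = idx00[ok], i10 = idx00[ok] + 1,
       i01 = idx00[ok] + H, i11 = idx00[ok] + H + 1,
       w00 = ((1 - fr) * (1 - fc))[ok], w10 = (fr * (1 - fc))[ok],
       w01 = ((1 - fr) * fc)[ok], w11 = (fr * fc)[ok],
       n = length(r))
}

bilinear_apply <- function(bl, img) {
  out <- rep(NA_real_, bl$n)
  out[bl$ok] <- bl$w00 * img[bl$i00] + bl$w10 * img[bl$i10] +
    bl$w01 * img[bl$i01] + bl$w11 * img[bl$i11]
  out
}

#' Default desk-scale stereo rig
#'
#' Builds the reference measurement geometry: two telecentric cameras whose
#' optical axes intersect at the world origin, symmetric about the `z` axis
#' with the stated inter-axis (stereo) angle, and a parallel projector along
#' `-z`. Both cameras image the origin at pixel `(0, 0)`.
#'
#' By default camera 2 is mounted rolled 180 degrees about its own optical
#' axis (`roll_camera2 = TRUE`), as physical rigs commonly are; the relative
#' rotation is then `Rz(180) Ry(theta)`, far from the identity — the
#' configuration in which the deviation-from-identity disambiguation rule of
#' thumb holds. Set `roll_camera2 = FALSE` for an unrolled symmetric mount.
#'
#' @param stereo_angle Inter-axis angle in degrees, in `(0, 180)`.
#'   The reference rig uses approximately 38.5.
#' @param mag Magnification of both lenses (default 0.69).
#' @param pixel_pitch Pixel pitch, mm. The default scales the reference
#'   sensor's 2.74 um pitch by `2848 / image_size[1]`, i.e. the sensor is
#'   binned so that the 11.3 mm field of view of the reference instrument is
#'   preserved at any synthetic resolution. Pass `2.74e-3` explicitly with
#'   `image_size = c(2848, 2848)` for the full-resolution physical rig.
#' @param image_size `c(width, height)` px. The physical cameras are
#'   2848 x 2848; the synthetic default 256 x 256 keeps a full pipeline run
#'   in minutes, and all geometric parameters are scale-free.
#' @param roll_camera2 Roll camera 2 by 180 degrees about its optical axis.
#' @param pattern_pitch Projector pattern pitch, mm/px; defaults to the
#'   camera's object-space pixel footprint `pixel_pitch / mag`.
#' @return A list with `cam1`, `cam2`, `proj`.
#' @examples
#' rig <- default_rig()
#' rotation_angle(rig$cam2$R %*% t(rig$cam1$R))  # 180-roll mount
#' @export
default_rig <- function(stereo_angle = 38.5, mag = 0.69,
                        pixel_pitch = 2.74e-3 * 2848 / image_size[1],
                        image_size = c(256L, 256L),
                        roll_camera2 = TRUE, pattern_pitch = pixel_pitch / mag) {
  stopifnot(stereo_angle > 0, stereo_angle < 180)
  half <- stereo_angle / 2
  R1 <- rotation_about_axis(c(0, 1, 0), -half)
  R2 <- rotation_about_axis(c(0, 1, 0), half)
  if (roll_camera2) {
    R2 <- rotation_about_axis(c(0, 0, 1), 180) %*% R2
  }
  cam1 <- telecentric_camera(mag, mag, pixel_pitch, R = R1,
                             image_size = image_size)
  cam2 <- telecentric_camera(mag, mag, pixel_pitch, R = R2,
                             image_size = image_size)
  proj <- projector_model(direction = c(0, 0, -1), up = c(0, 1, 0),
                          pattern_pitch = pattern_pitch)
  list(cam1 = cam1, cam2 = cam2, proj = proj)
}

# Save/restore .Random.seed so generator functions with a `seed` argument do
# not disturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
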