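#' Telecentric (affine) camera model
#'
#' A telecentric lens images the scene by parallel projection: chief rays are
#' parallel to the optical axis, so magnification is independent of object
#' depth. The intrinsic matrix is diagonal, \eqn{K = diag(M_x/pp, M_y/pp, 1)},
#' where `M` is the (dimensionless) magnification and `pp` the pixel pitch.
#' There is no principal-point term; pixel coordinates are therefore taken
#' relative to the image centre, `u` rightward (columns), `v` downward (rows).
#'
#' All lengths are millimetres. Intrinsic entries printed in px/m (as camera
#' data sheets do) must be converted to px/mm on input (`M/pp` with `pp` in
#' mm gives px/mm directly).
#'
#' @param mag_x,mag_y Dimensionless magnifications along image x and y.
#'   `mag_y` defaults to `mag_x` (isotropic optics).
#' @param pixel_pitch Sensor pixel pitch in mm/px.
#' @param R 3x3 rotation matrix, world to camera frame.
#' @param t Length-3 translation in mm, world to camera frame.
#' @param image_size Integer `c(width, height)` in pixels.
#' @return An object of class `telecam`.
#' @examples
#' cam <- telecentric_camera(0.69, pixel_pitch = 2.74e-3)
#' intrinsic_matrix(cam)
#' @export
telecentric_camera <- function(mag_x, mag_y = mag_x, pixel_pitch,
                               R = diag(3), t = c(0, 0, 0),
                               image_size = c(256L, 256L)) {
  stopifnot(is.numeric(mag_x), length(mag_x) == 1, mag_x > 0,
            is.numeric(mag_y), length(mag_y) == 1, mag_y > 0,
            is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0,
            length(t) == 3, length(image_size) == 2)
  R <- as.matrix(R)
  if (!is_rotation(R)) {
    stop("'R' must be an orthonormal rotation matrix with determinant +1")
  }
  structure(
    list(mag = c(x = mag_x, y = mag_y),
         pixel_pitch = pixel_pitch,
         R = R, t = as.numeric(t),
         image_size = as.integer(image_size)),
    class = "telecam"
  )
}

#' @export
print.telecam <- function(x, ...) {
  cat(sprintf("<telecentric camera  %d x %d px,  M = (%.4g, %.4g),  pp = %.4g mm>\n",
              x$image_size[1], x$image_size[2], x$mag["x"], x$mag["y"],
              x$pixel_pitch))
  cat(sprintf("  scale: %.6g px/mm (x), %.6g px/mm (y)\n",
              x$mag["x"] / x$pixel_pitch, x$mag["y"] / x$pixel_pitch))
  invisible(x)
}

#' Intrinsic matrix of a telecentric camera
#'
#' Returns the diagonal affine intrinsic matrix in px/mm:
#' `diag(M_x/pp, M_y/pp, 1)`. Off-diagonal entries are exactly zero — a
#' telecentric model has neither shear nor principal-point offset.
#'
#' @param cam A [telecentric_camera()].
#' @return A 3x3 matrix.
#' @export
intrinsic_matrix <- function(cam) {
  stopifnot(inherits(cam, "telecam"))
  diag(c(cam$mag[["x"]] / cam$pixel_pitch,
         cam$mag[["y"]] / cam$pixel_pitch, 1))
}

#' Project world points through a telecentric camera
#'
#' Applies the affine imaging model: with `x_cam = R X + t`,
#' `u = (M_x/pp) x_cam_1` and `v = (M_y/pp) x_cam_2`. The result does not
#' depend on `x_cam_3`: depth along the optical axis is invisible to a
#' telecentric lens.
#'
#' @param cam A [telecentric_camera()].
#' @param points Length-3 vector, n x 3 matrix, or data frame with columns
#'   `x`, `y`, `z` (mm, world frame).
#' @return A tibble with columns `u`, `v` (px, centred coordinates).
#' @export
project_points <- function(cam, points) {
  stopifnot(inherits(cam, "telecam"))
  X <- as_xyz_matrix(points)
  xc <- X %*% t(cam$R)
  kx <- cam$mag[["x"]] / cam$pixel_pitch
  ky <- cam$mag[["y"]] / cam$pixel_pitch
  tibble::tibble(u = kx * (xc[, 1] + cam$t[1]),
                 v = ky * (xc[, 2] + cam$t[2]))
}

#' Back-project pixels to parallel viewing rays
#'
#' The viewing rays of a telecentric camera are parallel: their common
#' direction is the world-frame optical axis `R' (0,0,1)`, and the meeting
#' point of the rays lies at infinity. For pixel `(u, v)` the ray origin is
#' chosen so that projecting it returns `(u, v)` exactly.
#'
#' @param cam A [telecentric_camera()].
#' @param uv Length-2 vector, n x 2 matrix, or data frame with columns
#'   `u`, `v` (px).
#' @return A list with `origin` (n x 3 matrix, mm) and `direction`
#'   (unit 3-vector shared by all rays).
#' @export
backproject_ray <- function(cam, uv) {
  stopifnot(inherits(cam, "telecam"))
  P <- as_uv_matrix(uv)
  kx <- cam$mag[["x"]] / cam$pixel_pitch
  ky <- cam$mag[["y"]] / cam$pixel_pitch
  n <- nrow(P)
  cam_pts <- cbind(P[, 1] / kx - cam$t[1],
                   P[, 2] / ky - cam$t[2],
                   rep(-cam$t[3], n))
  list(origin = cam_pts %*% cam$R,   # = t(R) applied row-wise
       direction = as.vector(t(cam$R) %*% c(0, 0, 1)))
}

#' Triangulate correspondence pairs from two telecentric cameras
#'
#' Intersects the back-projected rays of each pixel pair. Because the two
#' rays generally do not meet exactly, the midpoint of their common
#' perpendicular is returned together with the minimum ray-to-ray distance
#' (`gap`), a per-point quality diagnostic.
#'
#' @param cam1,cam2 [telecentric_camera()] objects.
#' @param p1,p2 Pixel coordinates in camera 1 / camera 2: length-2 vectors,
#'   n x 2 matrices, or data frames with columns `u`, `v`.
#' @return A tibble with columns `x`, `y`, `z` (mm) and `gap` (mm).
#' @export
triangulate_pairs <- function(cam1, cam2, p1, p2) {
  stopifnot(inherits(cam1, "telecam"), inherits(cam2, "telecam"))
  r1 <- backproject_ray(cam1, p1)
  r2 <- backproject_ray(cam2, p2)
  stopifnot(nrow(r1$origin) == nrow(r2$origin))
  d1 <- r1$direction
  d2 <- r2$direction
  b <- sum(d1 * d2)
  if (abs(b) > 1 - 1e-12) {
    stop("degenerate geometry: viewing directions are parallel")
  }
  w0 <- r1$origin - r2$origin
  w_d1 <- as.vector(w0 %*% d1)
  w_d2 <- as.vector(w0 %*% d2)
  denom <- 1 - b^2
  s1 <- (b * w_d2 - w_d1) / denom
  s2 <- (w_d2 - b * w_d1) / denom
  P1 <- r1$origin + s1 %o% d1
  P2 <- r2$origin + s2 %o% d2
  X <- (P1 + P2) / 2
  tibble::tibble(x = X[, 1], y = X[, 2], z = X[, 3],
                 gap = sqrt(rowSums((P1 - P2)^2)))
}

# ---- rotation utilities -----------------------------------------------------

#' Test for a proper rotation matrix
#'
#' @param R A 3x3 matrix.
#' @param tol Orthonormality tolerance on the Frobenius norm of `R'R - I`.
#' @return `TRUE` if `R` is orthonormal with determinant +1.
#' @export
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    norm(t(R) %*% R - diag(3), "F") < tol && det(R) > 0
}

#' Rotation about an axis
#'
#' Rodrigues' formula. Angle in degrees by default, following the package
#' convention that all user-facing angles are degrees.
#'
#' @param axis Length-3 axis (need not be unit length).
#' @param angle Rotation angle.
#' @param degrees Interpret `angle` in degrees (default) or radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle, degrees = TRUE) {
  if (degrees) angle <- angle * pi / 180
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-300) return(diag(3))
  a <- axis / nrm
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

#' Rotation angle of a rotation matrix
#'
#' @param R A 3x3 rotation matrix.
#' @param degrees Return degrees (default) or radians.
#' @return The rotation angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(R, degrees = TRUE) {
  ct <- (sum(diag(R)) - 1) / 2
  a <- acos(pmin(1, pmax(-1, ct)))
  if (degrees) a * 180 / pi else a
}

#' Angular distance between two rotations
#'
#' Two-view geometry under parallel projection determines the relative
#' rotation only up to the mirror (Necker) equivalence
#' `R ~ Dz R Dz`, `Dz = diag(1, 1, -1)`: both members reconstruct congruent
#' (possibly reflected) geometry. With `mod_mirror = TRUE` the distance is
#' minimised over that equivalence class.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @param mod_mirror Minimise over the mirror equivalence class of `R2`.
#' @param degrees Return degrees (default) or radians.
#' @return Angular distance.
#' @export
rotation_distance <- function(R1, R2, mod_mirror = FALSE, degrees = TRUE) {
  d <- rotation_angle(R1 %*% t(R2), degrees = degrees)
  if (mod_mirror) {
    Dz <- diag(c(1, 1, -1))
    d <- min(d, rotation_angle(R1 %*% t(Dz %*% R2 %*% Dz), degrees = degrees))
  }
  d
}

# ---- camera serialization ---------------------------------------------------

#' Read or write telecentric camera configurations (YAML)
#'
#' The on-disk format is `{mag_x, mag_y, pixel_pitch_mm, R (row-major, 9
#' floats), t_mm (3 floats), width, height}`.
#'
#' @param cam A [telecentric_camera()].
#' @param path File path.
#' @return `read_camera()` returns a `telecam`; `write_camera()` returns
#'   `path` invisibly.
#' @export
write_camera <- function(cam, path) {
  stopifnot(inherits(cam, "telecam"))
  yaml::write_yaml(camera_to_list(cam), path, precision = 15L)
  invisible(path)
}

#' @rdname write_camera
#' @export
read_camera <- function(path) {
  camera_from_list(yaml::read_yaml(path))
}

camera_to_list <- function(cam) {
  list(mag_x = unname(cam$mag[["x"]]), mag_y = unname(cam$mag[["y"]]),
       pixel_pitch_mm = cam$pixel_pitch,
       R = as.numeric(t(cam$R)), t_mm = cam$t,
       width = cam$image_size[1], height = cam$image_size[2])
}

camera_from_list <- function(x) {
  R <- matrix(as.numeric(x$R), 3, 3, byrow = TRUE)
  # polish away serialization rounding; reject anything genuinely non-rigid
  if (!is_rotation(R) && is_rotation(R, tol = 1e-5)) {
    s <- svd(R)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) stop("stored camera rotation has negative determinant")
  }
  telecentric_camera(
    mag_x = x$mag_x, mag_y = x$mag_y, pixel_pitch = x$pixel_pitch_mm,
    R = R, t = as.numeric(x$t_mm),
    image_size = c(x$width, x$height)
  )
}

# ---- internal coercion helpers ----------------------------------------------

as_xyz_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- cbind(points$x, points$y, points$z)
  } else if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, 1, 3)
  }
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  points
}

as_uv_matrix <- function(uv) {
  if (is.data.frame(uv)) {
    stopifnot(all(c("u", "v") %in% names(uv)))
    uv <- cbind(uv$u, uv$v)
  } else if (is.null(dim(uv))) {
    stopifnot(length(uv) == 2)
    uv <- matrix(uv, 1, 2)
  }
  storage.mode(uv) <- "double"
  stopifnot(ncol(uv) == 2, all(is.finite(uv)))
  uv
}
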