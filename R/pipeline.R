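#' Simulate a structured-illumination stereo measurement
#'
#' Renders the same pattern sequence onto the scene as seen by both cameras
#' of a rig — the synthetic stand-in for a physical acquisition, with full
#' ground truth.
#'
#' @param scene A `scene` object.
#' @param rig A list with `cam1`, `cam2`, `proj` (see [default_rig()]).
#' @param n_frames Number of patterns (default 100, the reference sequence
#'   length).
#' @param noise_sigma Gaussian intensity noise.
#' @param seed Integer seed driving patterns and noise.
#' @param cutoff Pattern band-limit, cycles/px.
#' @param pattern_size Pattern resolution `c(H, W)`; defaults to generously
#'   cover the camera footprint.
#' @return A list with `stack1`, `stack2` (`image_stack`s), `patterns`,
#'   `rig`, `seed`, `noise_sigma`.
#' @export
simulate_measurement <- function(scene, rig = default_rig(), n_frames = 100L,
                                 noise_sigma = 0, seed = 1L, cutoff = 0.1,
                                 pattern_size = NULL) {
  if (is.null(pattern_size)) {
    # pattern plane must cover the camera footprint seen under the stereo tilt
    side <- max(rig$cam1$image_size) * rig$cam1$pixel_pitch /
      min(rig$cam1$mag) / rig$proj$pattern_pitch
    side <- as.integer(ceiling(side * 1.6))
    pattern_size <- c(side, side)
  }
  patterns <- make_pattern_stack(n_frames, pattern_size, cutoff = cutoff,
                                 seed = seed,
                                 pattern_pitch = rig$proj$pattern_pitch)
  stack1 <- render_stack(scene, rig$cam1, rig$proj, patterns,
                         noise_sigma = noise_sigma, seed = seed + 1L,
                         camera_id = "cam1")
  stack2 <- render_stack(scene, rig$cam2, rig$proj, patterns,
                         noise_sigma = noise_sigma, seed = seed + 2L,
                         camera_id = "cam2")
  list(stack1 = stack1, stack2 = stack2, patterns = patterns, rig = rig,
       seed = as.integer(seed), noise_sigma = noise_sigma)
}

#' Calibrate stereo extrinsics from image stacks
#'
#' Runs the extrinsic calibration chain on a measured (or simulated) pair of
#' stacks: coarse full-search temporal-correlation matching, affine
#' fundamental-matrix estimation, pinhole-style candidate enumeration, and
#' both disambiguation routes — the deviation-from-identity rule of thumb
#' and the decisive reference-shape selection.
#'
#' @param stack1,stack2 `image_stack`s.
#' @param cam1,cam2 The rig cameras (intrinsics and image size).
#' @param reference `"sphere"` or `"plane"` — the shape of the measured
#'   calibration object.
#' @param fixed_radius Optional fixed reference-sphere radius (mm).
#' @param stride Matching stride for the coarse calibration search.
#' @param min_score Correlation threshold for calibration pairs.
#' @param refine Refine over the affine-consistent rotation family
#'   (recommended; see [select_by_reference()]).
#' @return A `stereo_calibration` list: `F`, `candidates`, `identity_rule`
#'   (result or the error message if ambiguous), `selection` (reference
#'   result), `R`, `t_unit`, `pairs`, `K1`, `K2`.
#' @export
calibrate_stereo <- function(stack1, stack2, cam1, cam2,
                             reference = "sphere", fixed_radius = NULL,
                             stride = 4L, min_score = 0.7, refine = TRUE,
                             trim_rounds = 2L) {
  pairs <- find_correspondences(stack1, stack2, search = "full",
                                min_score = min_score, stride = stride)
  if (nrow(pairs) < 10) stop("calibration found too few correspondences")
  F <- estimate_affine_fundamental(pairs)
  # trimmed refit: drop epipolar outliers (mismatches that survived the
  # correlation threshold) and re-estimate
  for (i in seq_len(trim_rounds)) {
    res <- abs(rowSums((cbind(pairs$u2, pairs$v2, 1) %*% F$F) *
                         cbind(pairs$u1, pairs$v1, 1)))
    keep <- res <= 3 * stats::median(res) + 1e-12
    if (sum(keep) < 10 || all(keep)) break
    pairs <- pairs[keep, , drop = FALSE]
    F <- estimate_affine_fundamental(pairs)
  }
  cands <- candidate_extrinsics(F, cam1, cam2)
  sel <- select_by_reference(cands, pairs, cam1, cam2,
                             reference = reference,
                             fixed_radius = fixed_radius, refine = refine)
  # identity rule of thumb on the raw decomposition pair (reported for
  # audit; the reference selection is authoritative)
  idr <- tryCatch(select_by_identity_rule(cands),
                  error = function(e) conditionMessage(e))
  structure(list(F = F, candidates = cands, identity_rule = idr,
                 selection = sel, R = sel$R, t_unit = sel$t_unit,
                 pairs = pairs,
                 K1 = intrinsic_matrix(cam1), K2 = intrinsic_matrix(cam2)),
            class = "stereo_calibration")
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat("<stereo calibration>\n")
  print(x$candidates)
  if (is.character(x$identity_rule)) {
    cat("  identity rule: ambiguous (", x$identity_rule, ")\n", sep = "")
  } else {
    cat(sprintf("  identity rule picks %s (margin %.4f)\n",
                x$identity_rule$which, x$identity_rule$margin))
  }
  cat(sprintf("  reference selection: std %.4g mm\n", x$selection$std))
  print(signif(x$R, 6))
  invisible(x)
}

#' Densely reconstruct a point cloud from calibrated stacks
#'
#' Epipolar-band temporal-correlation matching at the given stride,
#' followed by telecentric triangulation with camera 1 at the canonical
#' pose. The reconstruction lives in camera-1 coordinates; its metric scale
#' is nominal until fixed with [estimate_scale()] / [rescale_cloud()].
#'
#' @param stack1,stack2 `image_stack`s.
#' @param cam1,cam2 Rig cameras.
#' @param calibration A `stereo_calibration` (or list with `F`, `R`,
#'   `t_unit`).
#' @param stride Matching stride.
#' @param min_score Correlation threshold (0.3 for difficult scattering
#'   surfaces, 0.9 for cooperative ones).
#' @param half_width Epipolar band half-width, px.
#' @return A `pointcloud` tibble with `x, y, z, score, gap`.
#' @export
reconstruct_cloud <- function(stack1, stack2, cam1, cam2, calibration,
                              stride = 2L, min_score = 0.3, half_width = 2) {
  pairs <- find_correspondences(stack1, stack2, search = "epipolar_band",
                                F = calibration$F, half_width = half_width,
                                min_score = min_score, stride = stride)
  if (nrow(pairs) == 0) return(point_cloud(numeric(), numeric(), numeric()))
  cam1c <- canonical_camera(cam1)
  cam2c <- camera_with_pose(cam2, calibration$R, calibration$t_unit)
  X <- triangulate_pairs(cam1c, cam2c,
                         cbind(pairs$u1, pairs$v1), cbind(pairs$u2, pairs$v2))
  point_cloud(X$x, X$y, X$z, score = pairs$score, gap = X$gap)
}

#' Validate a point cloud against a reference shape
#'
#' Applies the correlation filter, optionally a crop box and central-patch
#' selection, fits the model, and assembles a JSON-serializable report.
#'
#' @param cloud A `pointcloud` tibble.
#' @param model `"plane"` or `"sphere"`.
#' @param min_score Correlation threshold applied first (if a `score`
#'   column exists).
#' @param fixed_radius Optional fixed sphere radius (mm).
#' @param fraction Optional central-patch fraction in `(0, 1]`.
#' @param viewing_axis Axis for [central_patch()].
#' @param crop Optional list with `xlim`, `ylim`, `zlim` for [crop_box()].
#' @return A list with the `shape_fit`, the filtered cloud, and `report`
#'   (model, parameters in mm, std in mm, n, threshold used).
#' @export
validate_cloud <- function(cloud, model = c("plane", "sphere"),
                           min_score = NULL, fixed_radius = NULL,
                           fraction = NULL, viewing_axis = c(0, 0, 1),
                           crop = NULL) {
  model <- match.arg(model)
  used <- cloud
  if (!is.null(min_score) && "score" %in% names(used)) {
    used <- filter_by_score(used, min_score)
  }
  if (!is.null(crop)) {
    used <- crop_box(used, crop$xlim, crop$ylim, crop$zlim)
  }
  if (!is.null(fraction) && fraction < 1) {
    used <- central_patch(used, viewing_axis, fraction)
  }
  fit <- if (model == "plane") {
    fit_plane(used)
  } else {
    fit_sphere(used, fixed_radius = fixed_radius)
  }
  params <- if (model == "plane") {
    list(normal = fit$normal, offset_mm = fit$offset)
  } else {
    list(center_mm = fit$center, radius_mm = fit$radius,
         radius_fixed = fit$radius_fixed)
  }
  list(fit = fit, cloud = used,
       report = list(model = model, params_mm = params,
                     std_mm = fit$std, std_um = fit$std * 1e3,
                     n = fit$n, threshold_used = min_score,
                     fraction_used = fraction))
}

#' Write a validation report as JSON
#'
#' @param report The `report` entry of [validate_cloud()] (or any list).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
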