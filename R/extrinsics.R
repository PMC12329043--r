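#' Estimate the affine fundamental matrix from correspondences
#'
#' For parallel-projection (telecentric) cameras the fundamental matrix has
#' the affine form with a zero upper-left 2x2 block, and the Gold-Standard
#' estimate is linear: after Hartley-style centring and isotropic scaling of
#' both images' coordinates, the unit vector `(a, b, c, d)` minimizing
#' `sum (a u2 + b v2 + c u1 + d v1)^2` in the total-least-squares sense is
#' the smallest right singular direction of the centred n x 4 coordinate
#' matrix; the constant term is recovered from the centroids. The result is
#' normalized to unit Frobenius norm, with the convention `x2' F x1 = 0`,
#' `x = (u, v, 1)` in centred pixel coordinates.
#'
#' @param pairs Correspondence tibble with columns `u1, v1, u2, v2`
#'   (>= 4 non-degenerate rows).
#' @return An `affine_fundamental` object: list with `F` (3x3, `||F|| = 1`),
#'   `n_pairs`, and `residual_rms` (RMS algebraic residual `|x2' F x1|`).
#' @export
estimate_affine_fundamental <- function(pairs) {
  stopifnot(all(c("u1", "v1", "u2", "v2") %in% names(pairs)))
  M <- cbind(pairs$u2, pairs$v2, pairs$u1, pairs$v1)
  if (nrow(M) < 4) stop("need at least 4 correspondence pairs")
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  s2 <- sqrt(mean(Mc[, 1]^2 + Mc[, 2]^2)) # image-2 RMS radius
  s1 <- sqrt(mean(Mc[, 3]^2 + Mc[, 4]^2))
  if (s1 < 1e-12 || s2 < 1e-12) stop("degenerate correspondences: zero spread")
  Mn <- Mc %*% diag(1 / c(s2, s2, s1, s1))
  sv <- svd(Mn)
  if (sv$d[3] < 1e-10 * sv$d[1]) {
    stop("degenerate correspondences: points collinear / on one epipolar line")
  }
  w <- sv$v[, 4]
  a <- w[1] / s2; b <- w[2] / s2; cc <- w[3] / s1; d <- w[4] / s1
  e <- -(a * mu[1] + b * mu[2] + cc * mu[3] + d * mu[4])
  Fm <- matrix(0, 3, 3)
  Fm[1, 3] <- a; Fm[2, 3] <- b
  Fm[3, 1] <- cc; Fm[3, 2] <- d; Fm[3, 3] <- e
  Fm <- Fm / norm(Fm, "F")
  res <- rowSums((cbind(pairs$u2, pairs$v2, 1) %*% Fm) *
                   cbind(pairs$u1, pairs$v1, 1))
  structure(list(F = Fm, n_pairs = nrow(M),
                 residual_rms = sqrt(mean(res^2))),
            class = "affine_fundamental")
}

#' @export
print.affine_fundamental <- function(x, ...) {
  cat(sprintf("<affine fundamental matrix, %d pairs, RMS residual %.3g>\n",
              x$n_pairs, x$residual_rms))
  print(signif(x$F, 6))
  invisible(x)
}

#' Enumerate candidate extrinsics from the fundamental matrix
#'
#' Reproduces what pinhole-model standard libraries emit when applied to a
#' telecentric system: forms `E = K2' F K1`, projects it onto the essential
#' manifold (equal nonzero singular values) and decomposes by the standard
#' two-rotation construction, yielding exactly two rotations `R_a`, `R_b`
#' and a sign-ambiguous unit translation. Because the data obey parallel
#' projection while the decomposition assumes a pinhole, the discrete set
#' generally contains a near-identity rotation (the re-projection in the
#' first camera view) and its 180-degree twin — the model mismatch that the
#' selection functions ([select_by_identity_rule()],
#' [select_by_reference()]) subsequently correct.
#'
#' @param F An `affine_fundamental` object or 3x3 matrix (pixel units).
#' @param cam1_K,cam2_K 3x3 intrinsic matrices (px/mm), or
#'   [telecentric_camera()] objects.
#' @return An `extrinsic_candidates` object with fields `R_a`, `R_b`,
#'   `t_unit`, plus the generating `F`, `K1`, `K2` (kept for the
#'   reference-based refinement) and the singular values of `E`.
#' @export
candidate_extrinsics <- function(F, cam1_K, cam2_K) {
  Fm <- as_F_matrix(F)
  K1 <- as_K_matrix(cam1_K)
  K2 <- as_K_matrix(cam2_K)
  stopifnot(all(diag(K1) > 0), all(diag(K2) > 0))
  E <- t(K2) %*% Fm %*% K1
  s <- svd(E)
  if (s$d[3] > 0.3 * s$d[1]) {
    stop("E has numerical rank 3 after projection; not an epipolar geometry")
  }
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  extrinsic_candidates(R_a = U %*% W %*% t(V),
                       R_b = U %*% t(W) %*% t(V),
                       t_unit = U[, 3],
                       F = if (inherits(F, "affine_fundamental")) F else NULL,
                       K1 = K1, K2 = K2,
                       singular_values = s$d)
}

#' Construct an extrinsic candidate set
#'
#' Container for the four-fold ambiguity `{R_a, R_b} x {+t, -t}` of
#' essential-matrix decomposition. Usually produced by
#' [candidate_extrinsics()]; the constructor is exported so candidate pairs
#' from external calibrations can be fed to the selection rules directly.
#'
#' @param R_a,R_b Candidate 3x3 rotation matrices.
#' @param t_unit Unit baseline direction (sign ambiguous).
#' @param F,K1,K2,singular_values Optional provenance (see
#'   [candidate_extrinsics()]).
#' @return An `extrinsic_candidates` object.
#' @export
extrinsic_candidates <- function(R_a, R_b, t_unit = c(1, 0, 0), F = NULL,
                                 K1 = NULL, K2 = NULL,
                                 singular_values = NULL) {
  R_a <- as.matrix(R_a); R_b <- as.matrix(R_b)
  if (!is_rotation(R_a, tol = 1e-3) || !is_rotation(R_b, tol = 1e-3)) {
    stop("candidate rotations must be orthonormal with determinant +1")
  }
  t_unit <- t_unit / sqrt(sum(t_unit^2))
  structure(list(R_a = R_a, R_b = R_b, t_unit = t_unit, F = F,
                 K1 = K1, K2 = K2, singular_values = singular_values),
            class = "extrinsic_candidates")
}

#' @export
print.extrinsic_candidates <- function(x, ...) {
  cat("<extrinsic candidate set {R_a, R_b} x {+t, -t}>\n")
  cat(sprintf("  ||R_a - I||_F = %.4f   ||R_b - I||_F = %.4f\n",
              norm(x$R_a - diag(3), "F"), norm(x$R_b - diag(3), "F")))
  cat("  t_unit =", sprintf("% .5f", x$t_unit), "\n")
  invisible(x)
}

as_K_matrix <- function(x) {
  if (inherits(x, "telecam")) intrinsic_matrix(x) else as.matrix(x)
}

#' Select extrinsics by deviation from the identity
#'
#' The rule of thumb for telecentric rigs whose cameras are mounted with a
#' roll between them: of the two candidate rotations, the one that deviates
#' more from the identity matrix is (usually) the physically correct second
#' perspective, while the near-identity one is the re-projection in the
#' first camera view. Deviation is the Frobenius distance `||R - I||_F`.
#' The translation sign is immaterial for reconstruction, so `+t` is
#' returned.
#'
#' @param cands An [extrinsic_candidates()] set.
#' @return A list with `R` (selected rotation), `t_unit`, `margin`
#'   (difference of the two deviations — a confidence diagnostic) and
#'   `which` (`"R_a"` or `"R_b"`).
#' @export
select_by_identity_rule <- function(cands) {
  stopifnot(inherits(cands, "extrinsic_candidates"))
  da <- norm(cands$R_a - diag(3), "F")
  db <- norm(cands$R_b - diag(3), "F")
  margin <- abs(da - db)
  if (margin < 1e-6) {
    stop("ambiguous selection: candidate rotations are equidistant from ",
         "the identity (margin < 1e-6); use select_by_reference()")
  }
  if (da > db) {
    list(R = cands$R_a, t_unit = cands$t_unit, margin = margin, which = "R_a")
  } else {
    list(R = cands$R_b, t_unit = cands$t_unit, margin = margin, which = "R_b")
  }
}

# ---- affine-consistent rotation family --------------------------------------

# The affine fundamental matrix fixes only the DIRECTIONS of (r13, r23) and
# (r31, r32) of the relative rotation; their common magnitude rho (the
# bas-relief / turn-angle parameter) and the sign of r33 are invisible to
# two parallel-projection views. The consistent rotations form four
# one-parameter branches indexed by (s, sigma) in {+-1}^2:
#   third column = (s rho n1, sigma sqrt(1 - rho^2))
#   third row    = (s rho n2, sigma sqrt(1 - rho^2))
# completed uniquely to a proper rotation. s flips select the mirror
# (Necker) twin; sigma flips the depth-reversed (wrong) family.
affine_family_basis <- function(F, K1, K2) {
  Fm <- as_F_matrix(F)
  E <- t(as_K_matrix(K2)) %*% Fm %*% as_K_matrix(K1)
  v1 <- c(-E[2, 3], E[1, 3])   # direction of (r13, r23)
  v2 <- c(-E[3, 2], E[3, 1])   # direction of (r31, r32)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-14 || n2 < 1e-14) {
    stop("degenerate affine fundamental matrix: epipolar directions undefined")
  }
  list(n1 = v1 / n1, n2 = v2 / n2)
}

# Proper rotation with prescribed third column c3 and third row r3
# (consistent z components and xy norms assumed).
complete_rotation <- function(c3, r3) {
  ax <- c(-c3[2], c3[1], 0)                   # e3 x c3
  ang <- acos(min(1, max(-1, c3[3])))
  G <- rotation_about_axis(ax, ang, degrees = FALSE)   # G e3 = c3
  g <- as.vector(t(G) %*% c(0, 0, 1))
  phi <- atan2(g[2], g[1]) - atan2(r3[2], r3[1])
  G %*% rotation_about_axis(c(0, 0, 1), phi, degrees = FALSE)
}

affine_family_rotation <- function(basis, rho, s = 1, sigma = 1) {
  z <- sigma * sqrt(max(0, 1 - rho^2))
  complete_rotation(c(s * rho * basis$n1, z), c(s * rho * basis$n2, z))
}

#' Select extrinsics against a reference shape
#'
#' The decisive disambiguation step: each candidate is used to triangulate
#' the correspondence pairs (camera 1 at the canonical pose; reconstruction
#' is expressed in camera-1 coordinates), the reference shape is fitted to
#' the resulting cloud, and the candidate with the smallest residual
#' standard deviation wins. A distorted reconstruction — the fingerprint of
#' a wrong extrinsic choice — shows up as a residual std orders of magnitude
#' above the measurement noise.
#'
#' When the candidate set carries the estimated affine fundamental matrix
#' (the usual case) and `refine = TRUE`, the selection additionally searches
#' the one-parameter family of rotations consistent with the affine epipolar
#' geometry: two parallel-projection views leave the turn-angle magnitude
#' (bas-relief parameter) and a depth-reversal sign free, so the reference
#' shape is what pins them down. The four sign branches of the family are
#' each optimized over the bas-relief parameter and the best refined
#' rotation is returned. Without refinement only the four discrete
#' candidates are compared.
#'
#' @param cands An [extrinsic_candidates()] set.
#' @param pairs Correspondence tibble (>= 10 rows).
#' @param cam1,cam2 The two [telecentric_camera()]s (intrinsics used;
#'   camera 1 defines the reconstruction frame).
#' @param reference `"sphere"` or `"plane"`.
#' @param fixed_radius Optional fixed sphere radius (mm); by default the
#'   radius is free, since a physical reference sphere's true radius may
#'   differ slightly from nominal.
#' @param refine Search the affine-consistent rotation family (default) or
#'   only the discrete candidates.
#' @return A list with `R`, `t_unit`, `std` (winning residual std, mm),
#'   `residuals` (tibble: one row per evaluated candidate with `candidate`,
#'   `type`, `rho`, `std`, `radius`), and `method = "reference"`.
#' @export
select_by_reference <- function(cands, pairs, cam1, cam2,
                                reference = c("sphere", "plane"),
                                fixed_radius = NULL, refine = TRUE) {
  stopifnot(inherits(cands, "extrinsic_candidates"),
            inherits(cam1, "telecam"), inherits(cam2, "telecam"))
  reference <- match.arg(reference)
  if (nrow(pairs) < 10) stop("need at least 10 correspondence pairs")

  cam1c <- canonical_camera(cam1)
  p1 <- cbind(pairs$u1, pairs$v1)
  p2 <- cbind(pairs$u2, pairs$v2)

  eval_candidate <- function(R, t_unit) {
    cam2c <- camera_with_pose(cam2, R, t_unit)
    X <- tryCatch(triangulate_pairs(cam1c, cam2c, p1, p2),
                  error = function(e) NULL)
    if (is.null(X)) return(list(std = Inf, radius = NA_real_))
    fit <- tryCatch(
      if (reference == "sphere") {
        fit_sphere(X, fixed_radius = fixed_radius)
      } else {
        fit_plane(X)
      },
      error = function(e) NULL)
    if (is.null(fit)) return(list(std = Inf, radius = NA_real_))
    list(std = fit$std,
         radius = if (reference == "sphere") fit$radius else NA_real_)
  }

  rows <- list()
  add_row <- function(candidate, type, rho, R, t_unit) {
    ev <- eval_candidate(R, t_unit)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      candidate = candidate, type = type, rho = rho,
      std = ev$std, radius = ev$radius)
    ev$std
  }

  best <- list(std = Inf, R = NULL, t_unit = cands$t_unit)
  consider <- function(std, R, t_unit) {
    if (std < best$std) best <<- list(std = std, R = R, t_unit = t_unit)
  }

  for (rn in c("R_a", "R_b")) {
    for (ts in c(1, -1)) {
      R <- cands[[rn]]
      tu <- ts * cands$t_unit
      lbl <- paste0(rn, if (ts > 0) " +t" else " -t")
      consider(add_row(lbl, "discrete", NA_real_, R, tu), R, tu)
    }
  }

  branch_best <- list(`1` = list(std = Inf), `-1` = list(std = Inf))
  if (refine && !is.null(cands$F)) {
    basis <- affine_family_basis(cands$F, cands$K1, cands$K2)
    for (s in c(1, -1)) {
      for (sigma in c(1, -1)) {
        obj <- function(rho) {
          ev <- eval_candidate(affine_family_rotation(basis, rho, s, sigma),
                               cands$t_unit)
          ev$std
        }
        opt <- stats::optimize(obj, c(1e-3, 1 - 1e-9), tol = 1e-10)
        R <- affine_family_rotation(basis, opt$minimum, s, sigma)
        lbl <- sprintf("family s=%+d sigma=%+d", s, sigma)
        std <- add_row(lbl, "refined", opt$minimum, R, cands$t_unit)
        consider(std, R, cands$t_unit)
        key <- as.character(sigma)
        if (std < branch_best[[key]]$std) {
          branch_best[[key]] <- list(std = std, R = R, rho = opt$minimum)
        }
      }
    }
  }

  tab <- dplyr::bind_rows(rows)
  if (!is.finite(best$std)) {
    stop("all candidates yield degenerate triangulations")
  }
  refined_pair <- NULL
  if (is.finite(branch_best[["1"]]$std) &&
      is.finite(branch_best[["-1"]]$std)) {
    # the telecentric-consistent analogue of the discrete candidate pair:
    # the best rotation of each depth-reversal branch
    refined_pair <- list(R_plus = branch_best[["1"]]$R,
                         std_plus = branch_best[["1"]]$std,
                         R_minus = branch_best[["-1"]]$R,
                         std_minus = branch_best[["-1"]]$std)
  }
  list(R = best$R, t_unit = best$t_unit, std = best$std,
       residuals = tab, refined_pair = refined_pair,
       method = "reference", reference = reference)
}

canonical_camera <- function(cam) {
  telecentric_camera(cam$mag[["x"]], cam$mag[["y"]], cam$pixel_pitch,
                     R = diag(3), t = c(0, 0, 0), image_size = cam$image_size)
}

camera_with_pose <- function(cam, R, t) {
  telecentric_camera(cam$mag[["x"]], cam$mag[["y"]], cam$pixel_pitch,
                     R = R, t = t, image_size = cam$image_size)
}

# ---- metric scale -----------------------------------------------------------

#' Estimate the metric rescaling factor from a grid-feature cloud
#'
#' The baseline magnitude is unrecoverable from the affine fundamental
#' matrix alone, and residual intrinsic-convention errors leave
#' reconstructions metrically off by a global factor. Measuring a
#' calibration plate of features at known spacing fixes it: the cloud is
#' projected onto its best-fit plane, feature points are clustered
#' (single linkage with an adaptive cut), and the modal nearest-neighbour
#' spacing between cluster centres is compared with the true spacing.
#'
#' @param cloud Point cloud tibble (columns `x, y, z`) containing the
#'   bright grid features only (filter by intensity/score first).
#' @param true_spacing True feature spacing, mm.
#' @param max_points Deterministic subsample bound for clustering.
#' @return A `scale_result`: list with `factor`
#'   (`= true_spacing / measured`), `feature_spacing_measured`,
#'   `feature_spacing_true`, `n_features`.
#' @export
estimate_scale <- function(cloud, true_spacing, max_points = 4000L) {
  X <- as_xyz_matrix(cloud)
  stopifnot(true_spacing > 0)
  if (nrow(X) < 2) stop("need at least 2 feature points")
  if (nrow(X) > max_points) {
    X <- X[seq(1, nrow(X), length.out = max_points), , drop = FALSE]
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  P2 <- Xc %*% ev$vectors[, 1:2]          # in-plane coordinates
  D <- stats::dist(P2)
  # adaptive single-linkage cut: intra-feature spacing << grid spacing
  Dm <- as.matrix(D)
  diag(Dm) <- Inf
  med_nn <- stats::median(apply(Dm, 1, min))
  hc <- stats::hclust(D, method = "single")
  cl <- stats::cutree(hc, h = 5 * med_nn)
  # stray points split off their feature; drop fragments before centring
  sizes <- table(cl)
  keep_ids <- as.integer(names(sizes)[sizes >= max(3, 0.1 * stats::median(sizes))])
  if (length(keep_ids) < 2) stop("fewer than 2 feature clusters detected")
  centers <- t(vapply(keep_ids,
                      function(i) colMeans(P2[cl == i, , drop = FALSE]),
                      numeric(2)))
  k <- length(keep_ids)
  # one reassignment pass: fragments dropped above rejoin their feature,
  # removing the centre bias of truncated clusters
  d2c <- outer(P2[, 1], centers[, 1], "-")^2 +
    outer(P2[, 2], centers[, 2], "-")^2
  nearest <- max.col(-d2c, ties.method = "first")
  centers <- t(vapply(seq_len(k),
                      function(i) colMeans(P2[nearest == i, , drop = FALSE]),
                      numeric(2)))
  Cd <- as.matrix(stats::dist(centers))
  diag(Cd) <- Inf
  # modal nearest-neighbour spacing: collect ALL adjacent pairs (distances
  # within 1.25x the per-point minimum) and take their median. Selecting
  # pairs by threshold rather than per-point minima avoids the downward
  # bias of min-statistics under centre noise.
  nn0 <- stats::median(apply(Cd, 1, min))
  adjacent <- Cd[upper.tri(Cd)]
  adjacent <- adjacent[adjacent < 1.25 * nn0]
  measured <- stats::median(adjacent)
  structure(list(factor = true_spacing / measured,
                 feature_spacing_measured = measured,
                 feature_spacing_true = true_spacing,
                 n_features = k),
            class = "scale_result")
}

#' @export
print.scale_result <- function(x, ...) {
  cat(sprintf("<scale: factor %.6g  (measured %.6g mm, true %.6g mm, %d features)>\n",
              x$factor, x$feature_spacing_measured, x$feature_spacing_true,
              x$n_features))
  invisible(x)
}

#' Apply a metric rescaling factor to a point cloud
#'
#' @param cloud Point cloud tibble with `x, y, z`.
#' @param factor Scale factor (e.g. from [estimate_scale()]).
#' @return The rescaled cloud.
#' @export
rescale_cloud <- function(cloud, factor) {
  if (inherits(factor, "scale_result")) factor <- factor$factor
  dplyr::mutate(cloud, x = .data$x * factor, y = .data$y * factor,
                z = .data$z * factor)
}

# ---- calibration serialization ----------------------------------------------

#' Write a calibration result to YAML
#'
#' Serializes `{K1, K2, R, t_unit, selection_method,
#' margin_or_residual_table, scale_factor}`.
#'
#' @param calib A list with at least `K1`, `K2`, `R`, `t_unit`; optionally
#'   `selection_method`, `margin`, `residuals` (data frame), `scale_factor`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  out <- list(
    K1 = as.numeric(t(as_K_matrix(calib$K1))),
    K2 = as.numeric(t(as_K_matrix(calib$K2))),
    R = as.numeric(t(calib$R)),
    t_unit = as.numeric(calib$t_unit),
    selection_method = calib$selection_method %||% "reference",
    scale_factor = calib$scale_factor %||% 1
  )
  if (!is.null(calib$F)) {
    out$F <- as.numeric(t(as_F_matrix(calib$F)))
  }
  if (!is.null(calib$margin)) out$margin <- calib$margin
  if (!is.null(calib$residuals)) {
    out$residual_table <- lapply(
      seq_len(nrow(calib$residuals)),
      function(i) as.list(calib$residuals[i, , drop = FALSE]))
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  x$K1 <- matrix(as.numeric(x$K1), 3, 3, byrow = TRUE)
  x$K2 <- matrix(as.numeric(x$K2), 3, 3, byrow = TRUE)
  x$R <- matrix(as.numeric(x$R), 3, 3, byrow = TRUE)
  x$t_unit <- as.numeric(x$t_unit)
  if (!is.null(x$F)) x$F <- matrix(as.numeric(x$F), 3, 3, byrow = TRUE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
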