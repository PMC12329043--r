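#' Point cloud tibbles
#'
#' Reconstructed point clouds are plain tibbles with columns `x, y, z` (mm),
#' usually `score` (the temporal correlation of the generating
#' correspondence, in `[-1, 1]`), and optionally `gap` (ray-to-ray distance,
#' mm), `red, green, blue` (colour in `[0, 1]`). They flow through dplyr
#' verbs unchanged; the `pointcloud` subclass only adds printing and
#' plotting.
#'
#' @param x,y,z Coordinates in mm.
#' @param score Optional per-point correlation values.
#' @param ... Further per-point columns (e.g. `gap`, `red`, `green`, `blue`).
#' @return A `pointcloud` tibble.
#' @export
point_cloud <- function(x, y, z, score = NULL, ...) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z))
  if (!is.null(score)) {
    stopifnot(all(score >= -1 & score <= 1))
    out$score <- as.numeric(score)
  }
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  as_pointcloud(out)
}

#' @rdname point_cloud
#' @param df A data frame with at least `x, y, z`.
#' @export
as_pointcloud <- function(df) {
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df <- tibble::as_tibble(df)
  class(df) <- unique(c("pointcloud", class(df)))
  df
}

# ---- shape fits -------------------------------------------------------------

new_shape_fit <- function(model, residuals, n, ...) {
  structure(c(list(model = model, residuals = residuals,
                   std = sqrt(mean(residuals^2)),   # population std about fit
                   n = n), list(...)),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("<%s fit: n = %d, residual std = %.4g mm (%.3g um)>\n",
              x$model, x$n, x$std, x$std * 1e3))
  if (x$model == "plane") {
    cat("  normal =", sprintf("% .6f", x$normal),
        sprintf("  offset = %.6g mm\n", x$offset))
  } else {
    cat("  center =", sprintf("% .6g", x$center),
        sprintf("  radius = %.6g mm%s\n", x$radius,
                if (isTRUE(x$radius_fixed)) " (fixed)" else ""))
  }
  invisible(x)
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing orthogonal (perpendicular) distances: the
#' normal is the smallest-eigenvalue direction of the centred covariance.
#' Residuals are signed point-plane distances; the reported standard
#' deviation is the population std of the residuals — the headline flatness
#' statistic of a reference-plane validation.
#'
#' @param points Cloud tibble / data frame with `x, y, z`, or n x 3 matrix
#'   (>= 3 non-collinear points).
#' @return A `shape_fit` with `model = "plane"`, `normal` (unit), `offset`
#'   (plane is `normal . X = offset`), `residuals`, `std` (mm), `n`.
#' @export
fit_plane <- function(points) {
  X <- as_xyz_matrix(points)
  if (nrow(X) < 3) stop("need at least 3 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  C <- crossprod(Xc) / nrow(X)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] < 1e-14 * max(ev$values[1], 1e-300)) {
    stop("degenerate input: points are collinear")
  }
  normal <- ev$vectors[, 3]
  if (normal[3] < 0) normal <- -normal      # deterministic orientation
  res <- as.vector(Xc %*% normal)
  new_shape_fit("plane", res, nrow(X),
                normal = normal, offset = sum(normal * ctr),
                inlier_count = nrow(X))
}

#' Least-squares sphere fit
#'
#' Free-radius fits start from the algebraic linear solution (expanding
#' `||X - c||^2 = r^2`) and refine centre and radius by Gauss-Newton on the
#' geometric distances; fixed-radius fits refine the centre only at the
#' given radius, the regime used for a reference sphere whose nominal
#' radius is trusted. Residuals are signed radial distances
#' `||X - c|| - r`.
#'
#' @param points Cloud tibble / data frame with `x, y, z`, or n x 3 matrix.
#' @param fixed_radius Optional known radius (mm); if given, only the
#'   centre is estimated.
#' @param max_iter,tol Gauss-Newton controls.
#' @return A `shape_fit` with `model = "sphere"`, `center`, `radius`,
#'   `radius_fixed`, `residuals`, `std` (mm), `n`.
#' @export
fit_sphere <- function(points, fixed_radius = NULL, max_iter = 100L,
                       tol = 1e-14) {
  X <- as_xyz_matrix(points)
  n <- nrow(X)
  fixed <- !is.null(fixed_radius)
  if (fixed) stopifnot(fixed_radius > 0)
  if (!fixed && n < 4) stop("need at least 4 points for a free-radius fit")
  if (fixed && n < 3) stop("need at least 3 points for a fixed-radius fit")

  # algebraic initialization
  A <- cbind(2 * X, 1)
  b <- rowSums(X^2)
  qrA <- qr(A)
  if (qrA$rank < 4 && !fixed) {
    stop("degenerate input: points are coplanar; free-radius sphere fit undefined")
  }
  if (qrA$rank >= 4) {
    sol <- qr.coef(qrA, b)
    ctr <- sol[1:3]
    r <- sqrt(max(sol[4] + sum(ctr^2), 1e-300))
  } else {
    ctr <- colMeans(X)
    r <- fixed_radius
  }
  if (fixed) r <- fixed_radius

  # Gauss-Newton on geometric distance with simple damping
  prev_rss <- Inf
  for (it in seq_len(max_iter)) {
    d <- sweep(X, 2, ctr)
    dist <- sqrt(rowSums(d^2))
    dist[dist < 1e-300] <- 1e-300
    res <- dist - r
    rss <- sum(res^2)
    J <- -d / dist
    if (!fixed) J <- cbind(J, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      ctr_new <- ctr + lambda * step[1:3]
      r_new <- if (fixed) r else r + lambda * step[4]
      dist_new <- sqrt(rowSums(sweep(X, 2, ctr_new)^2))
      rss_new <- sum((dist_new - max(r_new, 1e-300))^2)
      if (rss_new <= rss || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    ctr <- ctr_new
    if (!fixed) r <- max(r_new, 1e-300)
    if (sum(step^2) * lambda^2 < tol^2 || abs(prev_rss - rss_new) < tol) break
    prev_rss <- rss_new
  }
  dist <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  new_shape_fit("sphere", dist - r, n,
                center = as.numeric(ctr), radius = r, radius_fixed = fixed,
                inlier_count = n)
}

# ---- quality filters --------------------------------------------------------

#' Filter a point cloud by correlation score
#'
#' Retains exactly the points with `score >= min_score`, preserving order.
#' Typical thresholds: 0.9 for cooperative (matte, bright) surfaces, 0.3
#' for difficult scattering objects.
#'
#' @param cloud Cloud tibble with a `score` column.
#' @param min_score Threshold in `[-1, 1]`.
#' @return The filtered cloud (possibly empty).
#' @export
filter_by_score <- function(cloud, min_score) {
  stopifnot("score" %in% names(cloud), min_score >= -1, min_score <= 1)
  cloud[cloud$score >= min_score, , drop = FALSE]
}

#' Select the central patch of a cloud
#'
#' Reconstruction error grows with the surface slope relative to the viewing
#' direction, so validation statistics are also reported for a central patch
#' where the slope is weak. Points are ranked by radial distance from the
#' axis through the cloud centroid parallel to `viewing_axis`, and the
#' innermost `fraction` is kept (deterministic tie-break by row order).
#'
#' @param cloud Cloud tibble with `x, y, z`.
#' @param viewing_axis Length-3 axis (default `z`).
#' @param fraction Fraction of points to keep, in `(0, 1]`. The reference
#'   sphere analysis uses 0.485.
#' @return The central sub-cloud.
#' @export
central_patch <- function(cloud, viewing_axis = c(0, 0, 1), fraction = 0.485) {
  stopifnot(fraction > 0, fraction <= 1)
  X <- as_xyz_matrix(cloud)
  if (nrow(X) == 0) stop("empty cloud")
  a <- viewing_axis / sqrt(sum(viewing_axis^2))
  Xc <- sweep(X, 2, colMeans(X))
  along <- as.vector(Xc %*% a)
  r2 <- rowSums(Xc^2) - along^2
  keep_n <- ceiling(fraction * nrow(X))
  ord <- order(r2, seq_len(nrow(X)))     # tie-break by index
  cloud[sort(ord[seq_len(keep_n)]), , drop = FALSE]
}

#' Crop a point cloud to an axis-aligned box
#'
#' Used to remove points from a holding platform or other fixtures before
#' fitting; the box is supplied explicitly rather than classified
#' automatically.
#'
#' @param cloud Cloud tibble with `x, y, z`.
#' @param xlim,ylim,zlim Length-2 ranges (mm); `NULL` leaves an axis
#'   unconstrained.
#' @return The cropped cloud.
#' @export
crop_box <- function(cloud, xlim = NULL, ylim = NULL, zlim = NULL) {
  keep <- rep(TRUE, nrow(cloud))
  if (!is.null(xlim)) keep <- keep & cloud$x >= xlim[1] & cloud$x <= xlim[2]
  if (!is.null(ylim)) keep <- keep & cloud$y >= ylim[1] & cloud$y <= ylim[2]
  if (!is.null(zlim)) keep <- keep & cloud$z >= zlim[1] & cloud$z <= zlim[2]
  cloud[keep, , drop = FALSE]
}

#' Residual statistics and histogram of a shape fit
#'
#' @param fit A `shape_fit`.
#' @param bin_width Histogram bin width in mm; defaults to `std / 10`,
#'   matching the granularity at which residual distributions are usually
#'   displayed.
#' @return A list with `std` (mm) and `histogram`, a tibble with
#'   `bin_left`, `bin_right`, `count`.
#' @export
residual_stats <- function(fit, bin_width = NULL) {
  stopifnot(inherits(fit, "shape_fit"))
  r <- fit$residuals
  if (length(r) < 2) stop("need at least 2 residuals")
  if (is.null(bin_width)) bin_width <- fit$std / 10
  if (!is.finite(bin_width) || bin_width <= 0) bin_width <- 1e-6
  lo <- floor(min(r) / bin_width) * bin_width
  hi <- ceiling(max(r) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  list(std = fit$std,
       histogram = tibble::tibble(bin_left = h$breaks[-length(h$breaks)],
                                  bin_right = h$breaks[-1],
                                  count = h$counts))
}

#' Length of a 3D polyline
#'
#' Sum of Euclidean segment lengths of an ordered vertex sequence — the 3D
#' length measurement that a 2D projection underestimates through
#' foreshortening (an orthogonal projection of a curve is never longer than
#' the curve).
#'
#' @param vertices Ordered m x 3 matrix or data frame with `x, y, z`
#'   (m >= 2), mm.
#' @return Total length, mm.
#' @export
polyline_length <- function(vertices) {
  V <- as_xyz_matrix(vertices)
  if (nrow(V) < 2) stop("need at least 2 vertices")
  sum(sqrt(rowSums((V[-1, , drop = FALSE] - V[-nrow(V), , drop = FALSE])^2)))
}
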