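#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a shape fit
#'
#' One row per fitted parameter, broom-style.
#'
#' @param x A `shape_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (mm where dimensional).
#' @export
tidy.shape_fit <- function(x, ...) {
  if (x$model == "plane") {
    tibble::tibble(
      term = c("normal_x", "normal_y", "normal_z", "offset"),
      estimate = c(x$normal, x$offset))
  } else {
    tibble::tibble(
      term = c("center_x", "center_y", "center_z", "radius"),
      estimate = c(x$center, x$radius))
  }
}

#' Glance at a shape fit
#'
#' @param x A `shape_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `n`, `std_mm`, `std_um`,
#'   `rmax_mm` (largest absolute residual) and, for spheres, `radius_mm`.
#' @export
glance.shape_fit <- function(x, ...) {
  out <- tibble::tibble(model = x$model, n = x$n, std_mm = x$std,
                        std_um = x$std * 1e3,
                        rmax_mm = max(abs(x$residuals)))
  if (x$model == "sphere") out$radius_mm <- x$radius
  out
}

#' Tidy an extrinsic candidate set
#'
#' @param x An [extrinsic_candidates()] object.
#' @param ... Unused.
#' @return A tibble with one row per candidate rotation: `candidate`,
#'   `identity_deviation` (Frobenius distance from I) and `angle_deg`.
#' @export
tidy.extrinsic_candidates <- function(x, ...) {
  tibble::tibble(
    candidate = c("R_a", "R_b"),
    identity_deviation = c(norm(x$R_a - diag(3), "F"),
                           norm(x$R_b - diag(3), "F")),
    angle_deg = c(rotation_angle(x$R_a), rotation_angle(x$R_b)))
}

#' Residual histogram of a shape fit
#'
#' Displays the signed residual distribution about the fitted shape, the
#' visual companion of the reported standard deviation.
#'
#' @param object A `shape_fit`.
#' @param bin_width Histogram bin width in mm (default `std / 10`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_fit <- function(object, bin_width = NULL, ...) {
  rs <- residual_stats(object, bin_width)
  h <- rs$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2 * 1e3,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_right[1] - h$bin_left[1]) * 1e3,
                      fill = "grey35") +
    ggplot2::labs(
      x = expression(paste("signed residual (", mu, "m)")),
      y = "count",
      title = sprintf("%s fit: residual std %.1f um",
                      object$model, object$std * 1e3)) +
    ggplot2::theme_minimal()
}

#' Plot a point cloud projection
#'
#' A 2D orthographic projection of the cloud, coloured by depth or by
#' correlation score.
#'
#' @param object A `pointcloud` tibble.
#' @param colour `"z"` (depth) or `"score"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pointcloud <- function(object, colour = c("z", "score"), ...) {
  colour <- match.arg(colour)
  if (colour == "score" && !"score" %in% names(object)) colour <- "z"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = colour) +
    ggplot2::theme_minimal()
}

#' @export
print.pointcloud <- function(x, ...) {
  cat(sprintf("<point cloud: %d points%s>\n", nrow(x),
              if ("score" %in% names(x) && nrow(x) > 0)
                sprintf(", score %.3f-%.3f", min(x$score), max(x$score))
              else ""))
  NextMethod()
}
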