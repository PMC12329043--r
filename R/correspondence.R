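#' Temporal normalized cross-correlation of two intensity series
#'
#' The match score of temporal-correlation stereo: the zero-mean normalized
#' cross-correlation of the per-pixel intensity time series recorded under
#' the varying illumination patterns,
#' \deqn{\rho = \frac{\sum (a-\bar a)(b - \bar b)}
#'   {\sqrt{\sum (a-\bar a)^2 \sum (b-\bar b)^2}},}
#' clamped to `[-1, 1]` against rounding.
#'
#' @param series_a,series_b Numeric vectors of equal length >= 2.
#' @return The correlation score in `[-1, 1]`.
#' @export
temporal_ncc <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 2)
  a <- series_a - mean(series_a)
  b <- series_b - mean(series_b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("undefined score: zero temporal variance in a series")
  }
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# Flatten an image stack into a temporally normalized n_frames x n_pixels
# matrix (each column zero-mean, unit norm). Columns whose temporal standard
# deviation falls below the modulation floor (unlit/background pixels, whose
# pure-noise correlations would otherwise produce spurious extreme-value
# peaks over large search regions) are zeroed and flagged.
normalize_stack <- function(stack, min_modulation = 0) {
  d <- dim(stack$frames)
  M <- matrix(aperm(stack$frames, c(3, 1, 2)), d[3], d[1] * d[2])
  M <- M - rep(colMeans(M), each = d[3])
  nrm <- sqrt(colSums(M^2))
  ok <- nrm > max(1e-12, min_modulation * sqrt(d[3] - 1))
  M[, ok] <- M[, ok] / rep(nrm[ok], each = d[3])
  M[, !ok] <- 0
  list(M = M, ok = ok, H = d[1], W = d[2], n_frames = d[3])
}

pix_u <- function(col, W) col - (W + 1) / 2
pix_v <- function(row, H) row - (H + 1) / 2

# 3x3 paraboloid (quadratic surface) refinement of a correlation peak.
# scores9: n x 9 matrix, columns ordered by (dv, du) in
# (-1,-1),(0,-1),(1,-1),(-1,0),(0,0),(1,0),(-1,1),(0,1),(1,1).
# Returns n x 2 matrix of (du, dv) offsets clamped to [-0.5, 0.5].
paraboloid_peak <- function(scores9) {
  off <- expand.grid(dv = -1:1, du = -1:1)
  D <- cbind(1, off$du, off$dv, off$du^2, off$dv^2, off$du * off$dv)
  Dpinv <- solve(crossprod(D), t(D))          # 6 x 9
  cf <- scores9 %*% t(Dpinv)                  # n x 6
  det2 <- 4 * cf[, 4] * cf[, 5] - cf[, 6]^2
  du <- (-2 * cf[, 5] * cf[, 2] + cf[, 6] * cf[, 3]) / det2
  dv <- (-2 * cf[, 4] * cf[, 3] + cf[, 6] * cf[, 2]) / det2
  bad <- !is.finite(du) | !is.finite(dv)
  du[bad] <- 0; dv[bad] <- 0
  cbind(du = pmin(0.5, pmax(-0.5, du)), dv = pmin(0.5, pmax(-0.5, dv)))
}

#' Temporal-correlation correspondence search between two image stacks
#'
#' For every `stride`-th valid pixel of camera 1, finds the camera-2 pixel
#' maximizing the temporal NCC over the search region, optionally refines the
#' integer peak by fitting a 2D quadratic (paraboloid) to the 3x3 correlation
#' neighborhood (refined peak clamped to +-0.5 px), and drops pairs whose
#' score falls below `min_score`, whose series have zero temporal variance,
#' or whose integer peak lies on the border of the search region (where the
#' paraboloid fit is undefined).
#'
#' Two search strategies are provided: `"full"` (exhaustive over camera 2,
#' used at a coarse stride for calibration) and `"epipolar_band"` (pixels
#' within `half_width` px of the affine epipolar line of each camera-1 pixel,
#' used for dense reconstruction once the fundamental matrix is known).
#'
#' @param stack1,stack2 `image_stack` objects sharing `n_frames`.
#' @param search `"full"` or `"epipolar_band"`.
#' @param F Affine fundamental matrix (object from
#'   [estimate_affine_fundamental()] or plain 3x3 matrix), required for
#'   `search = "epipolar_band"`. Convention: `x2' F x1 = 0` with
#'   `x = (u, v, 1)` in centred pixel coordinates.
#' @param half_width Epipolar band half-width, px.
#' @param min_score Minimum retained score, in `[-1, 1]`.
#' @param subpixel Refine peaks to subpixel precision.
#' @param stride Sample every `stride`-th pixel of camera 1 (both axes).
#' @param min_modulation Temporal-modulation floor (intensity units):
#'   pixels whose intensity time series has a standard deviation below this
#'   are treated as unlit and excluded on both sides. Guards against the
#'   extreme-value statistics of pure-noise correlations over large search
#'   regions; set to 0 to disable.
#' @param chunk Internal block size (pixels per matrix product).
#' @return A tibble with columns `u1, v1, u2, v2, score`, one row per
#'   retained correspondence.
#' @export
find_correspondences <- function(stack1, stack2,
                                 search = c("full", "epipolar_band"),
                                 F = NULL, half_width = 2,
                                 min_score = 0.3, subpixel = TRUE,
                                 stride = 1L, min_modulation = 0.02,
                                 chunk = 256L) {
  search <- match.arg(search)
  stopifnot(inherits(stack1, "image_stack"), inherits(stack2, "image_stack"),
            min_score >= -1, min_score <= 1, stride >= 1)
  n1 <- normalize_stack(stack1, min_modulation)
  n2 <- normalize_stack(stack2, min_modulation)
  if (n1$n_frames != n2$n_frames) stop("stacks must share n_frames")

  # camera-1 sample grid: every stride-th pixel with temporal variance
  rows <- seq(1L, n1$H, by = as.integer(stride))
  cols <- seq(1L, n1$W, by = as.integer(stride))
  sel <- as.vector(outer(rows, (cols - 1L) * n1$H, "+"))
  sel <- sel[n1$ok[sel]]
  if (length(sel) == 0) {
    return(empty_correspondences())
  }

  if (search == "full") {
    peaks <- match_full(n1, n2, sel, chunk)
  } else {
    if (is.null(F)) stop("F is required for search = 'epipolar_band'")
    Fm <- as_F_matrix(F)
    peaks <- match_banded(n1, n2, sel, Fm, half_width)
  }
  finalize_matches(n1, n2, peaks, min_score, subpixel, search, chunk)
}

empty_correspondences <- function() {
  tibble::tibble(u1 = numeric(), v1 = numeric(),
                 u2 = numeric(), v2 = numeric(), score = numeric())
}

as_F_matrix <- function(F) {
  if (inherits(F, "affine_fundamental")) F$F else as.matrix(F)
}

# Exhaustive search: block matrix products against all camera-2 pixels.
match_full <- function(n1, n2, sel, chunk) {
  npix2 <- ncol(n2$M)
  best_idx <- integer(length(sel))
  best_score <- numeric(length(sel))
  border <- logical(length(sel))
  for (start in seq(1, length(sel), by = chunk)) {
    ii <- start:min(start + chunk - 1, length(sel))
    S <- crossprod(n1$M[, sel[ii], drop = FALSE], n2$M)  # |ii| x npix2
    bi <- max.col(S, ties.method = "first")
    best_idx[ii] <- bi
    best_score[ii] <- S[cbind(seq_along(ii), bi)]
  }
  r2 <- (best_idx - 1L) %% n2$H + 1L
  c2 <- (best_idx - 1L) %/% n2$H + 1L
  border <- r2 <= 1L | r2 >= n2$H | c2 <= 1L | c2 >= n2$W
  list(sel = sel, idx2 = best_idx, score = best_score, border = border)
}

# Epipolar-band search. For an affine F all epipolar lines in image 2 are
# parallel; camera-2 pixels are sorted once by their signed distance along
# the common line normal, and each camera-1 pixel's band is a contiguous
# range in that order. Camera-1 pixels are processed in groups of similar
# band offset so that each group is one matrix product.
match_banded <- function(n1, n2, sel, Fm, half_width) {
  a <- Fm[1, 3]; b <- Fm[2, 3]
  nn <- sqrt(a^2 + b^2)
  if (nn < 1e-14) stop("degenerate affine fundamental matrix (no epipolar direction)")
  # signed distance of every camera-2 pixel from the line a*u2 + b*v2 = 0
  r2 <- rep(seq_len(n2$H), times = n2$W)
  c2 <- rep(seq_len(n2$W), each = n2$H)
  s2 <- (a * pix_u(c2, n2$W) + b * pix_v(r2, n2$H)) / nn
  ord <- order(s2)
  s2s <- s2[ord]

  # band centre offset for each camera-1 sample
  r1 <- (sel - 1L) %% n1$H + 1L
  c1 <- (sel - 1L) %/% n1$H + 1L
  o1 <- -(Fm[3, 1] * pix_u(c1, n1$W) + Fm[3, 2] * pix_v(r1, n1$H) + Fm[3, 3]) / nn

  grp <- round(o1)              # 1 px offset bins
  best_idx <- integer(length(sel))
  best_score <- numeric(length(sel))
  keep <- logical(length(sel))
  for (g in unique(grp)) {
    gi <- which(grp == g)
    lo <- findInterval(g - half_width - 0.5, s2s) + 1L
    hi <- findInterval(g + half_width + 0.5, s2s)
    if (hi < lo) next
    cand <- ord[lo:hi]
    ok2 <- n2$ok[cand]
    cand <- cand[ok2]
    if (length(cand) == 0) next
    S <- crossprod(n1$M[, sel[gi], drop = FALSE],
                   n2$M[, cand, drop = FALSE])
    bi <- max.col(S, ties.method = "first")
    best_idx[gi] <- cand[bi]
    best_score[gi] <- S[cbind(seq_along(gi), bi)]
    keep[gi] <- TRUE
  }
  rr <- (best_idx - 1L) %% n2$H + 1L
  cc <- (best_idx - 1L) %/% n2$H + 1L
  # border of the search region: image border, or the outer edge of the band
  d2 <- (a * pix_u(cc, n2$W) + b * pix_v(rr, n2$H)) / nn - o1
  border <- !keep | rr <= 1L | rr >= n2$H | cc <= 1L | cc >= n2$W |
    abs(d2) > half_width - 0.5
  list(sel = sel, idx2 = best_idx, score = best_score, border = border)
}

# Shared tail: drop border/low-score peaks, then subpixel-refine survivors
# by recomputing the 3x3 NCC neighborhood around each integer peak.
finalize_matches <- function(n1, n2, peaks, min_score, subpixel, search,
                             chunk = 2048L) {
  keep <- !peaks$border & peaks$score >= min_score
  sel <- peaks$sel[keep]
  idx2 <- peaks$idx2[keep]
  score <- peaks$score[keep]
  if (length(sel) == 0) return(empty_correspondences())

  r1 <- (sel - 1L) %% n1$H + 1L
  c1 <- (sel - 1L) %/% n1$H + 1L
  r2 <- (idx2 - 1L) %% n2$H + 1L
  c2 <- (idx2 - 1L) %/% n2$H + 1L
  du <- rep(0, length(sel)); dv <- rep(0, length(sel))

  if (subpixel) {
    off <- expand.grid(dv = -1:1, du = -1:1)
    for (start in seq(1, length(sel), by = chunk)) {
      ii <- start:min(start + chunk - 1, length(sel))
      n_i <- length(ii)
      nb <- outer(idx2[ii], off$dv + off$du * n2$H, "+")    # n_i x 9
      A <- n1$M[, sel[ii], drop = FALSE]
      S9 <- matrix(0, n_i, 9)
      for (j in 1:9) {
        S9[, j] <- colSums(A * n2$M[, nb[, j], drop = FALSE])
      }
      # keep the integer peak where the fit is undefined (a zero-variance
      # neighbor) or unnecessary (an exact correlation-1 peak)
      okfit <- rowSums(matrix(n2$ok[nb], n_i, 9)) == 9 &
        S9[, 5] < 1 - 1e-9
      d <- paraboloid_peak(S9[okfit, , drop = FALSE])
      idx <- ii[okfit]
      du[idx] <- d[, "du"]
      dv[idx] <- d[, "dv"]
    }
  }
  tibble::tibble(
    u1 = pix_u(c1, n1$W), v1 = pix_v(r1, n1$H),
    u2 = pix_u(c2, n2$W) + du, v2 = pix_v(r2, n2$H) + dv,
    score = score
  )
}

#' Write / read correspondence tables (CSV)
#'
#' Plain CSV with header `u1,v1,u2,v2,score`, six decimals.
#'
#' @param pairs Correspondence tibble from [find_correspondences()].
#' @param path File path.
#' @return `read_correspondences()` returns the tibble; `write_...` returns
#'   `path` invisibly.
#' @export
write_correspondences <- function(pairs, path) {
  stopifnot(all(c("u1", "v1", "u2", "v2", "score") %in% names(pairs)))
  out <- pairs[, c("u1", "v1", "u2", "v2", "score")]
  out[] <- lapply(out, function(x) sprintf("%.6f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("u1", "v1", "u2", "v2", "score") %in% names(df)))
  tibble::as_tibble(df)
}
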