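# Shape descriptors of the bottom-phase trajectory from an
# eigen-decomposition of the 3x3 variance-covariance matrix of positions:
# eigenvalues measure dispersion along the main components, the first main
# component (MC1) is the dominant direction of travel, and quantile-based
# extents and widths summarise exploration along and around it.

#' Eigen-decomposition of bottom-phase positions
#'
#' Decomposes the sample variance-covariance matrix (n-1 denominator) of the
#' positions into eigenvalues (sorted descending) and eigenvectors. The sign
#' of the first eigenvector is fixed so that its horizontal projection points
#' along the net horizontal displacement of the track (falling back to +east,
#' then +up, for degenerate cases).
#'
#' @param positions tibble/data frame with columns `east`, `north`, `z` (m);
#'   at least 4 rows, non-degenerate in at least one dimension.
#' @return A list with `values` (length 3, descending, m^2) and `vectors`
#'   (3x3 matrix, columns v1..v3, unit norm).
#' @export
eigen_shape <- function(positions) {
  p <- as.matrix(positions[, c("east", "north", "z")])
  if (nrow(p) < 4) abort("need at least 4 positions for shape metrics")
  cv <- stats::cov(p)
  if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-12) {
    abort("degenerate position cloud: zero dispersion")
  }
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  disp <- p[nrow(p), ] - p[1, ]
  v1 <- vecs[, 1]
  ref_h <- sum(v1[1:2] * disp[1:2])
  flip <- if (abs(ref_h) > 1e-9) {
    ref_h < 0
  } else if (abs(v1[1]) > 1e-9) {
    v1[1] < 0
  } else {
    v1[3] < 0
  }
  if (flip) vecs[, 1] <- -vecs[, 1]
  # keep the basis right-handed after any sign fix
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  list(values = vals, vectors = vecs)
}

#' Extents of the first main component
#'
#' Positions are centred and projected onto the first eigenvector; the "ends"
#' of the first main component are the 10% and 90% quantiles of these scores
#' (type-7 quantiles). The score range is decomposed into a horizontal and a
#' vertical extent using the eigenvector's horizontal and vertical parts.
#'
#' @param positions tibble `east`, `north`, `z` (m).
#' @param v1 first eigenvector (unit length) from [eigen_shape()].
#' @return A one-row tibble `mc1_horizontal_extent`, `mc1_vertical_extent` (m).
#' @export
mc1_extents <- function(positions, v1) {
  p <- as.matrix(positions[, c("east", "north", "z")])
  centred <- sweep(p, 2, colMeans(p))
  s <- as.numeric(centred %*% v1)
  L <- diff(as.numeric(quantile(s, c(0.10, 0.90), names = FALSE)))
  tibble(
    mc1_horizontal_extent = L * sqrt(sum(v1[1:2]^2)),
    mc1_vertical_extent = L * abs(v1[3])
  )
}

#' Vertical and horizontal widths about the first main component
#'
#' Two orthogonal reference planes through the centroid are defined: plane A
#' contains the first eigenvector and the gravity (vertical) direction; plane
#' B contains the first eigenvector and the normal of plane A. The horizontal
#' width is the 10%-to-90% quantile range of the signed distances of the
#' positions to plane A (sideways horizontal deviations); the vertical width
#' is the same range of signed distances to plane B (vertical deviations).
#' When v1 is within 1 degree of vertical the planes are built with a fixed
#' arbitrary azimuth (north) and the result is flagged.
#'
#' @param positions tibble `east`, `north`, `z` (m).
#' @param v1 first eigenvector from [eigen_shape()].
#' @return A one-row tibble `horizontal_width`, `vertical_width` (m),
#'   `width_flagged` (logical).
#' @export
plane_widths <- function(positions, v1) {
  p <- as.matrix(positions[, c("east", "north", "z")])
  centred <- sweep(p, 2, colMeans(p))
  h <- sqrt(sum(v1[1:2]^2))
  flagged <- h < sin(pi / 180)
  n_a <- if (flagged) {
    c(1, 0, 0)  # plane A spans north and vertical
  } else {
    na <- c(v1[2], -v1[1], 0)  # v1 x vertical, horizontal normal
    na / sqrt(sum(na^2))
  }
  n_b <- vcross(v1, n_a)
  n_b <- n_b / sqrt(sum(n_b^2))
  qr10_90 <- function(d) diff(as.numeric(quantile(d, c(0.10, 0.90), names = FALSE)))
  tibble(
    horizontal_width = qr10_90(as.numeric(centred %*% n_a)),
    vertical_width = qr10_90(as.numeric(centred %*% n_b)),
    width_flagged = flagged
  )
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Assemble the shape-metric row for one bottom phase
#'
#' Combines the eigen-decomposition, extents, widths, mean depth, speed SD,
#' bottom duration and PEE count into the per-dive descriptor table row. The
#' horizontality is the length ratio between the first eigenvector projected
#' on the horizontal plane and the full eigenvector (1 = horizontal MC1,
#' 0 = vertical).
#'
#' @param positions bottom-phase `east`, `north`, `z` positions (m, 1 Hz).
#' @param speed bottom-phase swimming speed (m s^-1), `NA` allowed.
#' @param pee_count number of PEEs whose midpoint falls in the bottom phase.
#' @return A one-row tibble of shape metrics, or a row of `NA`s when the
#'   bottom phase has fewer than 4 positions.
#' @export
shape_metrics <- function(positions, speed = NA_real_, pee_count = 0L) {
  empty <- tibble(
    mean_depth = NA_real_, total_dispersion = NA_real_,
    mc1_dispersion = NA_real_, horizontality = NA_real_,
    mc1_horizontal_extent = NA_real_, mc1_vertical_extent = NA_real_,
    horizontal_width = NA_real_, vertical_width = NA_real_,
    width_flagged = NA, speed_sd = NA_real_,
    bottom_duration = NA_real_, pee_count = as.integer(pee_count)
  )
  if (is.null(positions) || nrow(positions) < 4) return(empty)
  es <- tryCatch(eigen_shape(positions), error = function(e) NULL)
  if (is.null(es)) return(empty)
  v1 <- es$vectors[, 1]
  tot <- sum(es$values)
  ext <- mc1_extents(positions, v1)
  wid <- plane_widths(positions, v1)
  tibble(
    mean_depth = mean(-positions$z),
    total_dispersion = tot,
    mc1_dispersion = es$values[1] / tot,
    horizontality = sqrt(sum(v1[1:2]^2)),
    mc1_horizontal_extent = ext$mc1_horizontal_extent,
    mc1_vertical_extent = ext$mc1_vertical_extent,
    horizontal_width = wid$horizontal_width,
    vertical_width = wid$vertical_width,
    width_flagged = wid$width_flagged,
    speed_sd = if (all(is.na(speed))) NA_real_ else sd(speed, na.rm = TRUE),
    bottom_duration = nrow(positions) - 1,
    pee_count = as.integer(pee_count)
  )
}
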