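# Prospected water volume: the volume of the union of detection spheres of
# radius r centred on every 1 Hz bottom-phase position. Self-intersecting
# paths rule out a closed-form swept volume, so the union is integrated by
# Monte Carlo: uniform samples in the r-expanded bounding box, hit = within r
# of any track position. A spatial-hash cull (cell size r) rejects samples
# far from the track before the exact distance test.

# Integer cell keys (strings) of points for a given cell size.
hash_cells <- function(p, cell) {
  ix <- floor(p[, 1] / cell)
  iy <- floor(p[, 2] / cell)
  iz <- floor(p[, 3] / cell)
  paste(ix, iy, iz, sep = ",")
}

# Keys of all 27-neighbourhood cells of the track points.
active_cells <- function(track, cell) {
  ix <- floor(track[, 1] / cell)
  iy <- floor(track[, 2] / cell)
  iz <- floor(track[, 3] / cell)
  base <- unique(cbind(ix, iy, iz))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keys <- character(0)
  for (k in seq_len(nrow(off))) {
    keys <- c(keys, paste(base[, 1] + off[k, 1], base[, 2] + off[k, 2],
                          base[, 3] + off[k, 3], sep = ","))
  }
  unique(keys)
}

# Exact hit test: which samples lie within r of any track point. Samples in
# inactive hash cells cannot be hits; survivors get a chunked exact
# distance-squared evaluation against the full track.
points_within_radius <- function(samples, track, r) {
  ns <- nrow(samples)
  hit <- rep(FALSE, ns)
  cand <- hash_cells(samples, r) %in% active_cells(track, r)
  if (!any(cand)) return(hit)
  idx <- which(cand)
  t2 <- rowSums(track^2)
  r2 <- r^2
  chunk <- max(1L, floor(4e6 / nrow(track)))
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    q <- samples[idx[s:e], , drop = FALSE]
    d2 <- outer(rowSums(q^2), t2, "+") - 2 * tcrossprod(q, track)
    hit[idx[s:e]] <- matrixStats_rowMins(d2) <= r2 + 1e-9
  }
  hit
}

# do.call(pmin, ...) row minimum without extra dependencies
matrixStats_rowMins <- function(m) {
  apply(m, 1, min)
}

#' Monte-Carlo volume of the union of detection spheres along a track
#'
#' Draws `n_samples` uniform points in the axis-aligned bounding box of the
#' track positions expanded by `r` on every side; the estimated volume is the
#' box volume times the fraction of samples within `r` of at least one track
#' position. The binomial relative standard error of the estimate is
#' reported.
#'
#' @param positions tibble/data frame with `east`, `north`, `z` (m), the
#'   1 Hz track positions (no segment interpolation).
#' @param r detection radius (m), > 0.
#' @param n_samples number of Monte-Carlo samples (>= 1e4 recommended).
#' @param seed integer seed for the sample stream.
#' @param box optional bounding box `rbind(lo, hi)` (2x3) overriding the
#'   default; used to share one sample stream across radii.
#' @return A one-row tibble: `radius`, `volume` (m^3), `relative_se`,
#'   `n_samples`, `seed`.
#' @export
mc_volume <- function(positions, r, n_samples = 2e5, seed = 1L, box = NULL) {
  if (r <= 0) abort("radius must be > 0")
  p <- as.matrix(positions[, c("east", "north", "z")])
  if (nrow(p) < 1) abort("empty track")
  if (is.null(box)) {
    box <- rbind(apply(p, 2, min) - r, apply(p, 2, max) + r)
  }
  span <- box[2, ] - box[1, ]
  vol_box <- prod(span)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  u <- matrix(runif(3 * n_samples), ncol = 3)
  samples <- sweep(sweep(u, 2, span, "*"), 2, box[1, ], "+")
  hit <- points_within_radius(samples, p, r)
  phat <- mean(hit)
  rel_se <- if (phat > 0) sqrt((1 - phat) / (n_samples * phat)) else NA_real_
  tibble(radius = r, volume = vol_box * phat, relative_se = rel_se,
         n_samples = as.integer(n_samples), seed = as.integer(seed))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Prospected volumes for several radii with one shared sample stream
#'
#' Evaluates [mc_volume()] at each radius using a single bounding box (the
#' largest radius) and a single uniform sample stream, so the hit sets are
#' nested and the estimated volume is non-decreasing in `r` realisation by
#' realisation.
#'
#' @param positions tibble `east`, `north`, `z` (m).
#' @param radii detection radii (m), e.g. `c(1.5, 9, 18)`.
#' @param n_samples,seed see [mc_volume()].
#' @return A tibble with one row per radius.
#' @export
prospected_volumes <- function(positions, radii = c(1.5, 9, 18),
                               n_samples = 2e5, seed = 1L) {
  p <- as.matrix(positions[, c("east", "north", "z")])
  rmax <- max(radii)
  box <- rbind(apply(p, 2, min) - rmax, apply(p, 2, max) + rmax)
  bind_rows(lapply(sort(radii), function(r) {
    mc_volume(positions, r, n_samples = n_samples, seed = seed, box = box)
  }))
}

#' Prey-encounter density proxy
#'
#' The ratio between the PEE count and the prospected water volume, expressed
#' in micro-PEE per cubic metre.
#'
#' @param pee_count non-negative event count(s).
#' @param volume prospected volume(s), m^3, > 0.
#' @return Density in uPEE m^-3 (`NA` where volume is not positive).
#' @export
density_proxy <- function(pee_count, volume) {
  ifelse(is.finite(volume) & volume > 0, 1e6 * pee_count / volume, NA_real_)
}
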