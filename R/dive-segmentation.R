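# Depth-stream processing: pressure tags drift over a deployment, so surface
# readings wander away from zero; dives are maximal runs deeper than 15 m of
# the corrected series; the bottom phase of each dive is delimited from a
# degree-4 polynomial model of the vertical speed.

#' Zero-offset correction of a depth series
#'
#' Removes the slowly drifting pressure offset by taking the median reading of
#' every surface interval (raw depth below `surface_threshold`) and linearly
#' interpolating these per-interval offsets across the whole record before
#' subtracting. Within-dive depth differences are unchanged. A record with no
#' surface interval is corrected by its global minimum, with a warning.
#'
#' @param depth tibble with columns `time`, `depth` (m, positive down) at 1 Hz.
#' @param surface_threshold raw depth (m) below which a sample is treated as
#'   a surface reading for offset estimation.
#' @return A tibble `time`, `depth` with corrected depth.
#' @export
zero_offset_correct <- function(depth, surface_threshold = 10) {
  stopifnot(all(c("time", "depth") %in% names(depth)))
  d <- depth$depth
  runs <- true_runs(d < surface_threshold)
  if (nrow(runs) == 0) {
    warn("no surface interval found; correcting by the global minimum depth")
    return(tibble(time = depth$time, depth = d - min(d, na.rm = TRUE)))
  }
  centers <- (runs$start + runs$end) / 2
  offs <- map_dbl(seq_len(nrow(runs)),
                  function(k) median(d[runs$start[k]:runs$end[k]], na.rm = TRUE))
  offset <- if (nrow(runs) == 1) {
    rep(offs, length(d))
  } else {
    stats::approx(centers, offs, xout = seq_along(d), rule = 2)$y
  }
  tibble(time = depth$time, depth = d - offset)
}

#' Find dives in a corrected depth series
#'
#' A dive is a maximal run of samples strictly deeper than `threshold`
#' (default 15 m, a conservative cut that keeps brief sub-surface excursions
#' from counting as dives).
#'
#' @param depth tibble `time`, `depth` (corrected, m) at 1 Hz.
#' @param threshold dive depth threshold (m).
#' @return A tibble with one row per dive: `dive_id`, `start`, `end` (row
#'   indices), `start_time`, `end_time` (s), `max_depth` (m), and unset phase
#'   columns `descent_end`, `ascent_start` (see [delimit_bottom()]).
#' @export
find_dives <- function(depth, threshold = 15) {
  runs <- true_runs(depth$depth > threshold)
  if (nrow(runs) == 0) {
    return(tibble(dive_id = integer(), start = integer(), end = integer(),
                  start_time = numeric(), end_time = numeric(),
                  max_depth = numeric(), descent_end = integer(),
                  ascent_start = integer()))
  }
  runs |>
    mutate(
      dive_id = row_number(),
      start_time = depth$time[.data$start],
      end_time = depth$time[.data$end],
      max_depth = map_dbl(row_number(), function(k) {
        max(depth$depth[runs$start[k]:runs$end[k]])
      }),
      descent_end = NA_integer_,
      ascent_start = NA_integer_
    ) |>
    select("dive_id", "start", "end", "start_time", "end_time", "max_depth",
           "descent_end", "ascent_start")
}

#' Delimit the bottom phase of each dive
#'
#' The vertical speed (first difference of depth at 1 Hz) of each dive is
#' modelled by a least-squares polynomial of degree 4 in time; the bottom
#' phase is the contiguous below-threshold interval (absolute fitted vertical
#' speed under `v_threshold`) containing the deepest below-threshold sample
#' — the deepest sample outright in the usual case. Descent and
#' ascent are the remainder. The polynomial makes the delimitation sensitive
#' to the overall dive shape but not to small-scale steps in the profile.
#'
#' @param dives tibble from [find_dives()].
#' @param depth corrected depth tibble `time`, `depth`.
#' @param v_threshold vertical-speed threshold (m s^-1).
#' @return `dives` with `descent_end` and `ascent_start` filled (row indices
#'   into `depth`; the bottom phase is `descent_end..ascent_start`, empty when
#'   `descent_end` is `NA`) and `bottom_duration` (s).
#' @export
delimit_bottom <- function(dives, depth, v_threshold = 0.75) {
  if (nrow(dives) == 0) {
    return(mutate(dives, bottom_duration = numeric()))
  }
  res <- map(seq_len(nrow(dives)), function(k) {
    idx <- dives$start[k]:dives$end[k]
    n <- length(idx)
    if (n < 5) {
      warn(sprintf("dive %d too short for a degree-4 fit; empty bottom",
                   dives$dive_id[k]))
      return(c(NA_integer_, NA_integer_))
    }
    d <- depth$depth[idx]
    vz <- c(diff(d), NA)
    tt <- seq_len(n)
    ok <- is.finite(vz)
    fit <- lm(vz[ok] ~ poly(tt[ok], 4, raw = TRUE))
    vfit <- cbind(1, poly(tt, 4, raw = TRUE)) %*% coef(fit)
    low <- abs(as.numeric(vfit)) < v_threshold
    if (!any(low)) {
      return(c(NA_integer_, NA_integer_))
    }
    # anchor at the deepest below-threshold sample (middle of a tied run):
    # identical to the deepest sample in the usual case, but robust when the
    # depth maximum sits a few seconds past the fitted threshold crossing
    cand <- which(low)
    deepest <- cand[d[cand] >= max(d[cand]) - 1e-9]
    imax <- deepest[ceiling(length(deepest) / 2)]
    runs <- true_runs(low)
    hit <- runs |> filter(.data$start <= imax, .data$end >= imax)
    c(idx[hit$start[1]], idx[hit$end[1]])
  })
  dives |>
    mutate(
      descent_end = map_dbl(res, 1),
      ascent_start = map_dbl(res, 2),
      bottom_duration = ifelse(is.na(.data$descent_end), 0,
                               .data$ascent_start - .data$descent_end)
    )
}

#' Flag drift dives from bottom-phase summary statistics
#'
#' Drift dives are passive resting/digesting dives excluded from foraging
#' analysis. The stand-in criterion used here flags a dive when the bottom
#' phase lasts at least `min_duration` and shows both a low swimming-speed SD
#' (`speed_sd < speed_sd_max`) and a near-constant vertical rate
#' (`vz_sd < vz_sd_max`). Dives with missing speed are flagged `FALSE` with a
#' warning; dives with an empty bottom are `FALSE`.
#'
#' @param dives tibble with `bottom_duration` (s) from [delimit_bottom()].
#' @param speed_sd per-dive bottom swimming-speed SD (m s^-1).
#' @param vz_sd per-dive bottom vertical-rate SD (m s^-1).
#' @param speed_sd_max,vz_sd_max,min_duration criterion thresholds.
#' @return `dives` with a logical `is_drift` column.
#' @export
flag_drift_dives <- function(dives, speed_sd, vz_sd,
                             speed_sd_max = 0.15, vz_sd_max = 0.1,
                             min_duration = 200) {
  if (anyNA(speed_sd)) {
    warn("missing bottom speed for some dives; those are flagged as non-drift")
  }
  flag <- !is.na(speed_sd) & !is.na(vz_sd) &
    dives$bottom_duration >= min_duration &
    speed_sd < speed_sd_max & vz_sd < vz_sd_max
  mutate(dives, is_drift = flag)
}
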