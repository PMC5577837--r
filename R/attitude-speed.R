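# Body posture from the low-frequency (gravity/geomagnetic) component of the
# 5 Hz sensors, and swimming speed from the vertical speed and pitch in the
# steep dive phases, extrapolated to the whole dive through a flow-noise
# calibration.

#' Low-pass static component of a tri-axial stream
#'
#' Isolates the gravity-dominated (or, for magnetics, the geomagnetic)
#' component with a zero-phase order-3 low-pass Butterworth filter with a
#' normalized cut-off of 0.20 at 5 Hz (normalized by the sampling rate, the
#' same convention as [dynamic_acceleration()]). Stroking and strike
#' transients are removed; postural changes over tens of seconds pass.
#'
#' @param xyz tibble with `time` plus three axis columns (any names).
#' @param fs sampling rate (Hz).
#' @param cutoff nominal low-pass cut-off, normalized by the sampling rate.
#' @return A tibble with the same columns, filtered.
#' @export
static_acceleration <- function(xyz, fs = 5, cutoff = 0.20) {
  if (nrow(xyz) < 30 * fs) abort("need at least 30 s of data")
  axes <- setdiff(names(xyz), "time")
  out <- xyz
  for (a in axes) out[[a]] <- butter_filtfilt(xyz[[a]], fs, cutoff, "low", norm = "rate")
  as_tibble(out)
}

#' Pitch and roll from the static acceleration
#'
#' The direction of the gravity vector in body coordinates gives pitch (angle
#' of the longitudinal axis above the horizontal, nose-up positive) and roll
#' (rotation about the longitudinal axis, right-side-down positive):
#' `pitch = atan2(gx, sqrt(gy^2 + gz^2))`, `roll = atan2(-gy, gz)`. In the
#' gimbal case (gravity along the longitudinal axis) roll is set to 0 by
#' convention; a zero-norm static vector yields missing values.
#'
#' @param static tibble `time`, `ax`, `ay`, `az` (static acceleration, any
#'   consistent units).
#' @return A tibble `time`, `pitch`, `roll` (rad).
#' @export
pitch_roll <- function(static) {
  gx <- static$ax; gy <- static$ay; gz <- static$az
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  horiz <- sqrt(gy^2 + gz^2)
  pitch <- atan2(gx, horiz)
  roll <- ifelse(horiz < 1e-12, 0, atan2(-gy, gz))
  bad <- nrm < 1e-12
  pitch[bad] <- NA_real_
  roll[bad] <- NA_real_
  tibble(time = static$time, pitch = pitch, roll = roll)
}

#' Tilt-compensated heading from static magnetics
#'
#' De-rotates the body-frame magnetic vector by roll then pitch so its
#' horizontal components can be read off, and returns the heading clockwise
#' from magnetic north in `[0, 2*pi)`. A magnetic vector (near-)parallel to
#' gravity leaves the heading undefined (missing).
#'
#' @param attitude tibble `time`, `pitch`, `roll` from [pitch_roll()].
#' @param static_mag tibble `time`, `mx`, `my`, `mz` (low-passed magnetics on
#'   the same clock).
#' @return `attitude` with a `heading` column (rad).
#' @export
tilt_compensated_heading <- function(attitude, static_mag) {
  stopifnot(nrow(attitude) == nrow(static_mag))
  a <- attitude$pitch; r <- attitude$roll
  mx <- static_mag$mx; my <- static_mag$my; mz <- static_mag$mz
  # undo roll about the longitudinal axis
  m0y <- cos(r) * my + sin(r) * mz
  m0z <- -sin(r) * my + cos(r) * mz
  # undo pitch: horizontal-forward and vertical components
  mh <- cos(a) * mx - sin(a) * m0z
  hnorm <- sqrt(mh^2 + m0y^2)
  heading <- ifelse(hnorm < 1e-9, NA_real_, wrap_2pi(atan2(-m0y, mh)))
  mutate(attitude, heading = heading)
}

#' Swimming speed from vertical speed and pitch
#'
#' In the steep descent and ascent phases the through-water speed follows
#' from the pressure-derived vertical speed and the pitch angle,
#' `v_seal = v_z / sin(pitch)`, sign-corrected to be non-negative. Below
#' `min_pitch` the division blows up, so those samples are returned missing.
#'
#' @param data tibble with columns `v_z` (m s^-1, positive down) and `pitch`
#'   (rad), e.g. one row per second.
#' @param min_pitch minimum absolute pitch (rad) for a valid estimate.
#' @return `data` with a `v_seal` column (m s^-1, `NA` where guarded).
#' @export
speed_from_pitch <- function(data, min_pitch = 20 * pi / 180) {
  stopifnot(all(c("v_z", "pitch") %in% names(data)))
  ok <- is.finite(data$pitch) & abs(data$pitch) >= min_pitch & is.finite(data$v_z)
  v <- ifelse(ok, abs(data$v_z / sin(data$pitch)), NA_real_)
  mutate(data, v_seal = v)
}

#' Calibrate flow-noise level against swimming speed
#'
#' Fits the monotone relationship `level = a + b * log(speed)` by least
#' squares on paired samples (typically descent/ascent seconds where the
#' pitch-derived speed is valid), to be inverted for speed prediction over
#' the rest of the dive. Requires at least `min_pairs` complete pairs
#' spanning at least `min_range` m s^-1 of speed.
#'
#' @param pairs tibble with columns `level` and `speed`.
#' @param min_pairs,min_range calibration validity guards.
#' @return An object of class `noise_speed_cal` with coefficients `a`, `b`
#'   and residual SD; use [predict_speed()] to invert it.
#' @export
calibrate_noise_speed <- function(pairs, min_pairs = 100, min_range = 0.5) {
  ok <- complete.cases(pairs[, c("level", "speed")]) & pairs$speed > 0
  x <- pairs[ok, ]
  if (nrow(x) < min_pairs) {
    abort(sprintf("calibration needs >= %d pairs (got %d)", min_pairs, nrow(x)))
  }
  if (diff(range(x$speed)) < min_range) {
    abort(sprintf("calibration speed range below %.2f m s^-1: degenerate", min_range))
  }
  fit <- lm(level ~ log(speed), data = x)
  structure(list(
    a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
    sigma = summary(fit)$sigma, n = nrow(x)
  ), class = "noise_speed_cal")
}

#' @export
print.noise_speed_cal <- function(x, ...) {
  cat(sprintf("<noise_speed_cal> level = %.2f + %.2f log(speed); sigma %.3f, n %d\n",
              x$a, x$b, x$sigma, x$n))
  invisible(x)
}

#' Predict swimming speed from flow-noise level
#'
#' Inverts a [calibrate_noise_speed()] fit: `speed = exp((level - a) / b)`,
#' clipped to `[0, 3]` m s^-1. Missing levels give missing speeds.
#'
#' @param cal a `noise_speed_cal` object.
#' @param level numeric noise level series.
#' @return Numeric speed series (m s^-1).
#' @export
predict_speed <- function(cal, level) {
  stopifnot(inherits(cal, "noise_speed_cal"))
  pmin(pmax(exp((level - cal$a) / cal$b), 0), 3)
}
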