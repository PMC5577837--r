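# Shared fixtures and independent oracles used across the suite.

# Independent forward model of the attitude sensors, built from explicit
# rotation matrices (not the package's vectorised formulas): world ENU, yaw
# clockwise from north, pitch nose-up, roll right-side-down.
oracle_rotation <- function(pitch, roll, heading) {
  cz <- cos(-heading); sz <- sin(-heading)  # ENU yaw: clockwise from +north
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  cy <- cos(pitch); sy <- sin(pitch)
  # pitch raises the forward (y-in-yaw-frame) axis: rotate about the east axis
  Rx_pitch <- matrix(c(1, 0, 0, 0, cy, sy, 0, -sy, cy), 3, 3)
  cr <- cos(roll); sr <- sin(roll)
  Ry_roll <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  # columns: body x (forward), y (right), z (dorsal) in world coordinates
  base <- cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  Rz %*% Rx_pitch %*% Ry_roll %*% base
}

oracle_body_reading <- function(v_world, pitch, roll, heading) {
  as.numeric(crossprod(oracle_rotation(pitch, roll, heading), v_world))
}

# A 5 Hz accel/mag frame for a given 1 Hz attitude (noise-free).
render_attitude_frame <- function(pitch, roll, heading, inclination = -65 * pi / 180) {
  n <- length(pitch)
  t5 <- seq(0, n - 0.2, by = 0.2)
  p5 <- rep(pitch, each = 5); r5 <- rep(roll, each = 5); h5 <- rep(heading, each = 5)
  g <- t(vapply(seq_along(p5), function(i) {
    oracle_body_reading(c(0, 0, 9.81), p5[i], r5[i], h5[i])
  }, numeric(3)))
  mw <- c(0, cos(inclination), -sin(inclination))
  m <- t(vapply(seq_along(p5), function(i) {
    oracle_body_reading(mw, p5[i], r5[i], h5[i])
  }, numeric(3)))
  list(
    accel = tibble::tibble(time = t5, ax = g[, 1], ay = g[, 2], az = g[, 3]),
    mag = tibble::tibble(time = t5, mx = m[, 1], my = m[, 2], mz = m[, 3])
  )
}

# Brute-force hit test: is each sample within r of any track point?
brute_within <- function(samples, track, r) {
  apply(samples, 1, function(s) {
    any(sqrt(colSums((t(track) - s)^2)) <= r + 1e-12)
  })
}

# Quick noise-free simulation config for deterministic chains.
quiet_config <- function(seed = 1, ...) {
  sim_config(seed = seed, duty_cycle = 24,
             sensor_noise_sd = 0, attitude_noise_sd = 0, depth_noise_sd = 0,
             depth_offset_drift = 0, mag_noise_sd = 0, noise_level_sd = 0,
             ...)
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- abs(((a - b) + pi) %% (2 * pi) - pi)
  expect_lt(max(d), tol)
}
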