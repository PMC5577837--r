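# Forward sensor model: plans per-second kinematics for each dive, integrates
# the true track, realises a Poisson prey field around the track, then renders
# depth, tri-axial acceleration, tri-axial magnetics and a flow-noise level
# exactly as the analysis pipeline expects to read them.

#' Simulate a complete bio-logging deployment
#'
#' Generates a synthetic deployment under a [sim_config()]: true per-second
#' attitude, speed and 3D positions for a sequence of foraging (and optionally
#' drift) dives; prey encounters from a Poisson prey field inside the
#' configured depth layer; and forward-modelled sensor streams (depth at 1 Hz,
#' acceleration and magnetics at 5 Hz, duty-cycled flow-noise level, surface
#' GPS fixes displaced by the ocean current). The returned truth bundle lets
#' every downstream stage be tested by parameter recovery.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `ses_deployment` with elements
#'   \describe{
#'     \item{frame}{a `sensor_frame`: tibbles `depth`, `accel`, `mag`, `noise`.}
#'     \item{fixes}{tibble of GPS fixes (`time`, `lat`, `lon`).}
#'     \item{truth}{a `truth_bundle` list: `positions` (per-dive earth-frame
#'       east/north/z at 1 Hz), `attitude`, `series` (true depth and speed),
#'       `pee` (dive id and encounter time), `dives` (phase boundaries and
#'       drift flags), `prey_density`, `current`.}
#'   }
#' @examples
#' dep <- simulate_deployment(sim_config(seed = 7, n_dives = 2))
#' dep$truth$dives
#' @export
simulate_deployment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object")
  }
  set.seed(config$seed)

  order_drift <- c(rep(FALSE, config$n_dives), rep(TRUE, config$n_drift_dives))
  order_drift <- sample(order_drift)

  plans <- vector("list", length(order_drift))
  azimuth <- runif(1, 0, 2 * pi)
  for (k in seq_along(order_drift)) {
    # successive dives head off in gently rotated directions
    azimuth <- wrap_2pi(azimuth + rnorm(1, 0, 0.6))
    plans[[k]] <- if (order_drift[k]) {
      plan_drift_dive(config, azimuth)
    } else {
      plan_foraging_dive(config, azimuth)
    }
  }

  timeline <- assemble_timeline(plans, config)
  n <- nrow(timeline)
  tsec <- timeline$time

  # true water-relative track, forward-Euler at 1 Hz (the dead-reckoning
  # kinematics exactly)
  step_h <- timeline$speed * cos(timeline$pitch)
  de <- step_h * sin(timeline$heading)
  dn <- step_h * cos(timeline$heading)
  east_w <- c(0, cumsum(de[-n]))
  north_w <- c(0, cumsum(dn[-n]))
  east <- east_w + config$current_velocity[1] * tsec
  north <- north_w + config$current_velocity[2] * tsec
  z <- -timeline$depth

  dive_tbl <- attr(timeline, "dives")

  pee <- realize_prey_encounters(config, timeline, east, north, z, dive_tbl)

  sens <- render_sensors(config, timeline, pee)
  fixes <- render_fixes(config, timeline, east, north)

  pos <- tibble(
    dive_id = timeline$dive_id, time = tsec,
    east = east, north = north, z = z
  ) |> filter(.data$dive_id > 0L)

  truth <- structure(list(
    positions = pos,
    attitude = tibble(
      time = tsec, pitch = timeline$pitch,
      roll = timeline$roll, heading = timeline$heading
    ),
    series = tibble(time = tsec, depth = timeline$depth, speed = timeline$speed),
    pee = pee,
    dives = dive_tbl,
    prey_density = config$prey_intensity,
    current = config$current_velocity
  ), class = "truth_bundle")

  structure(list(frame = sens, fixes = fixes, truth = truth),
            class = "ses_deployment")
}

# -- dive planning ------------------------------------------------------------

ar1_speed <- function(n, config, mean = config$swim_speed_mean,
                      sd = config$swim_speed_sd, phi = 0.95) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  dev <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  pmin(pmax(mean + dev, 0.8), 3.5)
}

ramp_env <- function(n, ramp) {
  if (n <= 1) return(rep(1, n))
  t <- seq_len(n)
  pmin(1, t / max(ramp, 1), (n - t + 1) / max(ramp, 1))
}

# One foraging dive: smooth descent at -descent_pitch to the layer, a bottom
# phase oscillating vertically inside the layer while heading mostly along one
# azimuth, smooth ascent back to the surface.
plan_foraging_dive <- function(config, azimuth) {
  # enter near the layer centre; the vertical oscillation amplitude (0.35 x
  # thickness) plus this entry offset stays inside the half-thickness, so the
  # bottom phase samples its prey layer as the layer hypothesis posits
  target <- config$layer_center_depth +
    runif(1, -0.1, 0.1) * config$layer_thickness
  ramp <- config$transition_ramp
  a0 <- config$descent_pitch

  # descent: step until the target depth is reached
  h <- ceiling(3 * target / (config$swim_speed_mean * sin(a0))) + 60L
  v_desc <- ar1_speed(h, config)
  pitch_desc <- numeric(0)
  depth <- 0
  i <- 1L
  while (depth < target && i <= h) {
    p <- -a0 * min(1, i / ramp)
    pitch_desc[i] <- p
    depth <- depth + v_desc[i] * sin(-p) * 1
    i <- i + 1L
  }
  nd <- length(pitch_desc)

  # bottom: vertical sinusoid inside the layer with a weak depth-restoring
  # term (seals track their prey layer), wiggly heading
  nb <- max(120L, round(rnorm(1, config$bottom_duration_mean,
                              config$bottom_duration_sd)))
  period <- 120
  amp_depth <- 0.3 * config$layer_thickness
  sin_a <- min(0.9, amp_depth * 2 * pi / (config$swim_speed_mean * period))
  a_bot <- asin(sin_a)
  phase0 <- runif(1, 0, 2 * pi)
  env <- ramp_env(nb, ramp)
  v_bot <- ar1_speed(nb, config)
  centre <- config$layer_center_depth
  pitch_bot <- numeric(nb)
  d <- depth
  for (t in seq_len(nb)) {
    p <- a_bot * sin(2 * pi * t / period + phase0) * env[t] +
      max(-0.25, min(0.25, 0.01 * (d - centre)))
    pitch_bot[t] <- p
    d <- d + v_bot[t] * sin(-p)
  }
  wiggle <- rolling_mean(cumsum(rnorm(nb, 0, config$bottom_turn_sd)), 7)
  heading_bot <- azimuth + (1 - config$bottom_linearity) * wiggle
  depth_end <- d

  # ascent: ramp to +descent_pitch, hold until back at the surface
  ha <- ceiling(3 * depth_end / (config$swim_speed_mean * sin(a0))) + 60L
  v_asc <- ar1_speed(ha, config)
  pitch_asc <- numeric(0)
  d <- depth_end
  i <- 1L
  while (d > 0.5 && i <= ha) {
    p <- a0 * min(1, i / ramp)
    pitch_asc[i] <- p
    d <- d - v_asc[i] * sin(p)
    i <- i + 1L
  }
  na <- length(pitch_asc)

  tibble(
    pitch = c(pitch_desc, pitch_bot, pitch_asc),
    heading = wrap_2pi(c(rep(azimuth, nd), heading_bot,
                         rep(heading_bot[nb], na))),
    speed = c(v_desc[seq_len(nd)], v_bot, v_asc[seq_len(na)]),
    phase = rep(c("descent", "bottom", "ascent"), c(nd, nb, na)),
    stroking = TRUE,
    is_drift = FALSE
  )
}

# One drift dive: active descent, then a passive low-speed sink (no stroking,
# near-constant vertical rate), then active ascent.
plan_drift_dive <- function(config, azimuth) {
  active <- plan_foraging_dive(config, azimuth)
  nd_bot <- sum(active$phase == "bottom")
  drift_sink <- 0.3                       # m s^-1 passive sinking rate
  drift_pitch <- -1.03                    # rad, head-down glide
  v_drift <- drift_sink / sin(-drift_pitch)
  active |>
    mutate(
      idx = row_number(),
      speed = ifelse(.data$phase == "bottom",
                     pmax(v_drift + rnorm(n(), 0, 0.01), 0.05), .data$speed),
      pitch = ifelse(.data$phase == "bottom", drift_pitch, .data$pitch),
      heading = ifelse(.data$phase == "bottom", azimuth, .data$heading),
      stroking = .data$phase != "bottom",
      is_drift = TRUE
    ) |>
    select(-"idx")
}

# Concatenate surface intervals and dives into one 1 Hz timeline; attach the
# per-dive truth table (indices are 1-based rows of the timeline).
assemble_timeline <- function(plans, config) {
  surf <- function(n, heading) {
    tibble(pitch = 0, heading = heading, speed = 0, phase = "surface",
           stroking = FALSE, is_drift = FALSE)[rep(1, n), ]
  }
  ns <- max(30L, round(config$surface_duration))
  pieces <- list(surf(ns, plans[[1]]$heading[1]))
  dive_rows <- list()
  row0 <- ns
  for (k in seq_along(plans)) {
    pl <- plans[[k]]
    npl <- nrow(pl)
    bottom <- range(which(pl$phase == "bottom"))
    dive_rows[[k]] <- tibble(
      dive_id = k,
      start = row0 + 1L, end = row0 + npl,
      bottom_start = row0 + bottom[1], bottom_end = row0 + bottom[2],
      is_drift = pl$is_drift[1]
    )
    pieces[[length(pieces) + 1L]] <- pl
    pieces[[length(pieces) + 1L]] <- surf(ns, pl$heading[npl])
    row0 <- row0 + npl + ns
  }
  tl <- bind_rows(pieces)
  # animals change posture smoothly: blend the planned pitch across phase
  # boundaries so rendered sensors carry no step discontinuities
  tl$pitch <- rolling_mean(tl$pitch, 9)
  tl$dive_id <- 0L
  dives <- bind_rows(dive_rows)
  for (k in seq_len(nrow(dives))) {
    tl$dive_id[dives$start[k]:dives$end[k]] <- dives$dive_id[k]
  }
  # integrate true depth (surface clamped at 0)
  n <- nrow(tl)
  dz <- tl$speed * sin(-tl$pitch)
  depth <- numeric(n)
  for (i in 2:n) {
    depth[i] <- if (tl$phase[i] == "surface") 0 else max(depth[i - 1] + dz[i - 1], 0)
  }
  tl$depth <- depth
  tl$time <- seq_len(n) - 1
  tl$roll <- rep(0, n)
  attr(tl, "dives") <- dives
  tl
}

# -- prey field ---------------------------------------------------------------

# Poisson prey field realised lazily per dive inside the layer slab; an
# encounter is the first second a prey point lies within detection_radius of
# the true (earth-frame) track. Drift dives yield no encounters.
realize_prey_encounters <- function(config, timeline, east, north, z, dives) {
  out <- list()
  r <- config$detection_radius
  slab <- c(-(config$layer_center_depth + config$layer_thickness / 2),
            -(config$layer_center_depth - config$layer_thickness / 2))
  for (k in seq_len(nrow(dives))) {
    if (dives$is_drift[k] || config$prey_intensity <= 0) next
    idx <- dives$start[k]:dives$end[k]
    near <- idx[z[idx] >= slab[1] - r & z[idx] <= slab[2] + r]
    if (!length(near)) next
    lo <- c(min(east[near]) - r, min(north[near]) - r,
            max(slab[1], min(z[near]) - r))
    hi <- c(max(east[near]) + r, max(north[near]) + r,
            min(slab[2], max(z[near]) + r))
    vol <- prod(pmax(hi - lo, 0))
    if (vol <= 0) next
    n_prey <- rpois(1, config$prey_intensity * vol)
    if (n_prey == 0) next
    prey <- cbind(runif(n_prey, lo[1], hi[1]),
                  runif(n_prey, lo[2], hi[2]),
                  runif(n_prey, lo[3], hi[3]))
    path <- cbind(east[near], north[near], z[near])
    hit_t <- first_hit_times(prey, path, r)
    hit <- which(is.finite(hit_t))
    if (length(hit)) {
      out[[length(out) + 1L]] <- tibble(
        dive_id = dives$dive_id[k],
        time = timeline$time[near[hit_t[hit]]]
      )
    }
  }
  if (!length(out)) {
    return(tibble(dive_id = integer(), time = numeric()))
  }
  bind_rows(out) |> arrange(.data$time)
}

# For each prey point, index (into the path rows) of the first sample within
# radius r, or NA. Brute-force distances, chunked over prey.
first_hit_times <- function(prey, path, r) {
  np <- nrow(prey)
  res <- rep(NA_integer_, np)
  p2 <- rowSums(path^2)
  chunk <- max(1L, floor(2e6 / nrow(path)))
  for (s in seq(1L, np, by = chunk)) {
    e <- min(s + chunk - 1L, np)
    q <- prey[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), p2, "+") - 2 * tcrossprod(q, path)
    within <- d2 <= r^2 + 1e-12
    res[s:e] <- apply(within, 1, function(w) if (any(w)) which(w)[1] else NA_integer_)
  }
  res
}

# -- sensor rendering ---------------------------------------------------------

render_sensors <- function(config, timeline, pee) {
  n <- nrow(timeline)
  t1 <- timeline$time
  t5 <- seq(0, n - 0.2, by = 0.2)

  # depth with pressure-offset drift and sensor noise
  depth_obs <- timeline$depth +
    config$depth_offset_drift * t1 / 3600 +
    rnorm(n, 0, config$depth_noise_sd)

  # 5 Hz attitude: interpolate angles (heading unwrapped), then angle-space
  # noise so the rendered gravity keeps unit norm
  unwrap <- signal::unwrap(timeline$heading)
  pitch5 <- stats::approx(t1, timeline$pitch, t5, rule = 2)$y
  roll5 <- stats::approx(t1, timeline$roll, t5, rule = 2)$y
  head5 <- stats::approx(t1, unwrap, t5, rule = 2)$y
  if (config$attitude_noise_sd > 0) {
    pitch5 <- pitch5 + rnorm(5 * n, 0, config$attitude_noise_sd)
    roll5 <- roll5 + rnorm(5 * n, 0, config$attitude_noise_sd)
    head5 <- head5 + rnorm(5 * n, 0, config$attitude_noise_sd)
  }

  acc <- STANDARD_GRAVITY * gravity_body(pitch5, roll5)
  # rhythmic propulsive stroking (below the 2.4 Hz detector band) while
  # actively swimming, plus always-on broadband sensor noise
  stroking5 <- rep(timeline$stroking & timeline$speed > 0.5, each = 5)
  if (config$accel_noise_sd > 0) {
    amp <- config$accel_noise_sd * sqrt(2)
    for (j in 1:3) {
      acc[, j] <- acc[, j] + amp * stroking5 *
        sin(2 * pi * config$stroke_frequency * t5 + runif(1, 0, 2 * pi))
    }
  }
  if (config$sensor_noise_sd > 0) {
    acc <- acc + rnorm(3 * 5 * n, 0, config$sensor_noise_sd)
  }
  acc <- acc + render_bursts(config, t5, pee$time)

  mag <- mag_body(pitch5, roll5, wrap_2pi(head5),
                  config$mag_inclination, config$mag_intensity)
  if (config$mag_noise_sd > 0) {
    mag <- mag + rnorm(3 * 5 * n, 0, config$mag_noise_sd)
  }

  # duty-cycled flow-noise level, log-linear in through-water speed
  on <- (t1 %% (12 * 3600)) < config$duty_cycle * 3600
  level <- config$noise_cal_intercept +
    config$noise_cal_slope * log(pmax(timeline$speed, 0.05)) +
    rnorm(n, 0, config$noise_level_sd)
  level[!on] <- NA_real_

  structure(list(
    depth = tibble(time = t1, depth = depth_obs),
    accel = tibble(time = t5, ax = acc[, 1], ay = acc[, 2], az = acc[, 3]),
    mag = tibble(time = t5, mx = mag[, 1], my = mag[, 2], mz = mag[, 3]),
    noise = tibble(time = t1, level = level)
  ), class = "sensor_frame", fs_fast = 5,
     origin = c(lat = config$origin_lat, lon = config$origin_lon))
}

# High-frequency strike transient on all three axes for burst_duration
# seconds after each encounter: a sign-alternating carrier near Nyquist with
# a random magnitude envelope shared across axes (a strike jerks the whole
# body, so the three axes see a common activity profile scaled per axis).
render_bursts <- function(config, t5, pee_times) {
  burst <- matrix(0, length(t5), 3)
  if (!length(pee_times) || config$burst_amplitude <= 0) return(burst)
  for (t0 in pee_times) {
    k <- which(t5 >= t0 & t5 < t0 + config$burst_duration)
    if (!length(k)) next
    # magnitudes fluctuate (ragged activity profile) but are floored so each
    # strike keeps the nominal signal-to-noise ratio
    w <- pmax(abs(rnorm(length(k))), 0.5) * (-1)^(seq_along(k))
    for (j in 1:3) {
      burst[k, j] <- burst[k, j] +
        config$burst_amplitude * w * runif(1, 0.8, 1.25)
    }
  }
  burst
}

render_fixes <- function(config, timeline, east, north) {
  runs <- true_runs(timeline$phase == "surface")
  # one fix at the first and one at the last second of each surface interval
  idx <- sort(unique(c(runs$start, runs$end)))
  origin <- c(lat = config$origin_lat, lon = config$origin_lon)
  ll <- local_to_gps(east[idx], north[idx], origin)
  tibble(time = timeline$time[idx], lat = ll$lat, lon = ll$lon)
}

#' @export
print.ses_deployment <- function(x, ...) {
  nd <- nrow(x$truth$dives)
  cat(sprintf("<ses_deployment> %d dives (%d drift), %d s, %d GPS fixes, %d prey encounters\n",
              nd, sum(x$truth$dives$is_drift), nrow(x$frame$depth),
              nrow(x$fixes), nrow(x$truth$pee)))
  invisible(x)
}
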