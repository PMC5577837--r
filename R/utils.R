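# Internal helpers shared across modules. Conventions (documented in the
# vignette): angles in radians internally; depth positive down; local frame is
# East-North-Up with z = -depth; pitch positive nose-up; roll positive
# right-side-down; heading clockwise from magnetic north in [0, 2*pi).

wrap_2pi <- function(x) {
  x %% (2 * pi)
}

# Body axes in the world (ENU) frame for a given attitude. Returns a list of
# three unit vectors: x forward (longitudinal), y right (lateral), z dorsal.
body_axes <- function(pitch, roll, heading) {
  sa <- sin(pitch); ca <- cos(pitch)
  sp <- sin(heading); cp <- cos(heading)
  sr <- sin(roll); cr <- cos(roll)
  xb <- cbind(ca * sp, ca * cp, sa)
  y0 <- cbind(cp, -sp, 0)
  z0 <- cbind(-sa * sp, -sa * cp, ca)
  yb <- cr * y0 - sr * z0
  zb <- sr * y0 + cr * z0
  list(x = xb, y = yb, z = zb)
}

# Project a world (ENU) vector onto body axes -> matrix with one row per
# sample and columns (x, y, z) in body coordinates.
world_to_body <- function(v_world, pitch, roll, heading) {
  ax <- body_axes(pitch, roll, heading)
  if (is.null(dim(v_world))) {
    v_world <- matrix(v_world, nrow = length(pitch), ncol = 3, byrow = TRUE)
  }
  cbind(
    rowSums(v_world * ax$x),
    rowSums(v_world * ax$y),
    rowSums(v_world * ax$z)
  )
}

# Gravity reading (g units) of a noise-free accelerometer at the attitude.
gravity_body <- function(pitch, roll) {
  cbind(sin(pitch), -sin(roll) * cos(pitch), cos(roll) * cos(pitch))
}

# Magnetic field in body coordinates given heading and field (unit intensity,
# inclination positive down).
mag_body <- function(pitch, roll, heading, inclination, intensity = 1) {
  m_world <- intensity * c(0, cos(inclination), -sin(inclination))
  world_to_body(m_world, pitch, roll, heading)
}

# Zero-phase order-3 Butterworth filter. cutoff in Hz, fs in Hz. `norm`
# selects the normalization convention of the nominal cutoff: "rate" divides
# by the sampling rate (the convention of the original tag-processing
# tooling; a nominal 2.4 at fs = 5 is 0.48 of Nyquist), "nyquist" by fs/2.
butter_filtfilt <- function(x, fs, cutoff, type = c("low", "high"),
                            norm = c("rate", "nyquist")) {
  type <- match.arg(type)
  norm <- match.arg(norm)
  w <- if (norm == "rate") cutoff / fs else cutoff / (fs / 2)
  if (w <= 0 || w >= 1) {
    abort(sprintf("cutoff %.3g Hz is outside (0, Nyquist) for fs = %g Hz", cutoff, fs))
  }
  n_min <- 3 * 2 * 3 + 1  # filtfilt edge transient of an order-3 filter
  n <- length(x)
  if (n <= n_min) {
    abort(sprintf("series too short to filter (need > %d samples)", n_min))
  }
  bf <- signal::butter(3, w, type = type)
  # demeaning plus odd-reflection padding tames the zero-initial-state
  # startup transient (exact for constant input)
  mu <- mean(x)
  x <- x - mu
  pad <- min(n - 1, ceiling(6 / w))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  if (type == "low") y + mu else y
}

# Centered rolling standard deviation with partial windows at the edges.
rolling_sd <- function(x, width) {
  zoo::rollapply(x, width = width, FUN = sd, align = "center", partial = TRUE)
}

rolling_mean <- function(x, width) {
  zoo::rollapply(x, width = width, FUN = mean, align = "center", partial = TRUE)
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) of indices.
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Local equirectangular projection anchored at `origin` (lat, lon in degrees).
# Returns east/north in metres. Inverse provided for the simulator.
gps_to_local <- function(fixes, origin = NULL) {
  stopifnot(all(c("lat", "lon") %in% names(fixes)))
  if (is.null(origin)) {
    origin <- c(lat = fixes$lat[1], lon = fixes$lon[1])
  }
  lat0 <- origin[["lat"]] * pi / 180
  fixes |>
    mutate(
      east = (.data$lon - origin[["lon"]]) * pi / 180 * EARTH_RADIUS * cos(lat0),
      north = (.data$lat - origin[["lat"]]) * pi / 180 * EARTH_RADIUS
    ) |>
    as_tibble()
}

local_to_gps <- function(east, north, origin) {
  lat0 <- origin[["lat"]] * pi / 180
  tibble(
    lat = origin[["lat"]] + north / EARTH_RADIUS * 180 / pi,
    lon = origin[["lon"]] + east / (EARTH_RADIUS * cos(lat0)) * 180 / pi
  )
}

# Linear interpolation of internal NA runs no longer than max_gap; returns
# NULL if a longer gap (or a leading/trailing gap) remains.
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2) return(NULL)
  runs <- true_runs(is.na(x))
  if (any(runs$start == 1L) || any(runs$end == length(x))) return(NULL)
  if (any(runs$end - runs$start + 1L > max_gap)) return(NULL)
  stats::approx(idx, x[idx], xout = seq_along(x))$y
}
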