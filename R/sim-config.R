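#' Simulation configuration for a synthetic deployment
#'
#' Bundles every parameter of the forward sensor model into a validated list.
#' Defaults emulate a post-breeding female southern elephant seal foraging on
#' a mesopelagic prey layer: dives to roughly 400-500 m, bottom phases of
#' ~500 s dominated by one horizontal direction, prey distributed as a Poisson
#' point field inside a depth layer, short tri-axial acceleration bursts at
#' prey encounters, duty-cycled acoustic sampling (three hours on per 12 h)
#' and a constant ocean current displacing the animal between GPS fixes.
#'
#' @param seed integer seed; the same seed reproduces the deployment
#'   bit-identically.
#' @param n_dives number of active foraging dives.
#' @param n_drift_dives number of passive drift dives interleaved at random.
#' @param layer_center_depth,layer_thickness centre (m) and vertical thickness
#'   (m) of the prey layer slab.
#' @param prey_intensity prey per cubic metre inside the layer.
#' @param detection_radius radius (m) within which a prey point triggers an
#'   encounter.
#' @param bottom_linearity fraction in \[0, 1\] of bottom-phase motion along
#'   one fixed azimuth; 1 gives a perfectly straight horizontal course.
#' @param current_velocity length-2 numeric, (east, north) current in m s^-1.
#' @param swim_speed_mean,swim_speed_sd mean and AR(1) innovation SD of the
#'   through-water swimming speed (m s^-1).
#' @param accel_noise_sd RMS amplitude (m s^-2) of the rhythmic propulsive
#'   stroking signal added to each accelerometer axis while actively swimming.
#' @param stroke_frequency stroking frequency (Hz), below the detector's
#'   high-pass band as in real swimming.
#' @param sensor_noise_sd SD (m s^-2) of the always-on broadband
#'   accelerometer sensor noise.
#' @param burst_amplitude,burst_duration amplitude (m s^-2) and duration (s)
#'   of the high-frequency acceleration transient rendered at each prey
#'   encounter.
#' @param attitude_noise_sd SD (rad) of angle-space noise applied to pitch,
#'   roll and heading before rendering sensors (keeps the gravity norm exact).
#' @param mag_inclination,mag_intensity magnetic inclination (rad, positive
#'   down; negative in the southern hemisphere) and field intensity
#'   (arbitrary units).
#' @param mag_noise_sd magnetometer noise SD (field units).
#' @param duty_cycle hours of acoustic recording per 12-h period; 0 disables
#'   the flow-noise stream entirely.
#' @param descent_pitch magnitude (rad) of the descent/ascent pitch.
#' @param bottom_duration_mean,bottom_duration_sd bottom-phase duration
#'   distribution (s).
#' @param surface_duration surface interval between dives (s).
#' @param transition_ramp duration (s) of the smooth pitch ramp between dive
#'   phases.
#' @param bottom_turn_sd heading random-walk step SD (rad s^-1) before scaling
#'   by `1 - bottom_linearity`.
#' @param depth_offset_drift linear pressure-offset drift (m per hour) added
#'   to the rendered depth, removed later by the zero-offset correction.
#' @param depth_noise_sd depth sensor noise SD (m).
#' @param noise_cal_intercept,noise_cal_slope,noise_level_sd parameters of the
#'   synthetic flow-noise level: `level = a + b * log(speed) + N(0, sd)`.
#' @param origin_lat,origin_lon deployment origin (decimal degrees).
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_deployment()]
#' @export
sim_config <- function(seed = 1L,
                       n_dives = 8L,
                       n_drift_dives = 0L,
                       layer_center_depth = 450,
                       layer_thickness = 50,
                       prey_intensity = 7e-4,
                       detection_radius = 1.5,
                       bottom_linearity = 0.9,
                       current_velocity = c(0.1, 0.05),
                       swim_speed_mean = 2.0,
                       swim_speed_sd = 0.3,
                       accel_noise_sd = 0.2,
                       stroke_frequency = 0.7,
                       sensor_noise_sd = 0.02,
                       burst_amplitude = 1.2,
                       burst_duration = 1.5,
                       attitude_noise_sd = 0.01,
                       mag_inclination = -65 * pi / 180,
                       mag_intensity = 1,
                       mag_noise_sd = 0.005,
                       duty_cycle = 3,
                       descent_pitch = 50 * pi / 180,
                       bottom_duration_mean = 500,
                       bottom_duration_sd = 100,
                       surface_duration = 120,
                       transition_ramp = 10,
                       bottom_turn_sd = 0.1,
                       depth_offset_drift = 0.3,
                       depth_noise_sd = 0.05,
                       noise_cal_intercept = 60,
                       noise_cal_slope = 20,
                       noise_level_sd = 0.5,
                       origin_lat = -49.35,
                       origin_lon = 70.22) {
  cfg <- as.list(environment())
  num <- unlist(cfg[setdiff(names(cfg), character(0))], use.names = TRUE)
  if (any(!is.finite(num))) {
    abort("sim_config: all configuration values must be finite")
  }
  if (cfg$prey_intensity < 0) abort("prey_intensity must be >= 0")
  if (cfg$bottom_linearity < 0 || cfg$bottom_linearity > 1) {
    abort("bottom_linearity must lie in [0, 1]")
  }
  if (cfg$layer_thickness <= 0) abort("layer_thickness must be > 0")
  if (cfg$detection_radius <= 0) abort("detection_radius must be > 0")
  if (length(cfg$current_velocity) != 2) {
    abort("current_velocity must be length 2 (east, north)")
  }
  if (cfg$n_dives < 1) abort("n_dives must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may appear in the file; missing fields take
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    abort(paste0("unknown sim_config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]], digits = 4), collapse = ", ")))
  }
  invisible(x)
}
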