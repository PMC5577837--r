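# End-to-end orchestration: raw sensor frame + GPS fixes -> per-dive table of
# bottom-phase shape metrics, prospected volumes and density proxies. Stage
# failures abort the affected dive (with a logged warning), never the run.

#' Pipeline parameters
#'
#' Collects every stage parameter with its default. Angles are given in
#' degrees at this surface and converted to radians internally.
#'
#' @param dive_threshold dive depth threshold (m).
#' @param surface_threshold raw-depth surface cut for the zero-offset
#'   correction (m).
#' @param v_threshold bottom-phase vertical-speed threshold (m s^-1).
#' @param hp_cutoff,lp_cutoff high-/low-pass Butterworth cut-offs (Hz).
#' @param min_pitch_deg minimum |pitch| (degrees) for pitch-derived speed.
#' @param max_speed_gap longest speed gap (s) bridged by interpolation.
#' @param radii detection radii (m) for the prospected volume.
#' @param n_samples Monte-Carlo samples per dive.
#' @param seed base seed for the Monte-Carlo stage (offset by dive id).
#' @param drift_speed_sd_max,drift_vz_sd_max,drift_min_duration drift-dive
#'   criterion, see [flag_drift_dives()].
#' @param cal_min_pairs,cal_min_range flow-noise calibration guards.
#' @return A named list of class `pipeline_control`.
#' @export
pipeline_control <- function(dive_threshold = 15,
                             surface_threshold = 10,
                             v_threshold = 0.75,
                             hp_cutoff = 2.4,
                             lp_cutoff = 0.20,
                             min_pitch_deg = 20,
                             max_speed_gap = 5,
                             radii = c(1.5, 9, 18),
                             n_samples = 2e5,
                             seed = 1L,
                             drift_speed_sd_max = 0.15,
                             drift_vz_sd_max = 0.1,
                             drift_min_duration = 200,
                             cal_min_pairs = 100,
                             cal_min_range = 0.5) {
  structure(as.list(environment()), class = "pipeline_control")
}

empty_pipeline_table <- function() {
  tibble(dive_id = integer(), start_time = numeric(), end_time = numeric(),
         max_depth = numeric(), mean_depth = numeric(),
         total_dispersion = numeric(), mc1_dispersion = numeric(),
         horizontality = numeric(), mc1_horizontal_extent = numeric(),
         mc1_vertical_extent = numeric(), horizontal_width = numeric(),
         vertical_width = numeric(), speed_sd = numeric(),
         bottom_duration = numeric(), pee_count = integer())
}

#' Run the full analysis pipeline on one deployment
#'
#' Zero-offset corrects the depth, segments dives and bottom phases, detects
#' prey-encounter events, estimates attitude and speed (pitch-derived in the
#' steep phases, flow-noise-predicted elsewhere), dead-reckons and closes a
#' 3D track per dive, computes bottom-phase shape metrics, Monte-Carlo
#' prospected volumes and density proxies, and drops drift dives and dives
#' without a reconstructable path (e.g. no acoustic coverage, so no bottom
#' speed).
#'
#' @param frame a `sensor_frame`.
#' @param fixes GPS fix tibble (`time`, `lat`, `lon`).
#' @param params a [pipeline_control()] list.
#' @return A tibble with one row per retained dive: dive bounds, shape
#'   metrics, `volume_<r>` and `density_<r>` per radius. The attribute
#'   `params_hash` records the parameter provenance.
#' @export
run_pipeline <- function(frame, fixes, params = pipeline_control()) {
  validate_sensor_frame(frame)
  if (nrow(frame$depth) < 60) {
    if (nrow(frame$depth) > 0) warn("record shorter than 60 s; nothing to analyse")
    return(finish_table(empty_pipeline_table(), params))
  }

  depth_c <- zero_offset_correct(frame$depth, params$surface_threshold)
  dives <- find_dives(depth_c, params$dive_threshold) |>
    delimit_bottom(depth_c, params$v_threshold)
  if (nrow(dives) == 0) return(finish_table(empty_pipeline_table(), params))

  att <- attitude_1hz(frame, params)
  spd <- speed_series(frame, depth_c, dives, att, params)
  if (all(is.na(spd$v_seal))) {
    warn("no usable speed anywhere (acoustic duty cycle off?); empty table")
    return(finish_table(empty_pipeline_table(), params))
  }

  events <- detect_pee_events(frame, dives, fs = attr(frame, "fs_fast") %||% 5,
                              cutoff = params$hp_cutoff)

  origin <- attr(frame, "origin")
  if (is.null(origin) || anyNA(origin)) {
    origin <- c(lat = fixes$lat[1], lon = fixes$lon[1])
  }
  fixes_en <- gps_to_local(fixes, origin)

  rows <- map(seq_len(nrow(dives)), function(k) {
    tryCatch(pipeline_dive_row(k, dives, depth_c, att, spd, events, fixes_en, params),
             error = function(e) {
               warn(sprintf("dive %d dropped: %s", dives$dive_id[k], conditionMessage(e)))
               NULL
             })
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(finish_table(empty_pipeline_table(), params))
  out <- flag_drift_dives(out, out$speed_sd_window, out$vz_sd,
                          params$drift_speed_sd_max, params$drift_vz_sd_max,
                          params$drift_min_duration) |>
    filter(!.data$is_drift) |>
    select(-"is_drift", -"vz_sd", -"speed_sd_window")
  finish_table(out, params)
}

# Minimum SDs of speed and vertical rate over sliding 200-s windows
# (whole-series SDs if the bottom is shorter than one window).
quietest_window_sds <- function(speed, vz, window = 200) {
  if (length(speed) < window + 1) {
    return(c(sd(speed, na.rm = TRUE), sd(vz, na.rm = TRUE)))
  }
  sp <- zoo::rollapply(speed, window, sd, na.rm = TRUE, align = "left")
  vr <- zoo::rollapply(vz, window, sd, na.rm = TRUE, align = "left")
  n <- min(length(sp), length(vr))
  both <- pmax(sp[seq_len(n)] / 0.15, vr[seq_len(n)] / 0.1)
  i <- which.min(both)
  c(sp[i], vr[i])
}

finish_table <- function(tbl, params) {
  attr(tbl, "params_hash") <- rlang::hash(unclass(params))
  tbl
}

# 1 Hz attitude from the low-passed 5 Hz sensors, sampled at integer seconds.
attitude_1hz <- function(frame, params) {
  fs <- attr(frame, "fs_fast") %||% 5
  st_acc <- static_acceleration(frame$accel, fs, params$lp_cutoff)
  st_mag <- static_acceleration(frame$mag, fs, params$lp_cutoff)
  att5 <- tilt_compensated_heading(pitch_roll(st_acc), st_mag)
  att5[seq(1, nrow(att5), by = fs), ]
}

# Combined speed series: pitch-derived where |pitch| is steep, flow-noise
# predicted elsewhere (when the calibration succeeds).
speed_series <- function(frame, depth_c, dives, att, params) {
  n <- nrow(depth_c)
  v_z <- c(diff(depth_c$depth), NA_real_)
  min_pitch <- params$min_pitch_deg * pi / 180
  sp <- speed_from_pitch(tibble(v_z = v_z, pitch = att$pitch), min_pitch)
  in_dive <- rep(FALSE, n)
  for (k in seq_len(nrow(dives))) in_dive[dives$start[k]:dives$end[k]] <- TRUE
  pairs <- tibble(level = frame$noise$level, speed = sp$v_seal)[in_dive, ]
  cal <- tryCatch(
    calibrate_noise_speed(pairs, params$cal_min_pairs, params$cal_min_range),
    error = function(e) {
      warn(paste0("flow-noise calibration failed: ", conditionMessage(e)))
      NULL
    })
  v_noise <- if (is.null(cal)) rep(NA_real_, n) else predict_speed(cal, frame$noise$level)
  v <- ifelse(is.finite(sp$v_seal), sp$v_seal, v_noise)
  tibble(time = depth_c$time, v_seal = v,
         source = ifelse(is.finite(sp$v_seal), "pitch_derived",
                         ifelse(is.finite(v_noise), "noise_predicted", NA)))
}

pipeline_dive_row <- function(k, dives, depth_c, att, spd, events, fixes_en, params) {
  idx <- dives$start[k]:dives$end[k]
  if (is.na(dives$descent_end[k])) abort("empty bottom phase")
  anchor_row <- max(which(fixes_en$time <= dives$start_time[k]))
  closing_row <- which(fixes_en$time >= dives$end_time[k])[1]
  if (!is.finite(anchor_row) || is.na(closing_row)) abort("missing GPS fix")

  track <- integrate_path(
    att[idx, ], tibble(time = spd$time[idx], v_seal = spd$v_seal[idx]),
    depth_c[idx, ],
    anchor = c(fixes_en$east[anchor_row], fixes_en$north[anchor_row]),
    max_gap = params$max_speed_gap
  )
  track <- close_track(track, c(fixes_en$east[closing_row],
                                fixes_en$north[closing_row]))

  bidx <- dives$descent_end[k]:dives$ascent_start[k]
  brows <- match(bidx, idx)
  bpos <- track[brows, c("east", "north", "z")]
  bspeed <- spd$v_seal[bidx]
  bt <- depth_c$time[bidx]
  pee_n <- 0L
  if (nrow(events) > 0) {
    mid <- (events$start_time + events$end_time) / 2
    pee_n <- sum(mid >= bt[1] & mid <= bt[length(bt)])
  }
  met <- shape_metrics(bpos, bspeed, pee_n)
  if (is.na(met$total_dispersion)) abort("degenerate bottom geometry")

  vols <- prospected_volumes(bpos, params$radii, params$n_samples,
                             seed = params$seed + dives$dive_id[k])
  vol_row <- as_tibble(setNames(as.list(vols$volume),
                                paste0("volume_", vols$radius)))
  den_row <- as_tibble(setNames(as.list(density_proxy(pee_n, vols$volume)),
                                paste0("density_", vols$radius)))

  # drift statistics: the most quiescent 200-s window of the bottom phase
  # (the delimited bottom can overrun into active transition seconds, which
  # would mask a passive drift core if whole-bottom SDs were used)
  drift <- quietest_window_sds(spd$v_seal[bidx], diff(depth_c$depth[bidx]))
  bind_cols(
    tibble(dive_id = dives$dive_id[k],
           start_time = dives$start_time[k], end_time = dives$end_time[k],
           max_depth = dives$max_depth[k]),
    met,
    tibble(vz_sd = drift[2], speed_sd_window = drift[1]),
    vol_row, den_row
  )
}
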