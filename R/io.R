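#' Construct and validate a sensor frame
#'
#' A sensor frame holds the time-aligned raw streams of one deployment:
#' depth (m, positive down) at 1 Hz, tri-axial body acceleration (m s^-2,
#' longitudinal/lateral/dorsoventral) and tri-axial magnetics (arbitrary
#' units) at 5 Hz, and a flow-noise level (arbitrary dB-like units) at 1 Hz
#' that may be missing outside the acoustic duty cycle.
#'
#' @param depth tibble with columns `time`, `depth`.
#' @param accel tibble with columns `time`, `ax`, `ay`, `az`.
#' @param mag tibble with columns `time`, `mx`, `my`, `mz`.
#' @param noise tibble with columns `time`, `level`, or `NULL`.
#' @param origin named numeric `c(lat = , lon = )` used to project GPS fixes.
#' @return A validated `sensor_frame` list.
#' @export
sensor_frame <- function(depth, accel, mag, noise = NULL,
                         origin = c(lat = NA_real_, lon = NA_real_)) {
  if (is.null(noise)) {
    noise <- tibble(time = depth$time, level = NA_real_)
  }
  frame <- structure(
    list(depth = as_tibble(depth), accel = as_tibble(accel),
         mag = as_tibble(mag), noise = as_tibble(noise)),
    class = "sensor_frame", fs_fast = 5, origin = origin
  )
  validate_sensor_frame(frame)
}

#' @rdname sensor_frame
#' @param frame a `sensor_frame` to validate.
#' @export
validate_sensor_frame <- function(frame) {
  need <- list(depth = c("time", "depth"), accel = c("time", "ax", "ay", "az"),
               mag = c("time", "mx", "my", "mz"), noise = c("time", "level"))
  for (nm in names(need)) {
    cols <- need[[nm]]
    if (!all(cols %in% names(frame[[nm]]))) {
      abort(sprintf("sensor_frame$%s must have columns %s",
                    nm, paste(cols, collapse = ", ")))
    }
    tm <- frame[[nm]]$time
    if (anyNA(tm) || is.unsorted(tm, strictly = TRUE)) {
      abort(sprintf("sensor_frame$%s time must be strictly increasing", nm))
    }
  }
  if (any(frame$depth$depth < -5, na.rm = TRUE)) {
    abort("depth below -5 m: not a plausible pre-correction surface offset")
  }
  n1 <- nrow(frame$depth)
  if (nrow(frame$accel) != 5 * n1 || nrow(frame$mag) != 5 * n1) {
    abort("5 Hz streams must be exactly 5x the length of the 1 Hz depth stream")
  }
  frame
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame> %d s at 1 Hz; accel/mag at 5 Hz; noise coverage %.0f%%\n",
              nrow(x$depth), 100 * mean(!is.na(x$noise$level))))
  invisible(x)
}

#' Write and read a sensor frame as CSV files
#'
#' One CSV per stream (`depth.csv`, `accel.csv`, `mag.csv`, `noise.csv`) plus
#' `origin.csv`, written into `dir`. `read_sensor_frame()` re-validates on
#' read: a schema mismatch or non-monotone time is rejected, gaps are kept as
#' `NA` (never interpolated).
#'
#' @param frame a `sensor_frame`.
#' @param dir directory to write to / read from (created if needed).
#' @param format only `"csv"` is supported.
#' @return `write_sensor_frame()` returns `dir` invisibly;
#'   `read_sensor_frame()` returns a `sensor_frame`.
#' @export
write_sensor_frame <- function(frame, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("depth", "accel", "mag", "noise")) {
    readr::write_csv(frame[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  org <- attr(frame, "origin")
  readr::write_csv(tibble(lat = org[["lat"]], lon = org[["lon"]]),
                   file.path(dir, "origin.csv"))
  invisible(dir)
}

#' @rdname write_sensor_frame
#' @export
read_sensor_frame <- function(dir, format = c("csv", "netcdf")) {
  format <- match.arg(format)
  if (format == "netcdf") {
    abort("NetCDF support requires a NetCDF library; use format = \"csv\"")
  }
  rd <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) abort(sprintf("missing stream file %s", path))
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  org_path <- file.path(dir, "origin.csv")
  origin <- c(lat = NA_real_, lon = NA_real_)
  if (file.exists(org_path)) {
    o <- readr::read_csv(org_path, show_col_types = FALSE, progress = FALSE)
    origin <- c(lat = o$lat[1], lon = o$lon[1])
  }
  sensor_frame(rd("depth"), rd("accel"), rd("mag"), rd("noise"), origin = origin)
}

#' Write and read GPS fixes as CSV
#'
#' Fixes are stored with ISO-8601 timestamps relative to an epoch plus the
#' second-of-deployment, and decimal-degree coordinates.
#'
#' @param fixes tibble with `time` (s since deployment start), `lat`, `lon`.
#' @param path CSV file path.
#' @param epoch POSIXct deployment start used to render ISO-8601 timestamps.
#' @return `read_gps_fixes()` returns a tibble (`time`, `lat`, `lon`).
#' @export
write_gps_fixes <- function(fixes, path,
                            epoch = as.POSIXct("2011-11-01 00:00:00", tz = "UTC")) {
  out <- fixes |>
    mutate(timestamp = format(epoch + .data$time, "%Y-%m-%dT%H:%M:%SZ")) |>
    select("timestamp", time_s = "time", "lat", "lon")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_gps_fixes
#' @export
read_gps_fixes <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "lat", "lon") %in% names(x))) {
    abort("GPS fix file must have columns time_s, lat, lon")
  }
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    abort("GPS fix times must be strictly increasing")
  }
  tibble(time = x$time_s, lat = x$lat, lon = x$lon)
}
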