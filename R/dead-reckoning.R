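# Dead-reckoning: the per-second velocity vector follows from heading, pitch
# and swimming speed under the assumption that the animal moves along its
# longitudinal axis; summing the vectors from the pre-dive GPS fix gives the
# raw track, and a uniform constant-current correction closes it onto the
# post-dive fix. The vertical coordinate is always taken from pressure.

#' Integrate a dead-reckoned 3D track
#'
#' Forward-Euler path integration at 1 Hz: the horizontal displacement over
#' second `t` is `v_seal * cos(pitch) * (sin(heading), cos(heading))`
#' evaluated at `t`; the vertical coordinate is overwritten with `-depth`
#' (pressure is the trusted vertical). Missing speed samples are linearly
#' interpolated over gaps of at most `max_gap` seconds; a longer (or
#' leading/trailing) gap rejects the dive with an error.
#'
#' @param attitude tibble `time`, `pitch`, `heading` at 1 Hz over the dive.
#' @param speed tibble `time`, `v_seal` on the same clock.
#' @param depth tibble `time`, `depth` on the same clock.
#' @param anchor numeric `c(east, north)` of the pre-dive GPS fix in the
#'   local frame (m).
#' @param max_gap longest speed gap (s) bridged by interpolation.
#' @return A `track3d` tibble `time`, `east`, `north`, `z` with attributes
#'   `anchor` and (after [close_track()]) `correction_velocity`.
#' @export
integrate_path <- function(attitude, speed, depth, anchor = c(0, 0),
                           max_gap = 5) {
  n <- nrow(attitude)
  stopifnot(nrow(speed) == n, nrow(depth) == n)
  v <- fill_short_gaps(speed$v_seal, max_gap)
  if (is.null(v)) {
    abort("speed gaps exceed max_gap; dive rejected")
  }
  step_h <- v * cos(attitude$pitch)
  de <- step_h * sin(attitude$heading)
  dn <- step_h * cos(attitude$heading)
  track <- tibble(
    time = attitude$time,
    east = anchor[1] + c(0, cumsum(de[-n])),
    north = anchor[2] + c(0, cumsum(dn[-n])),
    z = -depth$depth
  )
  structure(track, class = c("track3d", class(track)),
            anchor = anchor, correction_velocity = c(0, 0))
}

#' Close a dead-reckoned track onto the post-dive GPS fix
#'
#' The horizontal offset between the raw endpoint and the closing fix,
#' divided by the track's time span, defines a constant correction velocity
#' (an apparent current); every position is shifted by
#' `correction_velocity * (t - t0)`. The first position is unchanged, the
#' corrected endpoint matches the fix to numerical precision, and the
#' vertical coordinate is untouched. With a missing fix the track is kept
#' uncorrected and flagged.
#'
#' @param track a `track3d` from [integrate_path()].
#' @param closing numeric `c(east, north)` of the post-dive fix (m), or
#'   `NULL` if missing.
#' @return The corrected `track3d`; attributes `correction_velocity`
#'   (east, north, m s^-1) and `closed` (logical).
#' @export
close_track <- function(track, closing) {
  if (is.null(closing) || anyNA(closing)) {
    warn("missing closing fix; track kept uncorrected")
    attr(track, "closed") <- FALSE
    return(track)
  }
  n <- nrow(track)
  span <- track$time[n] - track$time[1]
  if (span <= 0) abort("track must span positive time")
  vc <- c(closing[1] - track$east[n], closing[2] - track$north[n]) / span
  dt <- track$time - track$time[1]
  track$east <- track$east + vc[1] * dt
  track$north <- track$north + vc[2] * dt
  attr(track, "correction_velocity") <- vc
  attr(track, "closed") <- TRUE
  track
}

#' Path length of a track
#'
#' Sum of the 3D step norms, a convenience for tests and summaries.
#'
#' @param track a `track3d`.
#' @return Numeric scalar (m).
#' @export
path_length <- function(track) {
  sum(sqrt(diff(track$east)^2 + diff(track$north)^2 + diff(track$z)^2))
}
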