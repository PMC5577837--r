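# Prey-encounter-event detection from 5 Hz tri-axial acceleration: rapid prey
# strikes leave broadband transients; the detector isolates them with a
# high-pass filter, summarises per-axis activity with nested standard
# deviations, splits each axis into low/high states with a deterministic
# two-means clustering, and calls an event where all three axes are high
# simultaneously.

#' High-pass dynamic acceleration
#'
#' Extracts the dynamic (rapid-movement) component of each acceleration axis
#' with a zero-phase order-3 high-pass Butterworth filter with a normalized
#' cut-off of 2.4 at a 5 Hz sampling rate. The nominal cut-off is normalized
#' by the sampling rate (0.48 of Nyquist, i.e. 1.2 Hz): slow postural and
#' stroking content is removed while the strike band passes with under 3 dB
#' loss at 2.45 Hz, and the passband stays wide enough that impulsive strikes
#' are not smeared into multi-second ringing.
#'
#' @param accel tibble `time`, `ax`, `ay`, `az` at `fs` Hz.
#' @param fs sampling rate (Hz).
#' @param cutoff nominal high-pass cut-off, normalized by the sampling rate.
#' @return A tibble with the same columns, filtered.
#' @export
dynamic_acceleration <- function(accel, fs = 5, cutoff = 2.4) {
  stopifnot(all(c("time", "ax", "ay", "az") %in% names(accel)))
  tibble(
    time = accel$time,
    ax = butter_filtfilt(accel$ax, fs, cutoff, "high", norm = "rate"),
    ay = butter_filtfilt(accel$ay, fs, cutoff, "high", norm = "rate"),
    az = butter_filtfilt(accel$az, fs, cutoff, "high", norm = "rate")
  )
}

# Deterministic 1-D two-means: initial centers at the 10th/90th percentiles,
# Lloyd iterations to convergence (<= max_iter). Returns a logical vector:
# TRUE for the cluster with the larger mean. A unimodal activity series with
# no genuine high state would otherwise be split through its bulk, so the
# high state is only accepted when the cluster means separate by more than
# `min_sep` low-cluster SDs (a strike stands tens of SDs above background).
kmeans2_high <- function(x, max_iter = 100, min_sep = 8) {
  c1 <- as.numeric(quantile(x, 0.10, names = FALSE))
  c2 <- as.numeric(quantile(x, 0.90, names = FALSE))
  if (!is.finite(c1) || !is.finite(c2) || c2 - c1 < 1e-12) {
    return(rep(FALSE, length(x)))
  }
  for (i in seq_len(max_iter)) {
    hi <- x > (c1 + c2) / 2
    if (!any(hi) || all(hi)) break
    n1 <- mean(x[!hi]); n2 <- mean(x[hi])
    if (isTRUE(all.equal(c(c1, c2), c(n1, n2), tolerance = 1e-12))) {
      c1 <- n1; c2 <- n2
      break
    }
    c1 <- n1; c2 <- n2
  }
  hi <- x > (c1 + c2) / 2
  if (!any(hi) || all(hi)) return(rep(FALSE, length(x)))
  if ((c2 - c1) < min_sep * max(sd(x[!hi]), 1e-12)) {
    return(rep(FALSE, length(x)))
  }
  hi
}

#' Per-axis high/low activity states
#'
#' For each axis of the high-passed acceleration: the SD over fixed
#' one-second windows gives a 1 Hz activity series; a centred five-second
#' moving SD smooths it; a two-means clustering splits the result into a
#' "high" and a "low" state (the cluster with the larger mean is high). An
#' axis whose activity range is below `1e-6` is all low state.
#'
#' @param dyn tibble from [dynamic_acceleration()] at `fs` Hz.
#' @param fs sampling rate (Hz); must divide the stream into whole seconds.
#' @return A 1 Hz tibble `time`, `sx`, `sy`, `sz` of logical states.
#' @export
state_signal <- function(dyn, fs = 5) {
  n5 <- nrow(dyn)
  n1 <- floor(n5 / fs)
  if (n1 < 5) abort("need at least 5 s of data to compute states")
  sec <- rep(seq_len(n1), each = fs)
  one_axis <- function(x) {
    x <- x[seq_len(n1 * fs)]
    sd1 <- vapply(split(x, sec), sd, numeric(1))
    sd5 <- rolling_sd(sd1, 5)
    if (diff(range(sd5)) < 1e-6) rep(FALSE, n1) else kmeans2_high(sd5)
  }
  tibble(
    time = dyn$time[seq(1, n1 * fs, by = fs)],
    sx = one_axis(dyn$ax),
    sy = one_axis(dyn$ay),
    sz = one_axis(dyn$az)
  )
}

#' Detect prey encounter events from tri-axial states
#'
#' An event occurs where the three axes are simultaneously in high state; a
#' continuous succession of such seconds is merged into a single event.
#'
#' @param states 1 Hz tibble `time`, `sx`, `sy`, `sz` from [state_signal()].
#' @return A tibble of events: `start_time`, `end_time` (s, inclusive of the
#'   last high second).
#' @export
detect_pee <- function(states) {
  stopifnot(all(c("time", "sx", "sy", "sz") %in% names(states)))
  if (length(unique(c(length(states$sx), length(states$sy), length(states$sz)))) != 1) {
    abort("state series must have equal length")
  }
  hi <- states$sx & states$sy & states$sz
  runs <- true_runs(hi)
  tibble(start_time = states$time[runs$start], end_time = states$time[runs$end])
}

#' Run the full detector on a sensor frame
#'
#' Convenience wrapper: [dynamic_acceleration()] then [state_signal()] then
#' [detect_pee()], with events annotated by dive and bottom membership when a
#' dive table is supplied (membership uses the event midpoint).
#'
#' @param frame a `sensor_frame`.
#' @param dives optional dive table from [delimit_bottom()].
#' @param fs,cutoff detector parameters, see [dynamic_acceleration()].
#' @return An event tibble `start_time`, `end_time` plus, when `dives` is
#'   given, `dive_id` and `in_bottom`.
#' @export
detect_pee_events <- function(frame, dives = NULL, fs = 5, cutoff = 2.4) {
  ev <- detect_pee(state_signal(dynamic_acceleration(frame$accel, fs, cutoff), fs))
  if (is.null(dives) || nrow(ev) == 0) return(ev)
  mid <- (ev$start_time + ev$end_time) / 2
  ev$dive_id <- NA_integer_
  ev$in_bottom <- FALSE
  for (k in seq_len(nrow(dives))) {
    inside <- mid >= dives$start_time[k] & mid <= dives$end_time[k]
    ev$dive_id[inside] <- dives$dive_id[k]
    if (!is.na(dives$descent_end[k])) {
      bs <- frame$depth$time[dives$descent_end[k]]
      be <- frame$depth$time[dives$ascent_start[k]]
      ev$in_bottom[inside] <- mid[inside] >= bs & mid[inside] <= be
    }
  }
  ev
}
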