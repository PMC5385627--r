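#' Detection configuration
#'
#' Collects every threshold of the turning-detection algorithm. Defaults are
#' the operating point used for validation against clinical observation: a
#' 90 degree magnitude threshold (sweepable over 45-110, see
#' [threshold_sweep()]), a 0.1-10 s duration window, and the hesitation rule
#' (an interruption shorter than 0.5 s whose magnitude is below 10% of both
#' neighbouring movements, each of which exceeds 10 degrees in the same
#' direction, does not end a turn).
#'
#' @param magnitude_threshold Minimum absolute turn magnitude, degrees
#'   (inclusive; default 90).
#' @param duration_min,duration_max Accepted turn duration window, seconds
#'   (defaults 0.1 and 10, inclusive).
#' @param hesitation_max_duration Maximum duration of a mergeable
#'   hesitation, seconds (exclusive; default 0.5).
#' @param hesitation_max_fraction Maximum hesitation magnitude as a fraction
#'   of each neighbour's magnitude (exclusive; default 0.10).
#' @param hesitation_min_neighbor Minimum magnitude of both neighbours,
#'   degrees (exclusive; default 10).
#' @param stable_window_samples,stable_pp_threshold Quasi-static window used
#'   for gravity alignment: length in samples (5) and per-axis peak-to-peak
#'   bound in m/s^2 (0.2); see [find_stable_window()].
#' @param match_tolerance Event-matching tolerance for validation, seconds
#'   (default 2.5; see [match_events()]).
#' @param direction_convention Mapping from the sign of the vertical-axis
#'   gyro integral (equivalently the signed yaw change) to a turn label.
#'   `"positive_right"` (default) labels a positive integral as a right
#'   turn; `"positive_left"` is the mirror. The two differ by the sensor's
#'   mounting orientation, which cannot be recovered from the data alone.
#' @return A validated list of class `detection_config`.
#' @export
detection_config <- function(magnitude_threshold = 90,
                             duration_min = 0.1,
                             duration_max = 10,
                             hesitation_max_duration = 0.5,
                             hesitation_max_fraction = 0.10,
                             hesitation_min_neighbor = 10,
                             stable_window_samples = 5L,
                             stable_pp_threshold = 0.2,
                             match_tolerance = 2.5,
                             direction_convention = c("positive_right",
                                                      "positive_left")) {
  direction_convention <- match.arg(direction_convention)
  cfg <- list(magnitude_threshold = magnitude_threshold,
              duration_min = duration_min, duration_max = duration_max,
              hesitation_max_duration = hesitation_max_duration,
              hesitation_max_fraction = hesitation_max_fraction,
              hesitation_min_neighbor = hesitation_min_neighbor,
              stable_window_samples = as.integer(stable_window_samples),
              stable_pp_threshold = stable_pp_threshold,
              match_tolerance = match_tolerance,
              direction_convention = direction_convention)
  num <- cfg[!names(cfg) %in% "direction_convention"]
  if (any(!vapply(num, function(v) is.finite(v) && v > 0, logical(1L))))
    stop("all detection_config thresholds must be positive and finite")
  if (cfg$duration_min >= cfg$duration_max)
    stop("duration_min must be smaller than duration_max")
  if (cfg$hesitation_max_fraction <= 0 || cfg$hesitation_max_fraction >= 1)
    stop("hesitation_max_fraction must lie in (0, 1)")
  structure(cfg, class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("turn detection configuration:\n",
      "  magnitude >= ", x$magnitude_threshold, " deg, duration ",
      x$duration_min, "-", x$duration_max, " s\n",
      "  hesitation: < ", x$hesitation_max_duration, " s, < ",
      100 * x$hesitation_max_fraction, "% of neighbours > ",
      x$hesitation_min_neighbor, " deg (same direction)\n",
      "  direction convention: ", x$direction_convention, "\n", sep = "")
  invisible(x)
}

direction_label <- function(signed, convention) {
  pos <- if (convention == "positive_right") "right" else "left"
  neg <- if (convention == "positive_right") "left" else "right"
  ifelse(signed > 0, pos, ifelse(signed < 0, neg, "indeterminate"))
}

#' Segment an unwrapped yaw trace at direction reversals
#'
#' Cuts the continuous yaw trace into pieces at its local extrema: the start
#' of a right turn is a change from increase to decrease and its end the
#' change back (vice versa for left turns), so each piece is a maximal run
#' over which yaw is monotone. The segments tile the trace — the end of one
#' piece is the start of the next. Runs of exactly constant yaw become their
#' own zero-magnitude segments (they can only arise in noise-free signals; a
#' fully constant trace yields no segments).
#'
#' @param track An `attitude_track` from [propagate()], or a numeric
#'   unwrapped-yaw vector (degrees) with times given via `t`.
#' @param t Timestamps, seconds; taken from the track when omitted.
#' @return A `data.frame` with one row per segment: `start_idx`, `end_idx`
#'   (1-based sample indices), `t_start`, `t_end`, `duration`, `magnitude`
#'   (signed yaw change end minus start, degrees).
#' @export
segment_yaw <- function(track, t = NULL) {
  if (inherits(track, "attitude_track")) {
    yaw <- track$yaw
    if (is.null(t)) t <- track$t
  } else {
    yaw <- as.numeric(track)
  }
  stopifnot(length(t) == length(yaw))
  n <- length(yaw)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), magnitude = numeric(0))
  if (n < 2L) return(empty)
  s <- sign(diff(yaw))
  if (all(s == 0)) return(empty)
  r <- rle(s)
  ends_d <- cumsum(r$lengths)            # last diff index of each run
  starts_d <- ends_d - r$lengths + 1L    # first diff index of each run
  start_idx <- starts_d                  # sample index of segment start
  end_idx <- ends_d + 1L                 # sample index of segment end
  data.frame(start_idx = start_idx, end_idx = end_idx,
             t_start = t[start_idx], t_end = t[end_idx],
             duration = t[end_idx] - t[start_idx],
             magnitude = yaw[end_idx] - yaw[start_idx])
}

#' Merge hesitations between same-direction turn segments
#'
#' A movement lasting less than 0.5 s whose magnitude stays below 10% of the
#' magnitude of both the previous and the following segment — each of which
#' must exceed 10 degrees in the same direction — is a hesitation: the
#' flanking segments and the hesitation are replaced by a single segment
#' spanning their union, whose magnitude is the net yaw change from start to
#' end. The interruption may consist of several consecutive sub-threshold
#' segments (at full sampling resolution, sensor noise splits one physical
#' hesitation into a chain of minute reversals): the rule is applied to the
#' whole gap between two qualifying neighbours, requiring the gap's total
#' duration to be under the limit and every gap segment's magnitude to be
#' under the neighbour fraction — for a single-segment gap this is exactly
#' the triple rule. Merging scans left to right and repeats until a fixed
#' point, so chains of hesitations collapse into one turn.
#'
#' @param segments Segment table from [segment_yaw()] (must tile the trace).
#' @param cfg A [detection_config()] supplying the rule parameters.
#' @return Segment table of the same shape, still tiling the trace.
#' @export
merge_hesitations <- function(segments, cfg = detection_config()) {
  seg <- segments
  repeat {
    m <- nrow(seg)
    if (m < 3L) break
    mag <- seg$magnitude
    maj <- which(abs(mag) > cfg$hesitation_min_neighbor)
    if (length(maj) < 2L) break
    cum_dur <- cumsum(seg$duration)
    # candidate pairs of consecutive qualifying neighbours with a
    # non-empty gap of sub-threshold segments between them
    merge_from <- integer(0); merge_to <- integer(0)
    last_end <- 0L
    for (k in seq_len(length(maj) - 1L)) {
      i <- maj[k]; j <- maj[k + 1L]
      if (j - i < 2L || (last_end > 0L && i <= last_end)) next
      if (sign(mag[i]) != sign(mag[j])) next
      gap_dur <- cum_dur[j - 1L] - cum_dur[i]
      if (gap_dur >= cfg$hesitation_max_duration) next
      gap <- (i + 1L):(j - 1L)
      lim <- cfg$hesitation_max_fraction * min(abs(mag[i]), abs(mag[j]))
      if (any(abs(mag[gap]) >= lim)) next
      merge_from <- c(merge_from, i); merge_to <- c(merge_to, j)
      last_end <- j
    }
    if (!length(merge_from)) break
    drop <- unlist(mapply(seq, merge_from, merge_to, SIMPLIFY = FALSE))
    merged <- data.frame(start_idx = seg$start_idx[merge_from],
                         end_idx = seg$end_idx[merge_to],
                         t_start = seg$t_start[merge_from],
                         t_end = seg$t_end[merge_to],
                         duration = seg$t_end[merge_to] -
                           seg$t_start[merge_from],
                         magnitude = vapply(seq_along(merge_from),
                           function(k) sum(mag[merge_from[k]:merge_to[k]]),
                           numeric(1L)))
    out <- rbind(seg[-drop, , drop = FALSE], merged)
    seg <- out[order(out$start_idx), , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

#' Filter merged segments into accepted turn events
#'
#' Keeps segments whose absolute magnitude reaches the configured threshold
#' (inclusive) and whose duration lies within the accepted window (0.1-10 s,
#' inclusive). The event duration is the horizontal extent of the segment
#' and its magnitude the vertical extent of the yaw trace over it.
#'
#' @param segments Segment table from [merge_hesitations()].
#' @param cfg A [detection_config()].
#' @return A [turn_events()] table (`source = "algorithm"`), direction taken
#'   from the sign of the yaw change under the configured convention.
#' @export
filter_turns <- function(segments, cfg = detection_config()) {
  keep <- abs(segments$magnitude) >= cfg$magnitude_threshold &
    segments$duration >= cfg$duration_min &
    segments$duration <= cfg$duration_max
  seg <- segments[keep, , drop = FALSE]
  turn_events(seg$t_start, seg$t_end, abs(seg$magnitude),
              direction_label(seg$magnitude, cfg$direction_convention),
              source = "algorithm")
}

#' Turn direction from the gyroscope integral
#'
#' Integrates the vertical (global-frame) angular velocity over the event
#' interval by the trapezoid rule and labels the turn from the sign of the
#' integral under the configured convention (by default a positive integral
#' — positive net yaw — is a right turn; mirror with `"positive_left"`).
#' For any accepted turn this agrees with the sign of the segment's yaw
#' change.
#'
#' @param track An `attitude_track` from [propagate()].
#' @param t_start,t_end Event interval, seconds (within the recording).
#' @param cfg A [detection_config()] (supplies the convention).
#' @return `"left"`, `"right"`, or `"indeterminate"` when the integral is
#'   below 1 degree (cannot occur for accepted turns). The integral in
#'   degrees is attached as attribute `integral_deg`.
#' @export
turn_direction <- function(track, t_start, t_end, cfg = detection_config()) {
  stopifnot(inherits(track, "attitude_track"), t_end > t_start)
  if (t_start < track$t[1L] - 1e-9 ||
      t_end > track$t[length(track$t)] + 1e-9)
    stop("event interval outside the recording")
  idx <- which(track$t >= t_start - 1e-9 & track$t <= t_end + 1e-9)
  w <- track$gw_z[idx] * 180 / pi
  integral <- sum(diff(track$t[idx]) * (w[-1L] + w[-length(w)]) / 2)
  lab <- if (abs(integral) < 1) "indeterminate" else
    direction_label(integral, cfg$direction_convention)
  structure(lab, integral_deg = integral)
}

#' Detect turns in a 6DOF IMU recording
#'
#' The full pipeline: locate the quasi-static accelerometer window and align
#' the initial orientation with gravity; propagate orientation through the
#' gyroscope signal with the Rodrigues rotation-matrix update; unwrap the
#' yaw trace; cut it into monotone segments at direction reversals; merge
#' hesitations; and keep segments passing the magnitude and duration
#' thresholds. Each accepted event's direction is determined by the sign of
#' the vertical gyroscope integral over the event.
#'
#' @param rec An [imu_recording()].
#' @param cfg A [detection_config()].
#' @return An object of class `turn_detection`: list with `events` (a
#'   [turn_events()] table, sorted, non-overlapping), `track` (the
#'   `attitude_track`), `segments` (pre-merge), `merged` (post-merge) and
#'   `config`. Print, summary and plot methods are provided.
#' @examples
#' script <- turn_script(list(quiet_phase(3), turn_phase(120, 2),
#'                            quiet_phase(3)),
#'                       gyro_noise_sd = 0, accel_noise_sd = 0)
#' sim <- render_script(script, seed = 1)
#' fit <- detect_turns(sim$recording)
#' fit$events
#' @export
detect_turns <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  track <- propagate(rec, window = cfg$stable_window_samples,
                     pp_threshold = cfg$stable_pp_threshold)
  segments <- segment_yaw(track)
  merged <- merge_hesitations(segments, cfg)
  events <- filter_turns(merged, cfg)
  if (nrow(events)) {
    gyro_dir <- vapply(seq_len(nrow(events)), function(i)
      as.character(turn_direction(track, events$t_start[i], events$t_end[i],
                                  cfg)), character(1L))
    if (any(gyro_dir != events$direction))
      warning("gyro-integral direction disagrees with yaw-segment sign for ",
              sum(gyro_dir != events$direction), " event(s)")
    events$direction <- ifelse(gyro_dir == "indeterminate",
                               events$direction, gyro_dir)
  }
  structure(list(events = events, track = track, segments = segments,
                 merged = merged, config = cfg,
                 span = c(rec$t[1L], rec$t[rec$n])),
            class = "turn_detection")
}

#' @export
print.turn_detection <- function(x, ...) {
  ev <- x$events
  cat("Turn detection (threshold ", x$config$magnitude_threshold,
      " deg, duration ", x$config$duration_min, "-", x$config$duration_max,
      " s)\n", sep = "")
  cat("  ", nrow(ev), " turn(s) in ", format(round(diff(x$span), 1)),
      " s of recording\n", sep = "")
  if (nrow(ev))
    cat("  mean magnitude ", format(round(mean(ev$magnitude), 1)),
        " deg, mean duration ", format(round(mean(ev$duration), 2)),
        " s; ", sum(ev$direction == "left"), " left / ",
        sum(ev$direction == "right"), " right\n", sep = "")
  invisible(x)
}

#' @export
summary.turn_detection <- function(object, ...) {
  ev <- object$events
  out <- list(n_turns = nrow(ev),
              threshold = object$config$magnitude_threshold,
              span_s = diff(object$span),
              n_segments = nrow(object$segments),
              n_merged = nrow(object$segments) - nrow(object$merged),
              magnitude = if (nrow(ev)) summary(ev$magnitude),
              duration = if (nrow(ev)) summary(ev$duration),
              left = sum(ev$direction == "left"),
              right = sum(ev$direction == "right"))
  class(out) <- "summary.turn_detection"
  out
}

#' @export
print.summary.turn_detection <- function(x, ...) {
  cat(x$n_turns, " turn(s) over ", format(round(x$span_s, 1)),
      " s (threshold ", x$threshold, " deg); ",
      x$left, " left / ", x$right, " right\n",
      x$n_merged, " hesitation merge(s) over ", x$n_segments,
      " raw yaw segment(s)\n", sep = "")
  if (!is.null(x$magnitude)) {
    cat("magnitude (deg):\n"); print(x$magnitude)
    cat("duration (s):\n"); print(x$duration)
  }
  invisible(x)
}

#' Plot the yaw trace with detected turns
#'
#' Draws the unwrapped yaw angle against time and shades each accepted turn,
#' with flags at event starts and ends — the standard way to inspect the
#' segmentation of a lower-back recording.
#'
#' @param x A `turn_detection` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.turn_detection <- function(x, ...) {
  tr <- x$track
  graphics::plot(tr$t, tr$yaw, type = "l", xlab = "time (s)",
                 ylab = "unwrapped yaw (deg)", ...)
  ev <- x$events
  if (nrow(ev)) {
    usr <- graphics::par("usr")
    graphics::rect(ev$t_start, usr[3L], ev$t_end, usr[4L],
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
    graphics::abline(v = c(ev$t_start, ev$t_end), lty = 3, col = "grey40")
    graphics::lines(tr$t, tr$yaw)
  }
  invisible(x)
}
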