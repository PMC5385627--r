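#' Script phases for the synthetic-recording generator
#'
#' A script is a sequence of phases: `quiet_phase()` renders quiet standing
#' (zero true angular velocity), `turn_phase()` a smooth turn about the
#' vertical axis. Hesitations are brief opposite-direction velocity dips
#' inside a turn; the scripted magnitude is the net yaw change from turn
#' start to turn end, so ground truth stays exact whether or not hesitations
#' are present.
#'
#' @param duration Phase duration, seconds.
#' @param magnitude Signed net yaw change of the turn, degrees (positive =
#'   counterclockwise about global up = "right" under the default direction
#'   convention).
#' @param profile Angular-velocity shape: `"raised_cosine"` (default,
#'   zero-velocity entry and exit) or `"trapezoid"` (ramp-hold-ramp).
#' @param hesitations List of hesitations, each `c(offset, dip, dur)`:
#'   `offset` — position in (0,1) along the moving part of the turn; `dip` —
#'   magnitude of the opposite-direction excursion, degrees (> 0); `dur` —
#'   dip duration, seconds.
#' @return A phase object consumed by [turn_script()].
#' @export
quiet_phase <- function(duration) {
  stopifnot(duration > 0)
  structure(list(kind = "quiet", duration = duration), class = "imu_phase")
}

#' @rdname quiet_phase
#' @export
turn_phase <- function(magnitude, duration, profile = c("raised_cosine",
                                                        "trapezoid"),
                       hesitations = list()) {
  profile <- match.arg(profile)
  stopifnot(duration > 0, magnitude != 0)
  for (h in hesitations)
    stopifnot(length(h) == 3L, h[1L] > 0, h[1L] < 1, h[2L] > 0, h[3L] > 0)
  if (length(hesitations)) {
    if (sum(vapply(hesitations, `[`, numeric(1L), 3L)) >= duration)
      stop("hesitations longer than the turn itself")
  }
  structure(list(kind = "turn", magnitude = magnitude, duration = duration,
                 profile = profile, hesitations = hesitations),
            class = "imu_phase")
}

#' Assemble a simulation script
#'
#' Defines everything the generator needs: the phase sequence, the static
#' mounting tilt of the sensor on the lower back, gyroscope bias and noise,
#' accelerometer noise, and the sampling rate. Defaults emulate a
#' consumer-grade 6DOF unit: 128 Hz, gyroscope white noise 0.5 deg/s,
#' accelerometer white noise 0.05 m/s^2, zero bias, 10 degree mounting
#' tilt. The first phase must be quiet and long enough for the quasi-static
#' initialisation window.
#'
#' @param phases List of [quiet_phase()] / [turn_phase()] objects.
#' @param tilt_deg Static mounting inclination relative to vertical,
#'   degrees (rotation about the sensor y axis).
#' @param gyro_bias_dps Constant gyroscope bias 3-vector, deg/s, sensor
#'   frame.
#' @param gyro_noise_sd_dps Gyroscope white-noise SD, deg/s.
#' @param accel_noise_sd Accelerometer white-noise SD, m/s^2.
#' @param fs Sampling rate, Hz.
#' @param direction_convention Label mapping used for ground-truth events;
#'   see [detection_config()].
#' @param seed Default seed used by [render_script()].
#' @return Object of class `turn_script`.
#' @export
turn_script <- function(phases, tilt_deg = 10, gyro_bias_dps = c(0, 0, 0),
                        gyro_noise_sd_dps = 0.5, accel_noise_sd = 0.05,
                        fs = 128, direction_convention = "positive_right",
                        seed = 1L) {
  stopifnot(length(phases) >= 1L,
            all(vapply(phases, inherits, logical(1L), "imu_phase")),
            length(gyro_bias_dps) == 3L, gyro_noise_sd_dps >= 0,
            accel_noise_sd >= 0, fs > 0)
  if (phases[[1L]]$kind != "quiet" || phases[[1L]]$duration < 5 / fs + 0.1)
    stop("the script must start with a quiet phase of at least ",
         format(5 / fs + 0.1), " s so gravity alignment can succeed")
  structure(list(phases = phases, tilt_deg = tilt_deg,
                 gyro_bias_dps = gyro_bias_dps,
                 gyro_noise_sd_dps = gyro_noise_sd_dps,
                 accel_noise_sd = accel_noise_sd, fs = fs,
                 direction_convention = direction_convention,
                 seed = as.integer(seed)),
            class = "turn_script")
}

# Discrete angular-velocity samples (deg/s) for a smooth movement of
# `magnitude` degrees over `n` samples. Profiles are evaluated at interval
# midpoints (never exactly zero inside the movement) and rescaled so the
# left-endpoint discrete integral sum(w)/fs equals the magnitude exactly.
profile_rate <- function(magnitude, n, fs, profile) {
  stopifnot(n >= 1L)
  x <- (seq_len(n) - 0.5) / n
  raw <- switch(profile,
                raised_cosine = 1 - cos(2 * pi * x),
                trapezoid = pmin(1, pmin(x, 1 - x) / 0.25),
                stop("unknown profile: ", profile))
  raw * (magnitude * fs / sum(raw))
}

# Rate samples for one turn phase, hesitation dips included; the dips go
# against the turn direction and the moving portions are scaled up so the
# net integral is exactly the scripted magnitude.
turn_rate <- function(phase, fs) {
  n <- max(2L, round(phase$duration * fs))
  hes <- phase$hesitations
  if (!length(hes))
    return(profile_rate(phase$magnitude, n, fs, phase$profile))
  hes <- hes[order(vapply(hes, `[`, numeric(1L), 1L))]
  n_dip <- vapply(hes, function(h) max(1, round(h[3L] * fs)), numeric(1L))
  if (sum(n_dip) >= n - length(hes))
    stop("hesitations leave no room for the turn itself")
  n_move <- n - sum(n_dip)
  offs <- vapply(hes, `[`, numeric(1L), 1L)
  bounds <- round(c(0, offs, 1) * n_move)
  n_part <- diff(bounds)
  if (any(n_part < 1L)) stop("hesitation offsets too close together")
  s <- sign(phase$magnitude)
  dip_mag <- -s * vapply(hes, `[`, numeric(1L), 2L)
  move_total <- phase$magnitude - sum(dip_mag)
  part_mag <- move_total * n_part / n_move
  out <- profile_rate(part_mag[1L], n_part[1L], fs, phase$profile)
  for (k in seq_along(hes)) {
    out <- c(out, profile_rate(dip_mag[k], n_dip[k], fs, "raised_cosine"),
             profile_rate(part_mag[k + 1L], n_part[k + 1L], fs,
                          phase$profile))
  }
  out
}

#' Render a script into a synthetic IMU recording with ground truth
#'
#' Builds the continuous yaw trajectory implied by the phases, composes it
#' with the static mounting tilt into an orientation trajectory, and emits
#' the corresponding sensor signals: the gyroscope reads the body-frame
#' angular velocity plus bias plus Gaussian white noise; the accelerometer
#' reads gravity rotated into the sensor frame plus Gaussian white noise
#' (no linear-acceleration model — the algorithm uses the accelerometer only
#' for initial alignment). The same seed reproduces the recording exactly.
#'
#' @param script A [turn_script()].
#' @param seed Integer seed for the noise draws (default `script$seed`).
#' @return List with `recording` (an [imu_recording()]), `truth` (a
#'   [turn_events()] table, `source = "reference"`, carrying the exact
#'   scripted magnitude/duration/direction of every turn phase), and
#'   `yaw_true` (the noise-free yaw trajectory, degrees, per sample).
#' @export
render_script <- function(script, seed = script$seed) {
  stopifnot(inherits(script, "turn_script"))
  fs <- script$fs
  rate <- numeric(0)                 # deg/s at interval left endpoints
  t_start <- t_end <- mag <- numeric(0)
  for (ph in script$phases) {
    n <- max(2L, round(ph$duration * fs))
    if (ph$kind == "quiet") {
      rate <- c(rate, numeric(n))
    } else {
      t_start <- c(t_start, length(rate) / fs)
      rate <- c(rate, turn_rate(ph, fs))
      t_end <- c(t_end, length(rate) / fs)
      mag <- c(mag, ph$magnitude)
    }
  }
  n_total <- length(rate) + 1L
  t <- (seq_len(n_total) - 1L) / fs
  yaw_true <- c(0, cumsum(rate)) / fs

  tilt <- script$tilt_deg * pi / 180
  # sensor->global tilt about y: v_G = Ry(tilt) v_S
  u <- c(-sin(tilt), 0, cos(tilt))   # global up in sensor frame (Ry^T e3)
  rate_rad <- c(rate, 0) * pi / 180
  gyro <- outer(rate_rad, u)
  gyro <- sweep(gyro, 2L, script$gyro_bias_dps * pi / 180, "+")
  accel <- matrix(9.81 * u, n_total, 3L, byrow = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (script$gyro_noise_sd_dps > 0)
    gyro <- gyro + matrix(stats::rnorm(3L * n_total,
                                       sd = script$gyro_noise_sd_dps *
                                         pi / 180), n_total, 3L)
  if (script$accel_noise_sd > 0)
    accel <- accel + matrix(stats::rnorm(3L * n_total,
                                         sd = script$accel_noise_sd),
                            n_total, 3L)
  truth <- turn_events(t_start, t_end, abs(mag),
                       direction_label(mag, script$direction_convention),
                       source = "reference")
  list(recording = imu_recording(t, accel, gyro, fs = fs), truth = truth,
       yaw_true = yaw_true)
}

#' Random turning script
#'
#' Draws a script of `n_turns` turns separated by quiet standing, with
#' magnitudes, durations, gaps and directions sampled from ranges typical of
#' indoor activity (turn magnitudes around 100-180 degrees, durations
#' around 1.5-4 s, gaps 2-4 s). Optionally each turn carries one hesitation
#' with probability `hesitation_prob` (dip about 5% of the magnitude,
#' 0.2-0.4 s).
#'
#' @param n_turns Number of turn phases.
#' @param seed Integer seed (draws the script; also stored as the render
#'   seed).
#' @param magnitude_range,duration_range,gap_range Sampling ranges.
#' @param hesitation_prob Probability a turn contains a hesitation.
#' @param ... Passed to [turn_script()] (noise levels, tilt, fs, ...).
#' @return A [turn_script()].
#' @export
random_turn_script <- function(n_turns, seed = 1L,
                               magnitude_range = c(100, 180),
                               duration_range = c(1.5, 4),
                               gap_range = c(2, 4),
                               hesitation_prob = 0, ...) {
  set.seed(seed)
  phases <- list(quiet_phase(3))
  for (i in seq_len(n_turns)) {
    magnitude <- sample(c(-1, 1), 1L) *
      stats::runif(1L, magnitude_range[1L], magnitude_range[2L])
    duration <- stats::runif(1L, duration_range[1L], duration_range[2L])
    hes <- if (stats::runif(1L) < hesitation_prob)
      list(c(stats::runif(1L, 0.3, 0.7), 0.05 * abs(magnitude),
             stats::runif(1L, 0.2, 0.4))) else list()
    phases <- c(phases, list(turn_phase(magnitude, duration,
                                        hesitations = hes)),
                list(quiet_phase(stats::runif(1L, gap_range[1L],
                                              gap_range[2L]))))
  }
  turn_script(phases, seed = seed, ...)
}

#' Canned simulation scenarios
#'
#' Named fixtures covering the conditions the detector must handle:
#' \describe{
#'   \item{clean}{eight turns, no noise, no bias — exact recovery expected.}
#'   \item{noisy}{the same turns with sensor-grade noise (gyro 0.5 deg/s,
#'     accel 0.05 m/s^2).}
#'   \item{hesitant}{turns each interrupted by a 0.2-0.4 s dip of about 5%
#'     of the turn magnitude — every dip must merge so each turn counts
#'     once.}
#'   \item{wide_radius}{slow, wide-radius turning (12-15 s per turn) — an
#'     acknowledged failure mode: durations exceed the 10 s window, so
#'     these turns are missed by design.}
#'   \item{wrap}{large same-direction turns driving cumulative yaw across
#'     the +/-180 degree seam, including a 540 degree continuous rotation —
#'     the wrap must never create or split an event.}
#' }
#'
#' @param seed Integer seed controlling all draws.
#' @return Named list of scenarios, each a [render_script()] result plus the
#'   generating `script`.
#' @export
scenario_suite <- function(seed = 1L) {
  base_mags <- c(95, -120, 150, -180, 110, -100, 135, -160)
  base_durs <- c(1.5, 2, 2.5, 3, 2, 1.8, 2.2, 2.8)
  turns <- function(mags, durs, hes_fn = function(m) list()) {
    phases <- list(quiet_phase(3))
    for (i in seq_along(mags))
      phases <- c(phases, list(turn_phase(mags[i], durs[i],
                                          hesitations = hes_fn(mags[i]))),
                  list(quiet_phase(2.5)))
    phases
  }
  out <- list(
    clean = turn_script(turns(base_mags, base_durs),
                        gyro_noise_sd_dps = 0, accel_noise_sd = 0,
                        seed = seed),
    noisy = turn_script(turns(base_mags, base_durs), seed = seed + 1L),
    hesitant = turn_script(
      turns(c(120, -150, 140, -130, 160, -145),
            c(2.5, 3, 2.8, 2.6, 3.2, 2.9),
            hes_fn = function(m) list(c(0.5, 0.05 * abs(m), 0.3))),
      seed = seed + 2L),
    wide_radius = turn_script(
      turns(c(150, -160, 140), c(12, 14, 15)),
      gyro_noise_sd_dps = 0, accel_noise_sd = 0, seed = seed + 3L),
    wrap = turn_script(
      list(quiet_phase(3), turn_phase(170, 2.5), quiet_phase(2.5),
           turn_phase(170, 2.5), quiet_phase(2.5), turn_phase(540, 6),
           quiet_phase(2.5), turn_phase(-170, 2.5), quiet_phase(2.5)),
      gyro_noise_sd_dps = 0, accel_noise_sd = 0, seed = seed + 4L)
  )
  lapply(out, function(s) c(render_script(s), list(script = s)))
}
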