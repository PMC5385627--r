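#' Locate the quasi-static accelerometer window used for gravity alignment
#'
#' Scans for the earliest run of `window` consecutive samples whose per-axis
#' peak-to-peak accelerometer amplitude is below `pp_threshold` on every
#' axis. The mean accelerometer vector over that window estimates gravity in
#' the sensor frame and anchors the initial orientation.
#'
#' @param rec An [imu_recording()].
#' @param window Window length in samples (default 5; at 128 Hz the five
#'   samples span the first few hundredths of a second of a still recording).
#' @param pp_threshold Per-axis peak-to-peak stability bound, m/s^2
#'   (default 0.2).
#' @return An object of class `gravity_estimate`: list with `mean_accel`
#'   (3-vector, m/s^2), `inclination_deg` (angle between the gravity estimate
#'   and the sensor +Z axis, diagnostic only), `start_index` (1-based index
#'   of the first window sample) and `window`.
#' @details If no window in the whole recording is stable the function fails
#'   rather than guessing an initial frame; the caller may relax
#'   `pp_threshold`. A gravity-magnitude estimate outside 20% of 9.81 m/s^2
#'   indicates the window was not actually quasi-static and triggers a
#'   warning.
#' @export
find_stable_window <- function(rec, window = 5L, pp_threshold = 0.2) {
  stopifnot(inherits(rec, "imu_recording"))
  window <- as.integer(window)
  if (rec$n < window)
    stop("recording shorter than the stability window (", window, " samples)")
  # rolling per-axis peak-to-peak over all length-`window` runs
  ok <- rep(TRUE, rec$n - window + 1L)
  for (j in 1:3) {
    e <- embed(rec$accel[, j], window)
    pp <- apply(e, 1L, max) - apply(e, 1L, min)
    ok <- ok & (pp < pp_threshold)
  }
  idx <- which(ok)
  if (!length(idx))
    stop("initialization failure: no ", window, "-sample window with ",
         "per-axis peak-to-peak accel < ", pp_threshold,
         " m/s^2 found; the sensor never appears quasi-static")
  start <- idx[1L]
  g <- colMeans(rec$accel[start:(start + window - 1L), , drop = FALSE])
  gn <- sqrt(sum(g^2))
  if (abs(gn - 9.81) > 0.2 * 9.81)
    warning("stable-window accel magnitude ", format(round(gn, 3)),
            " m/s^2 deviates >20% from gravity; window may not be static")
  incl <- acos(max(-1, min(1, g[3L] / gn))) * 180 / pi
  structure(list(mean_accel = unname(g), inclination_deg = incl,
                 start_index = start, window = window),
            class = "gravity_estimate")
}

#' Initial sensor-to-global rotation from a gravity estimate
#'
#' Builds the initial rotation matrix whose rows are the global axes
#' expressed in the sensor frame: the global Z row is the normalised gravity
#' estimate; the X row is seeded with the sensor x axis `[1 0 0]` and the
#' triad completed by two cross products (Y = Z x X, then X = Y x Z) so the
#' result is orthonormal and right-handed. By this construction the initial
#' yaw of the attitude track is exactly 0.
#'
#' @param grav A `gravity_estimate` from [find_stable_window()], or a plain
#'   3-vector mean accelerometer reading (m/s^2).
#' @return A 3x3 orthonormal rotation matrix with determinant +1, mapping
#'   sensor-frame vectors to the global frame (`v_G = R %*% v_S`).
#' @details If gravity is parallel to the sensor x axis (within 1e-6) the
#'   seed degenerates and `[0 1 0]` is used instead (with a message).
#' @export
init_orientation <- function(grav) {
  g <- if (inherits(grav, "gravity_estimate")) grav$mean_accel else
    as.numeric(grav)
  stopifnot(length(g) == 3L, all(is.finite(g)))
  z <- g / sqrt(sum(g^2))
  seed <- c(1, 0, 0)
  if (sqrt(sum(cross3(z, seed)^2)) < 1e-6) {
    message("gravity parallel to sensor x axis; seeding yaw reference with y")
    seed <- c(0, 1, 0)
  }
  y <- cross3(z, seed)
  y <- y / sqrt(sum(y^2))
  x <- cross3(y, z)
  x <- x / sqrt(sum(x^2))
  rbind(x, y, z, deparse.level = 0)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rodrigues rotation matrix for one gyroscope sample
#'
#' Axis-angle rotation about the unit axis `w/||w||` by the angle
#' `theta = ||w|| / fs`, i.e. the orientation increment accrued over one
#' sampling interval at constant angular velocity `w`. A zero angular
#' velocity yields the identity.
#'
#' @param w Angular velocity 3-vector, rad/s (sensor or global frame; the
#'   result rotates vectors of the same frame).
#' @param fs Sampling rate, Hz.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_transform <- function(w, fs) {
  stopifnot(length(w) == 3L, all(is.finite(w)), fs > 0)
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(diag(3))
  theta <- nw / fs
  u <- w / nw
  c_ <- cos(theta); s <- sin(theta); t <- 1 - c_
  wx <- u[1L]; wy <- u[2L]; wz <- u[3L]
  matrix(c(t * wx * wx + c_,     t * wx * wy - s * wz, t * wx * wz + s * wy,
           t * wx * wy + s * wz, t * wy * wy + c_,     t * wy * wz - s * wx,
           t * wx * wz - s * wy, t * wy * wz + s * wx, t * wz * wz + c_),
         nrow = 3L, byrow = TRUE)
}

#' Propagate orientation through a recording (strapdown integration)
#'
#' Starting from the initial orientation `R0` (held fixed for all samples up
#' to `start`), each subsequent sample advances the rotation by the Rodrigues
#' increment of the gyroscope reading at the previous sample: the body rate
#' is mapped to the global frame (`w_G = R w_S`) and the update is
#' `R_new = transform(w_G) %*% R_old` (algebraically identical to
#' `R_old %*% transform(w_S)`). Euler angles (intrinsic Z-Y-X, degrees) and
#' the unwrapped yaw trace are emitted per sample.
#'
#' @param rec An [imu_recording()].
#' @param R0 Initial 3x3 rotation; default from [find_stable_window()] +
#'   [init_orientation()].
#' @param start 1-based sample index at which integration starts (default:
#'   the stable-window start).
#' @param window,pp_threshold Passed to [find_stable_window()] when `R0` is
#'   not supplied.
#' @return An object of class `attitude_track`: list with `t`, `R` (n x 9
#'   matrix, rows are row-major 3x3 rotations), `euler` (n x 3, degrees,
#'   columns roll/pitch/yaw with yaw wrapped to (-180, 180]), `yaw`
#'   (unwrapped yaw, degrees), `gw_z` (vertical global-frame angular rate,
#'   rad/s, used for the turn-direction integral), `fs`, `start_index`, and
#'   `n_reortho` (number of re-orthonormalisation events; drift beyond 1e-6
#'   from orthonormality is projected back and counted).
#' @export
propagate <- function(rec, R0 = NULL, start = NULL, window = 5L,
                      pp_threshold = 0.2) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(R0)) {
    grav <- find_stable_window(rec, window = window,
                               pp_threshold = pp_threshold)
    R0 <- init_orientation(grav)
    if (is.null(start)) start <- grav$start_index
  }
  if (is.null(start)) start <- 1L
  check_rotation(R0)
  out <- propagate_core(rec$gyro, rec$fs, R0, as.integer(start))
  yaw_wrapped <- out$euler[, 3L]
  structure(list(t = rec$t, R = out$R, euler = out$euler,
                 yaw = unwrap_yaw(yaw_wrapped), gw_z = out$gwz,
                 fs = rec$fs, start_index = as.integer(start),
                 n_reortho = out$n_reortho),
            class = "attitude_track")
}

#' @export
print.attitude_track <- function(x, ...) {
  n <- length(x$t)
  cat("attitude track: ", n, " samples at ", format(x$fs), " Hz; yaw range [",
      format(round(min(x$yaw), 1)), ", ", format(round(max(x$yaw), 1)),
      "] deg", if (x$n_reortho) paste0("; ", x$n_reortho,
      " re-orthonormalisation(s)"), "\n", sep = "")
  invisible(x)
}

check_rotation <- function(R, tol = 1e-9) {
  stopifnot(is.matrix(R), dim(R) == c(3L, 3L))
  if (max(abs(R %*% t(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("not a proper rotation matrix (orthonormal, det +1) within ", tol)
  invisible(R)
}

# Pure-R propagation, used as an independent cross-check of the compiled
# core. `convention` selects the global left-multiply or body right-multiply
# update; the two are algebraically identical.
propagate_ref <- function(gyro, fs, R0, start = 1L,
                          convention = c("global", "body")) {
  convention <- match.arg(convention)
  n <- nrow(gyro)
  Rm <- matrix(NA_real_, n, 9L)
  R <- R0
  for (i in seq_len(n)) {
    if (i > start) {
      w <- gyro[i - 1L, ]
      if (convention == "global") {
        R <- axis_angle_transform(as.numeric(R %*% w), fs) %*% R
      } else {
        R <- R %*% axis_angle_transform(w, fs)
      }
    }
    Rm[i, ] <- as.numeric(t(R))
  }
  Rm
}

#' Convert a rotation matrix to Euler angles
#'
#' Intrinsic Z-Y-X (yaw-pitch-roll) decomposition of a sensor-to-global
#' rotation: roll is the displacement about X, pitch about Y, yaw about the
#' vertical Z axis. Only yaw is consumed by turning detection.
#'
#' @param R 3x3 rotation matrix (`v_G = R v_S`).
#' @return Named numeric vector `c(roll, pitch, yaw)` in degrees, yaw in
#'   (-180, 180]. Near-gimbal-lock input (|pitch| > 89.9 deg) carries
#'   attribute `gimbal = TRUE`.
#' @export
to_euler <- function(R) {
  check_rotation(R, tol = 1e-6)
  pitch <- asin(max(-1, min(1, -R[3L, 1L])))
  yaw <- atan2(R[2L, 1L], R[1L, 1L])
  roll <- atan2(R[3L, 2L], R[3L, 3L])
  out <- c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
  if (out[["yaw"]] <= -180) out[["yaw"]] <- out[["yaw"]] + 360
  if (abs(out[["pitch"]]) > 89.9) attr(out, "gimbal") <- TRUE
  out
}

#' Unwrap a wrapped yaw series
#'
#' Removes the artificial +/-360 degree jumps a (-180, 180]-wrapped yaw trace
#' shows whenever the heading crosses the seam; the abrupt change when yaw
#' reaches 180 (to -180) or -180 (to 180) does not indicate a turn, so the
#' unwrapped trace is the signal turns are segmented from.
#'
#' @param yaw_deg Numeric vector of wrapped yaw angles, degrees.
#' @return Continuous yaw series in degrees: consecutive differences larger
#'   than 180 in absolute value are corrected by the appropriate multiple of
#'   360; the physical yaw rate is preserved.
#' @export
unwrap_yaw <- function(yaw_deg) {
  if (length(yaw_deg) < 2L) return(yaw_deg)
  d <- diff(yaw_deg)
  corr <- -360 * round(d / 360)
  yaw_deg + c(0, cumsum(corr))
}

#' Export a yaw trace for plotting
#'
#' Debug helper writing `t,yaw_deg_wrapped,yaw_deg_unwrapped` as CSV so the
#' segmentation input can be inspected alongside detected turns.
#'
#' @param track An `attitude_track` from [propagate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yaw_csv <- function(track, path) {
  stopifnot(inherits(track, "attitude_track"))
  utils::write.csv(data.frame(t = track$t,
                              yaw_deg_wrapped = track$euler[, 3L],
                              yaw_deg_unwrapped = track$yaw),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
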