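# Shared fixtures built in code.

# Stationary recording: gravity on +Z (optionally tilted), zero rates.
still_recording <- function(n = 256L, fs = 128, accel = c(0, 0, 9.81)) {
  imu_recording(t = (seq_len(n) - 1L) / fs,
                accel = matrix(accel, n, 3L, byrow = TRUE),
                gyro = matrix(0, n, 3L), fs = fs)
}

# Recording rotating at a constant body rate (rad/s) starting aligned.
const_rate_recording <- function(w, duration = 1, fs = 128) {
  n <- as.integer(round(duration * fs)) + 1L
  imu_recording(t = (seq_len(n) - 1L) / fs,
                accel = matrix(c(0, 0, 9.81), n, 3L, byrow = TRUE),
                gyro = matrix(w, n, 3L, byrow = TRUE), fs = fs)
}

# Closed-form rotation about Z (sensor-to-global, v_G = R v_S).
Rz <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

expect_rotation <- function(R, tol = 1e-9) {
  expect_lt(max(abs(R %*% t(R) - diag(3))), tol)
  expect_equal(det(R), 1, tolerance = tol)
}

# Sample a piecewise-linear yaw trajectory through `knots` (deg) at `fs`,
# spending `seg_s` seconds on each leg; knot times land on samples.
piecewise_yaw <- function(knots, seg_s = 1, fs = 16) {
  n_leg <- round(seg_s * fs)
  yaw <- knots[1L]
  for (k in seq_len(length(knots) - 1L))
    yaw <- c(yaw, knots[k] + (knots[k + 1L] - knots[k]) *
               seq_len(n_leg) / n_leg)
  list(yaw = yaw, t = (seq_along(yaw) - 1L) / fs)
}

# Hand-built tiling segment table (for exercising the hesitation rule).
make_segments <- function(mags, durs) {
  t_end <- cumsum(durs)
  t_start <- c(0, t_end[-length(t_end)])
  fs <- 100
  data.frame(start_idx = as.integer(round(t_start * fs)) + 1L,
             end_idx = as.integer(round(t_end * fs)) + 1L,
             t_start = t_start, t_end = t_end, duration = durs,
             magnitude = mags)
}
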