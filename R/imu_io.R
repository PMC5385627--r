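#' Construct a 6DOF IMU recording
#'
#' Bundles uniformly sampled tri-axial accelerometer and gyroscope data into
#' the container consumed by the attitude and turning modules. Internal units
#' are fixed: seconds, m/s^2 and rad/s; unit conversion happens only at the
#' I/O boundary (see [read_imu_csv()]).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing and
#'   uniformly spaced (absolute seconds from recording start).
#' @param accel n x 3 numeric matrix of accelerometer samples (m/s^2), sensor
#'   frame, columns x/y/z.
#' @param gyro n x 3 numeric matrix of gyroscope samples (rad/s), sensor
#'   frame, columns x/y/z.
#' @param fs Sampling rate in Hz. If `NULL`, inferred from the median
#'   timestamp spacing.
#'
#' @details Sampling must be uniform: any spacing deviating from `1/fs` by
#'   more than 1e-6 s is rejected with the index of the offending gap
#'   (resampling is out of scope).
#'
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `accel`, `gyro`, `fs` and `n`.
#' @seealso [read_imu_csv()], [detect_turns()], [render_script()]
#' @export
imu_recording <- function(t, accel, gyro, fs = NULL) {
  t <- as.numeric(t)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  storage.mode(accel) <- "double"
  storage.mode(gyro) <- "double"
  n <- length(t)
  if (n < 2L)
    stop("an IMU recording needs at least 2 samples, got ", n)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must have 3 columns (x, y, z)")
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("channel lengths differ: t=", n, ", accel=", nrow(accel),
         ", gyro=", nrow(gyro))
  if (anyNA(t) || anyNA(accel) || anyNA(gyro))
    stop("IMU recording contains missing values")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("timestamps not strictly increasing at index ",
         which(dt <= 0)[1L] + 1L)
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate: ", fs)
  bad <- which(abs(dt - 1 / fs) >= 1e-6)
  if (length(bad))
    stop("non-uniform sampling: gap of ", format(dt[bad[1L]]),
         " s (expected ", format(1 / fs), " s) between samples ",
         bad[1L], " and ", bad[1L] + 1L)
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(list(t = t, accel = accel, gyro = gyro, fs = fs, n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat("6DOF IMU recording: ", x$n, " samples at ", format(x$fs),
      " Hz (", format(round(x$t[x$n] - x$t[1L], 2)), " s)\n", sep = "")
  invisible(x)
}

#' Read an IMU recording from CSV
#'
#' Expects columns `t,ax,ay,az,gx,gy,gz` and an optional leading metadata
#' comment line of the form `# gyro_unit=deg_s fs=128`. Gyroscope values
#' declared in deg/s are converted to rad/s on read; accelerometer values are
#' taken as m/s^2.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz; if missing, taken from the metadata line or
#'   inferred from the timestamps.
#' @param gyro_unit Override for the gyroscope unit, `"rad_s"` or `"deg_s"`;
#'   default is the metadata line's declaration (falling back to rad/s).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, fs = NULL, gyro_unit = NULL) {
  first <- readLines(path, n = 1L)
  meta <- character(0)
  if (length(first) && startsWith(first, "#"))
    meta <- strsplit(trimws(sub("^#+", "", first)), "[[:space:]]+")[[1L]]
  meta_get <- function(key) {
    hit <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NULL
  }
  if (is.null(gyro_unit)) gyro_unit <- meta_get("gyro_unit")
  if (is.null(gyro_unit)) gyro_unit <- "rad_s"
  gyro_unit <- match.arg(gyro_unit, c("rad_s", "deg_s"))
  if (is.null(fs)) {
    fs_meta <- meta_get("fs")
    if (!is.null(fs_meta)) fs <- as.numeric(fs_meta)
  }
  dat <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("IMU CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  gyro <- as.matrix(dat[c("gx", "gy", "gz")])
  if (gyro_unit == "deg_s") gyro <- gyro * pi / 180
  imu_recording(dat$t, as.matrix(dat[c("ax", "ay", "az")]), gyro, fs = fs)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]: writes the metadata comment line followed by
#' the `t,ax,ay,az,gx,gy,gz` table.
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @param gyro_unit Unit to write the gyroscope columns in (`"rad_s"`, the
#'   internal unit, or `"deg_s"`).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, gyro_unit = c("rad_s", "deg_s")) {
  stopifnot(inherits(rec, "imu_recording"))
  gyro_unit <- match.arg(gyro_unit)
  gyro <- rec$gyro
  if (gyro_unit == "deg_s") gyro <- gyro * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gyro_unit=%s fs=%s", gyro_unit,
                     format(rec$fs, digits = 15)), con)
  dat <- data.frame(t = rec$t, rec$accel, gyro)
  names(dat) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  utils::write.csv(format(dat, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a table of turn events
#'
#' @param t_start,t_end Event interval in seconds (shared clock with the
#'   recording timestamps).
#' @param magnitude Absolute turn magnitude in degrees.
#' @param direction `"left"` or `"right"`.
#' @param source `"algorithm"` for detected events, `"reference"` for
#'   annotations. Filters (magnitude/duration) apply only to algorithm turns.
#' @return A `data.frame` of class `turn_events` with columns `t_start`,
#'   `t_end`, `duration`, `magnitude`, `direction`, `source`, sorted by
#'   `t_start`. Overlapping events within one source are kept but trigger a
#'   warning.
#' @export
turn_events <- function(t_start = numeric(0), t_end = numeric(0),
                        magnitude = numeric(0),
                        direction = character(0),
                        source = "algorithm") {
  n <- length(t_start)
  stopifnot(length(t_end) == n, length(magnitude) == n,
            length(direction) == n)
  if (length(source) == 1L) source <- rep(source, n)
  ev <- data.frame(t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   duration = as.numeric(t_end) - as.numeric(t_start),
                   magnitude = as.numeric(magnitude),
                   direction = as.character(direction),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(ev$duration <= 0)) stop("turn events must have t_end > t_start")
    if (any(ev$magnitude < 0)) stop("turn magnitudes must be >= 0")
    bad_dir <- setdiff(unique(ev$direction), c("left", "right"))
    if (length(bad_dir))
      stop("unknown turn direction(s): ", paste(bad_dir, collapse = ", "))
    ev <- ev[order(ev$t_start), , drop = FALSE]
    rownames(ev) <- NULL
    for (src in unique(ev$source)) {
      e <- ev[ev$source == src, , drop = FALSE]
      if (nrow(e) > 1L && any(e$t_start[-1L] < e$t_end[-nrow(e)]))
        warning("overlapping turn events in source '", src,
                "' preserved as-is")
    }
  }
  class(ev) <- c("turn_events", "data.frame")
  ev
}

#' Write / read turn events
#'
#' Lossless round trip of detected or reference turn events. Format follows
#' the file extension: `.json` gives an array of objects with keys `t_start`,
#' `t_end`, `duration`, `magnitude_deg`, `direction`, `source`; anything else
#' is written as CSV with the same fields.
#'
#' @param events A [turn_events()] table (sorted by `t_start`).
#' @param path Output/input path.
#' @return `write_turns()` returns `path` invisibly; `read_turns()` returns a
#'   [turn_events()] table.
#' @export
write_turns <- function(events, path) {
  events <- as.data.frame(events)
  out <- data.frame(t_start = events$t_start, t_end = events$t_end,
                    duration = events$duration,
                    magnitude_deg = events$magnitude,
                    direction = events$direction, source = events$source,
                    stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_turns
#' @export
read_turns <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    dat <- jsonlite::fromJSON(path)
    if (length(dat) == 0L) dat <- NULL
  } else {
    dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.null(dat) || NROW(dat) == 0L) return(turn_events())
  turn_events(dat$t_start, dat$t_end, dat$magnitude_deg, dat$direction,
              dat$source)
}
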