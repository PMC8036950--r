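#' Sensor specifications for the wrist-worn 9-DoF IMU
#'
#' Returns the physical ranges, shipped sampling rates, and post-resampling
#' target rates of the four sensors in the unit: a low-g accelerometer
#' (+/-16 g, 1125 Hz), a high-g accelerometer (+/-200 g, 1600 Hz), a gyroscope
#' (+/-2000 deg/s, 1125 Hz), and a magnetometer (+/-4900 uT, 100 Hz; carried
#' for completeness, never resampled and unused by the feature inventory).
#' The low-g accelerometer and the gyroscope are resampled to 1150 Hz and the
#' high-g accelerometer to 1600 Hz to absorb sampling-frequency fluctuation
#' among sensors.
#'
#' @return A data.frame with columns `name`, `range`, `units`,
#'   `nominal_rate_hz`, and `target_rate_hz` (NA for the magnetometer).
#' @export
sensor_specs <- function() {
  data.frame(
    name = c("acc_low", "acc_high", "gyro", "mag"),
    range = c(16, 200, 2000, 4900),
    units = c("g", "g", "dps", "uT"),
    nominal_rate_hz = c(1125, 1600, 1125, 100),
    target_rate_hz = c(1150, 1600, 1150, NA),
    stringsAsFactors = FALSE
  )
}

#' Default CSV column schema for session files
#'
#' Session files are comma-separated with a header row, UTF-8, '.' decimal:
#' one timestamp column (seconds) plus three columns per sensor. Sensors
#' sampled at different rates occupy different rows; cells belonging to the
#' other sensors on such rows are empty (NA). The magnetometer columns are
#' optional.
#'
#' @return A list with elements `time` (timestamp column name) and `sensors`
#'   (named list mapping sensor name to its three axis column names).
#' @export
default_schema <- function() {
  list(
    time = "time_s",
    sensors = list(
      acc_low = c("alx", "aly", "alz"),
      acc_high = c("ahx", "ahy", "ahz"),
      gyro = c("gx", "gy", "gz"),
      mag = c("mx", "my", "mz")
    )
  )
}

#' Read a raw multi-rate IMU session from CSV
#'
#' Reads a per-session CSV and splits it into per-sensor timestamped axis
#' arrays. For each sensor, rows where the timestamp or any of the sensor's
#' three axes is non-finite are dropped (and counted), so sensors sampled at
#' different rates can share one file. Timestamps must be strictly increasing
#' within each sensor after filtering.
#'
#' @param path Path to the session CSV.
#' @param schema Column mapping as produced by [default_schema()] (or read
#'   from a YAML file with [read_schema()]).
#' @param subject_id Optional subject label attached to the recording.
#' @return A `raw_recording`: list with `subject_id`, `sensors` (per sensor a
#'   list with `t`, `x`, `y`, `z`), and `dropped` (named count of discarded
#'   rows per sensor).
#' @export
read_recording <- function(path, schema = default_schema(), subject_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!schema$time %in% names(df)) {
    stop("schema error: timestamp column '", schema$time, "' missing")
  }
  sensors <- list()
  dropped <- integer(0)
  for (sname in names(schema$sensors)) {
    cols <- schema$sensors[[sname]]
    have <- cols %in% names(df)
    if (!all(have)) {
      if (sname == "mag") next  # magnetometer optional
      stop("schema error: missing column(s) for sensor '", sname, "': ",
           paste(cols[!have], collapse = ", "))
    }
    t <- df[[schema$time]]
    vals <- as.matrix(df[cols])
    keep <- is.finite(t) & rowSums(!is.finite(vals)) == 0
    dropped[sname] <- sum(!keep)
    t <- t[keep]
    vals <- vals[keep, , drop = FALSE]
    if (length(t) == 0) next
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      stop("data error: non-monotonic timestamps for sensor '", sname,
           "' at row index ", bad[1] + 1L)
    }
    sensors[[sname]] <- list(t = t, x = vals[, 1], y = vals[, 2], z = vals[, 3])
  }
  structure(
    list(subject_id = subject_id, sensors = sensors, dropped = dropped),
    class = "raw_recording"
  )
}

#' Read a column schema from a YAML file
#'
#' @param path YAML file with fields `time` and `sensors` (sensor name to
#'   three axis column names).
#' @return A schema list usable with [read_recording()].
#' @export
read_schema <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$time) || is.null(sc$sensors)) {
    stop("schema error: YAML must define 'time' and 'sensors'")
  }
  sc$sensors <- lapply(sc$sensors, unlist)
  sc
}

#' Linear-interpolation resampling onto a uniform grid
#'
#' Resamples one irregularly sampled axis onto a uniform grid anchored at the
#' first input timestamp. The grid spans `[t[1], t[n]]` at exact spacing
#' `1/target_rate_hz`; each output value is the linear interpolant of the
#' bracketing input samples. There is no extrapolation beyond the input range.
#'
#' @param t Strictly increasing timestamps, seconds.
#' @param v Values at `t`.
#' @param target_rate_hz Target sampling rate, Hz.
#' @return List with `t0` (grid origin), `rate_hz`, and `values`.
#' @export
resample_linear <- function(t, v, target_rate_hz) {
  if (length(t) < 2) stop("insufficient data: need at least 2 samples to resample")
  if (length(t) != length(v)) stop("timestamp/value length mismatch")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (target_rate_hz <= 0) stop("target rate must be positive")
  n_out <- floor((t[length(t)] - t[1]) * target_rate_hz) + 1L
  grid <- t[1] + (seq_len(n_out) - 1L) / target_rate_hz
  out <- stats::approx(t, v, xout = grid, method = "linear", rule = 1)$y
  list(t0 = t[1], rate_hz = target_rate_hz, values = out)
}

#' Resample a raw recording into uniform sensor streams
#'
#' Applies [resample_linear()] axis-wise to every feature-bearing sensor
#' (low-g accelerometer, high-g accelerometer, gyroscope) at its target rate.
#' The magnetometer carries no features and is omitted from the output.
#'
#' @param raw A `raw_recording` (from [read_recording()] or the simulator).
#' @param specs Sensor specification table, see [sensor_specs()].
#' @return Named list of `sensor_stream` objects (`sensor`, `rate_hz`, `t0`,
#'   `x`, `y`, `z`, `units`), one per feature-bearing sensor.
#' @export
to_streams <- function(raw, specs = sensor_specs()) {
  needed <- c("acc_low", "acc_high", "gyro")
  missing <- setdiff(needed, names(raw$sensors))
  if (length(missing) > 0) {
    stop("configuration error: recording lacks feature-bearing sensor(s): ",
         paste(missing, collapse = ", "))
  }
  streams <- list()
  for (sname in needed) {
    spec <- specs[specs$name == sname, ]
    s <- raw$sensors[[sname]]
    rx <- resample_linear(s$t, s$x, spec$target_rate_hz)
    ry <- resample_linear(s$t, s$y, spec$target_rate_hz)
    rz <- resample_linear(s$t, s$z, spec$target_rate_hz)
    streams[[sname]] <- structure(
      list(sensor = sname, rate_hz = spec$target_rate_hz, t0 = rx$t0,
           x = rx$values, y = ry$values, z = rz$values, units = spec$units),
      class = "sensor_stream"
    )
  }
  streams
}

#' Timestamps of a uniform sensor stream
#'
#' @param stream A `sensor_stream`.
#' @return Numeric vector of sample times, seconds.
#' @export
stream_times <- function(stream) {
  stream$t0 + (seq_along(stream$x) - 1L) / stream$rate_hz
}

#' Write a recording (or simulated session) to the session CSV dialect
#'
#' Sensors with distinct timestamps are written on separate rows; each row
#' carries the timestamp plus that sensor's three axis values, with the other
#' sensors' cells empty. The result round-trips through [read_recording()].
#'
#' @param raw A `raw_recording` or `simulated_session`.
#' @param path Output CSV path.
#' @param schema Column mapping, see [default_schema()].
#' @return Invisibly, the path.
#' @export
write_session_csv <- function(raw, path, schema = default_schema()) {
  pieces <- list()
  all_cols <- unlist(schema$sensors[names(raw$sensors)], use.names = FALSE)
  for (sname in names(raw$sensors)) {
    cols <- schema$sensors[[sname]]
    if (is.null(cols)) next
    s <- raw$sensors[[sname]]
    piece <- data.frame(time = s$t)
    names(piece) <- schema$time
    for (cn in all_cols) piece[[cn]] <- NA_real_
    piece[[cols[1]]] <- s$x
    piece[[cols[2]]] <- s$y
    piece[[cols[3]]] <- s$z
    pieces[[sname]] <- piece
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out[[schema$time]]), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
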