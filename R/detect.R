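#' Throw-detection configuration
#'
#' A throw is recognised as a supra-threshold excursion of the gyroscope
#' y-axis: the wrist rotates past `threshold_dps` only during the acceleration
#' phase of a throw. Excursions closer together than `min_separation_s` are
#' merged (a handball throw cannot recur faster), keeping the larger peak.
#'
#' @param threshold_dps Detection threshold on gyroscope y, deg/s.
#' @param min_separation_s Minimum time between distinct events, seconds.
#' @param window_sizes_s Window lengths cut around each event, seconds.
#' @param use_abs Threshold `|gyro-y|` instead of signed gyro-y.
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold_dps = 1500, min_separation_s = 1,
                             window_sizes_s = c(2, 3, 4, 6), use_abs = FALSE) {
  stopifnot(threshold_dps > 0, min_separation_s > 0, all(window_sizes_s > 0))
  structure(
    list(threshold_dps = threshold_dps, min_separation_s = min_separation_s,
         window_sizes_s = window_sizes_s, use_abs = use_abs),
    class = "detection_config"
  )
}

#' Detect peak-rotation throw events on the gyroscope y-axis
#'
#' Finds contiguous runs of samples at or above the threshold, takes each
#' run's maximum as a candidate event, then merges candidates closer than
#' `min_separation_s`, keeping the larger peak. Events are returned in time
#' order.
#'
#' @param gyro A gyroscope `sensor_stream` (uniform grid).
#' @param cfg A [detection_config()].
#' @return data.frame with one row per event: `t_peak` (s), `peak_dps`,
#'   `index_gyro` (sample index on the gyro stream).
#' @export
detect_throws <- function(gyro, cfg = detection_config()) {
  if (!inherits(gyro, "sensor_stream")) {
    stop("contract violation: detect_throws requires a uniform sensor_stream")
  }
  y <- gyro$y
  if (cfg$use_abs) y <- abs(y)
  empty <- data.frame(t_peak = numeric(0), peak_dps = numeric(0),
                      index_gyro = integer(0))
  if (length(y) == 0) return(empty)
  over <- y >= cfg$threshold_dps
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  idx <- mapply(function(s, e) s + which.max(y[s:e]) - 1L, starts, ends)
  peaks <- y[idx]
  t_peak <- gyro$t0 + (idx - 1L) / gyro$rate_hz
  # merge events closer than min_separation_s, keeping the larger peak
  keep_i <- integer(0)
  for (k in seq_along(idx)) {
    if (length(keep_i) == 0) {
      keep_i <- k
    } else {
      last <- keep_i[length(keep_i)]
      if (t_peak[k] - t_peak[last] >= cfg$min_separation_s) {
        keep_i <- c(keep_i, k)
      } else if (peaks[k] > peaks[last]) {
        keep_i[length(keep_i)] <- k
      }
    }
  }
  data.frame(t_peak = t_peak[keep_i], peak_dps = peaks[keep_i],
             index_gyro = as.integer(idx[keep_i]))
}

#' Cut a multi-channel window centered on a throw event
#'
#' Extracts, from every feature-bearing stream, `round(window_s * rate)`
#' samples centered on the event's peak time. Each sensor is located by time
#' (not by shared index), so multi-rate streams stay aligned. Windows that
#' would extend beyond the recording are discarded (returned as `NULL`): a
#' padded window would distort spectral and moment features.
#'
#' @param streams Named list of `sensor_stream`s (from [to_streams()]).
#' @param event One row of the data.frame returned by [detect_throws()], or a
#'   list with `t_peak`.
#' @param window_s Window length, seconds.
#' @return A `throw_window` (list with `event`, `window_s`, and per-sensor
#'   excerpts, each a list with `rate_hz`, `x`, `y`, `z`), or `NULL` when the
#'   window exceeds the recording bounds.
#' @export
extract_window <- function(streams, event, window_s) {
  stopifnot(window_s > 0)
  excerpts <- list()
  for (sname in names(streams)) {
    s <- streams[[sname]]
    n <- round(window_s * s$rate_hz)
    center <- round((event$t_peak - s$t0) * s$rate_hz) + 1L
    i0 <- center - floor(n / 2)
    i1 <- i0 + n - 1L
    if (i0 < 1L || i1 > length(s$x)) return(NULL)
    excerpts[[sname]] <- list(rate_hz = s$rate_hz,
                              x = s$x[i0:i1], y = s$y[i0:i1], z = s$z[i0:i1])
  }
  structure(list(event = event, window_s = window_s, excerpts = excerpts),
            class = "throw_window")
}

#' Cut windows for a set of events, discarding out-of-bounds ones
#'
#' @param streams Named list of `sensor_stream`s.
#' @param events data.frame from [detect_throws()].
#' @param window_s Window length, seconds.
#' @return List with `windows` (list of `throw_window`), `kept` (row indices
#'   of `events` that produced a window), and `discarded` (data.frame of
#'   event index + reason).
#' @export
cut_windows <- function(streams, events, window_s) {
  windows <- list()
  kept <- integer(0)
  disc <- list()
  for (i in seq_len(nrow(events))) {
    w <- extract_window(streams, events[i, ], window_s)
    if (is.null(w)) {
      disc[[length(disc) + 1L]] <- data.frame(
        event = i,
        reason = sprintf("window %gs at t=%.3fs exceeds recording bounds",
                         window_s, events$t_peak[i]))
    } else {
      windows[[length(windows) + 1L]] <- w
      kept <- c(kept, i)
    }
  }
  discarded <- if (length(disc)) do.call(rbind, disc) else
    data.frame(event = integer(0), reason = character(0))
  list(windows = windows, kept = kept, discarded = discarded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match detected events to ground-truth times
#'
#' Greedy one-to-one matching by time proximity: candidate pairs within
#' `tol_s` are taken in order of increasing |dt|, each detection and each
#' truth time used at most once.
#'
#' @param detected_times Detected event times, seconds.
#' @param truth_times Ground-truth event times, seconds.
#' @param tol_s Matching tolerance, seconds.
#' @return List with `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`, and `undefined_precision` (TRUE when there were no detections,
#'   in which case precision is reported as 0).
#' @export
match_events_to_truth <- function(detected_times, truth_times, tol_s = 0.1) {
  stopifnot(tol_s > 0)
  nd <- length(detected_times)
  nt <- length(truth_times)
  pairs <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  if (nrow(pairs) > 0) {
    pairs$dt <- abs(detected_times[pairs$d] - truth_times[pairs$t])
    pairs <- pairs[pairs$dt <= tol_s, , drop = FALSE]
    pairs <- pairs[order(pairs$dt), , drop = FALSE]
  }
  used_d <- logical(nd)
  used_t <- logical(nt)
  matched <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; t <- pairs$t[i]
    if (!used_d[d] && !used_t[t]) {
      used_d[d] <- TRUE
      used_t[t] <- TRUE
      matched <- matched + 1L
    }
  }
  list(
    precision = if (nd == 0) 0 else matched / nd,
    recall = if (nt == 0) 1 else matched / nt,
    n_matched = matched, n_detected = nd, n_truth = nt,
    undefined_precision = nd == 0
  )
}
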