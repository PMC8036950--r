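#' Per-sample vector magnitude of a triaxial signal
#'
#' @param x,y,z Equal-length axis sequences.
#' @return `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("contract error: axes must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

# Names of the 16 per-channel statistics, in catalogue order.
CHANNEL_STATS <- c(
  "mean", "sum", "sd", "variance", "cv", "min", "max", "amp", "iqr",
  "skewness", "kurtosis", "power", "rms", "autocorr_lag1",
  "dominant_frequency", "spectral_entropy"
)

#' The 16 per-channel signal statistics of one windowed channel
#'
#' Computes, for one channel of a throw window: mean, sum, sd, variance,
#' coefficient of variation (sd/|mean|, 0 when the mean is ~0), min, max,
#' peak-to-peak amplitude, interquartile range, skewness and excess kurtosis
#' (Fisher moment definitions, no bias correction, 0 for constant signals),
#' power (mean of squares), RMS, lag-1 autocorrelation (Pearson correlation of
#' the signal with itself shifted one sample, 0 for ~zero variance), dominant
#' frequency (periodogram argmax of the mean-removed signal, zero bin
#' excluded), and spectral entropy (Shannon entropy of the normalised
#' periodogram divided by log of the number of bins, in [0, 1]).
#'
#' @param v Channel values (length >= 8).
#' @param rate_hz Sampling rate of the channel, Hz.
#' @return Named numeric vector of the 16 statistics.
#' @export
channel_features <- function(v, rate_hz) {
  n <- length(v)
  if (n < 8) stop("contract error: channel too short (need >= 8 samples)")
  if (rate_hz <= 0) stop("contract error: rate must be positive")
  m <- mean(v)
  s <- stats::sd(v)
  centered <- v - m
  m2 <- mean(centered^2)
  degen <- m2 < 1e-20 * max(1, mean(v^2))
  skw <- if (degen) 0 else mean(centered^3) / m2^1.5
  krt <- if (degen) 0 else mean(centered^4) / m2^2 - 3
  cv <- if (abs(m) < 1e-12) 0 else s / abs(m)
  ac1 <- if (degen) 0 else {
    a <- v[-n]; b <- v[-1]
    if (stats::sd(a) < 1e-15 || stats::sd(b) < 1e-15) 0 else stats::cor(a, b)
  }
  # one-sided periodogram of the mean-removed signal, zero bin excluded
  spec <- Mod(stats::fft(centered))^2
  nb <- floor(n / 2)
  p <- spec[2:(nb + 1L)]
  tot <- sum(p)
  if (tot < 1e-20 * max(1, sum(v^2))) {
    dfr <- 0
    ent <- 0
  } else {
    dfr <- which.max(p) * rate_hz / n
    pn <- p / tot
    pn <- pn[pn > 0]
    ent <- -sum(pn * log(pn)) / log(nb)
  }
  c(
    mean = m, sum = sum(v), sd = s, variance = stats::var(v), cv = cv,
    min = min(v), max = max(v), amp = max(v) - min(v),
    iqr = stats::IQR(v), skewness = skw, kurtosis = krt,
    power = mean(v^2), rms = sqrt(mean(v^2)), autocorr_lag1 = ac1,
    dominant_frequency = dfr, spectral_entropy = ent
  )
}

#' Pearson correlations between the three axes of a sensor
#'
#' @param x,y,z Equal-length axis sequences (length >= 3). An axis with
#'   (near-)zero variance yields 0 for its correlations.
#' @return Named vector `c(r_xy, r_xz, r_yz)`, each in [-1, 1].
#' @export
cross_axis_correlations <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("contract error: axes must have equal length")
  }
  if (length(x) < 3) stop("contract error: need >= 3 samples")
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-15 || stats::sd(b) < 1e-15) 0 else stats::cor(a, b)
  }
  c(r_xy = safe_cor(x, y), r_xz = safe_cor(x, z), r_yz = safe_cor(y, z))
}

#' The 201-feature catalogue
#'
#' Twelve channels (low-g accelerometer, high-g accelerometer, and gyroscope,
#' each with axes x, y, z and the vector magnitude) times the 16 per-channel
#' statistics, plus the three between-axis correlations of each sensor:
#' 12 x 16 + 3 x 3 = 201 named features. Names follow the
#' `<acc|gyr>_<x|y|z|vm>_<stat>` convention, with suffix `_h` marking features
#' obtained from the high-g accelerometer. Between-axis correlations use the
#' measured axes only (the derived vector magnitude is excluded).
#'
#' @return data.frame with columns `name`, `sensor`, `channel`, `stat` and a
#'   `version` attribute identifying the catalogue revision.
#' @export
feature_catalogue <- function() {
  sensors <- c("acc_low", "acc_high", "gyro")
  prefix <- c(acc_low = "acc", acc_high = "acc", gyro = "gyr")
  suffix <- c(acc_low = "", acc_high = "_h", gyro = "")
  rows <- list()
  for (sname in sensors) {
    for (ch in c("x", "y", "z", "vm")) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(prefix[sname], "_", ch, "_", CHANNEL_STATS, suffix[sname]),
        sensor = sname, channel = ch, stat = CHANNEL_STATS,
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(prefix[sname], "_", c("xy", "xz", "yz"), "_cor", suffix[sname]),
      sensor = sname, channel = "cross",
      stat = paste0("cor_", c("xy", "xz", "yz")),
      stringsAsFactors = FALSE
    )
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  attr(cat, "version") <- "throwsense-catalogue-1"
  cat
}

#' Featurize one throw window
#'
#' Computes the full 201-feature vector for a throw window: for every sensor
#' excerpt, the 16 statistics of x, y, z and the vector magnitude, plus the
#' three between-axis correlations, in catalogue order.
#'
#' @param w A `throw_window` from [extract_window()].
#' @param catalogue Feature catalogue, see [feature_catalogue()].
#' @return Named numeric vector of 201 finite values.
#' @export
featurize_throw <- function(w, catalogue = feature_catalogue()) {
  out <- numeric(0)
  for (sname in c("acc_low", "acc_high", "gyro")) {
    e <- w$excerpts[[sname]]
    if (is.null(e)) stop("window lacks sensor '", sname, "'")
    if (length(e$x) < 8) {
      stop("excerpt too short for sensor '", sname, "' (", length(e$x),
           " samples)")
    }
    chans <- list(x = e$x, y = e$y, z = e$z,
                  vm = vector_magnitude(e$x, e$y, e$z))
    for (ch in names(chans)) {
      out <- c(out, channel_features(chans[[ch]], e$rate_hz))
    }
    out <- c(out, cross_axis_correlations(e$x, e$y, e$z))
  }
  names(out) <- catalogue$name
  if (!all(is.finite(out))) {
    stop("non-finite feature value(s): ",
         paste(catalogue$name[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Column names of the high-g and low-g feature sets
#'
#' Both sets share the 67 gyroscope features; the high-g set adds the 67
#' high-g accelerometer features and the low-g set the 67 low-g accelerometer
#' features (134 columns each; their union is the full 201).
#'
#' @param catalogue Feature catalogue.
#' @return List with character vectors `high_g` and `low_g`.
#' @export
range_feature_sets <- function(catalogue = feature_catalogue()) {
  list(
    high_g = catalogue$name[catalogue$sensor %in% c("gyro", "acc_high")],
    low_g = catalogue$name[catalogue$sensor %in% c("gyro", "acc_low")]
  )
}

#' Split a full feature matrix into high-g and low-g range sets
#'
#' @param fm data.frame holding the 201 feature columns plus any label
#'   columns; label columns are carried through unchanged.
#' @param catalogue Feature catalogue.
#' @return List of two data.frames, `high_g` and `low_g`, each with 134
#'   feature columns plus the label columns.
#' @export
split_range_sets <- function(fm, catalogue = feature_catalogue()) {
  sets <- range_feature_sets(catalogue)
  missing <- setdiff(catalogue$name, names(fm))
  if (length(missing) > 0) {
    stop("feature matrix lacks catalogue column(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  labels <- setdiff(names(fm), catalogue$name)
  list(
    high_g = fm[, c(labels, sets$high_g), drop = FALSE],
    low_g = fm[, c(labels, sets$low_g), drop = FALSE]
  )
}
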