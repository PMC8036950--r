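# Independent brute-force oracles, deliberately written with different code
# paths than the package implementations.

# All 16 channel statistics from first principles (explicit sums, O(n^2) DFT).
oracle_channel_stats <- function(v, rate_hz) {
  n <- length(v)
  m <- sum(v) / n
  dev <- v - m
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  sdv <- sqrt(sum(dev^2) / (n - 1))
  # explicit DFT of the mean-removed signal
  k <- 1:floor(n / 2)
  P <- vapply(k, function(kk) {
    re <- sum(dev * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(dev * sin(-2 * pi * kk * (0:(n - 1)) / n))
    re^2 + im^2
  }, numeric(1))
  tot <- sum(P)
  if (tot < 1e-20 * max(1, sum(v^2))) {
    dfr <- 0; ent <- 0
  } else {
    dfr <- k[which.max(P)] * rate_hz / n
    pn <- P / tot
    pn <- pn[pn > 0]
    ent <- -sum(pn * log(pn)) / log(length(P))
  }
  degen <- m2 < 1e-20 * max(1, sum(v^2) / n)
  a <- v[1:(n - 1)]; b <- v[2:n]
  ac1 <- if (degen || stats::sd(a) < 1e-15 || stats::sd(b) < 1e-15) 0 else {
    ma <- mean(a); mb <- mean(b)
    sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }
  c(mean = m, sum = sum(v), sd = sdv, variance = sum(dev^2) / (n - 1),
    cv = if (abs(m) < 1e-12) 0 else sdv / abs(m),
    min = min(v), max = max(v), amp = max(v) - min(v),
    iqr = unname(diff(stats::quantile(v, c(0.25, 0.75)))),
    skewness = if (degen) 0 else m3 / m2^1.5,
    kurtosis = if (degen) 0 else m4 / m2^2 - 3,
    power = sum(v^2) / n, rms = sqrt(sum(v^2) / n),
    autocorr_lag1 = ac1, dominant_frequency = dfr, spectral_entropy = ent)
}

# Greedy correlation pruning re-implemented from scratch: recompute the
# correlation matrix of the surviving columns at every iteration.
oracle_greedy_prune <- function(x, cutoff = 0.95) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  colnames(x) <- nm
  keep <- nm
  repeat {
    if (length(keep) < 2) break
    C <- suppressWarnings(abs(stats::cor(x[, keep, drop = FALSE])))
    C[!is.finite(C)] <- 0
    diag(C) <- 0
    if (max(C) <= cutoff) break
    w <- which(C == max(C), arr.ind = TRUE)[1, ]
    cand <- keep[c(w[1], w[2])]
    means <- c(mean(C[w[1], -w[1]]), mean(C[w[2], -w[2]]))
    drop <- if (means[1] > means[2]) cand[1]
            else if (means[2] > means[1]) cand[2]
            else cand[which.max(match(cand, nm))]
    keep <- setdiff(keep, drop)
  }
  keep
}

# Uniform synthetic gyro-like stream with given y values.
make_stream <- function(y, rate_hz = 100, t0 = 0, sensor = "gyro",
                        x = NULL, z = NULL) {
  if (is.null(x)) x <- numeric(length(y))
  if (is.null(z)) z <- numeric(length(y))
  structure(
    list(sensor = sensor, rate_hz = rate_hz, t0 = t0, x = x, y = y, z = z,
         units = if (sensor == "gyro") "dps" else "g"),
    class = "sensor_stream"
  )
}

# Raised-cosine pulse evaluated on a time grid (mirrors the simulator shape).
pulse_on <- function(t, tc, w, amp) {
  out <- numeric(length(t))
  i <- which(abs(t - tc) < w / 2)
  out[i] <- amp * 0.5 * (1 + cos(2 * pi * (t[i] - tc) / w))
  out
}
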