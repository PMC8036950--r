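test_that("vector magnitude is the per-sample Euclidean norm", {
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(numeric(3), numeric(3), numeric(3)),
               numeric(3))
  set.seed(10)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  brute <- vapply(1:50, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2),
                  numeric(1))
  expect_equal(vector_magnitude(x, y, z), brute, tolerance = 1e-12)
  expect_error(vector_magnitude(1:3, 1:2, 1:3), "equal length")
})

test_that("constant-signal policies: zero spread, zero shape, defined power", {
  f <- channel_features(rep(2, 16), 100)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["amp"]], 0)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["cv"]], 0)
  expect_equal(f[["power"]], 4)
  expect_equal(f[["autocorr_lag1"]], 0)
  expect_equal(f[["spectral_entropy"]], 0)
})

test_that("order statistics of a ramp match hand computation", {
  f <- channel_features(1:8, 100)
  expect_equal(f[["mean"]], 4.5)
  expect_equal(f[["sum"]], 36)
  expect_equal(f[["min"]], 1)
  expect_equal(f[["max"]], 8)
  expect_equal(f[["amp"]], 7)
  expect_equal(f[["iqr"]], 3.5)
  expect_equal(f[["variance"]], 6)
  expect_equal(f[["power"]], 25.5)
  expect_error(channel_features(1:7, 100), "too short")
})

test_that("a pure 5 Hz tone has dominant frequency 5 and power 1/2", {
  t <- (0:199) / 100
  v <- sin(2 * pi * 5 * t)
  f <- channel_features(v, 100)
  expect_equal(f[["dominant_frequency"]], 5)
  expect_equal(f[["power"]], 0.5, tolerance = 1e-9)
  expect_lt(f[["spectral_entropy"]], 0.05)
})

test_that("all 16 statistics match the brute-force oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(c(16, 64, 101), 1)
    v <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    rate <- sample(c(50, 100, 1150), 1)
    expect_equal(channel_features(v, rate), oracle_channel_stats(v, rate),
                 tolerance = 1e-9)
  }
})

test_that("statistics scale and stay invariant as their definitions demand", {
  set.seed(12)
  v <- rnorm(64, 1, 2)
  a <- 3.7
  f1 <- channel_features(v, 100)
  f2 <- channel_features(a * v, 100)
  linear <- c("mean", "sum", "sd", "min", "max", "amp", "iqr", "rms")
  for (s in linear) expect_equal(f2[[s]], a * f1[[s]], tolerance = 1e-9)
  for (s in c("variance", "power")) {
    expect_equal(f2[[s]], a^2 * f1[[s]], tolerance = 1e-9)
  }
  invariant <- c("cv", "skewness", "kurtosis", "autocorr_lag1",
                 "dominant_frequency", "spectral_entropy")
  for (s in invariant) expect_equal(f2[[s]], f1[[s]], tolerance = 1e-9)
})

test_that("between-axis correlations behave like Pearson r", {
  x <- as.numeric(1:20)
  expect_equal(cross_axis_correlations(x, x, -x),
               c(r_xy = 1, r_xz = -1, r_yz = -1))
  # degenerate variance policy
  expect_equal(cross_axis_correlations(x, rep(1, 20), x)[["r_xy"]], 0)
  set.seed(13)
  r <- cross_axis_correlations(rnorm(2300), rnorm(2300), rnorm(2300))
  expect_true(all(abs(r) < 0.1))
})

test_that("the catalogue enumerates exactly 201 uniquely named features", {
  cat <- feature_catalogue()
  expect_equal(nrow(cat), 201L)
  expect_false(any(duplicated(cat$name)))
  # 12 channels x 16 statistics + 3 sensors x 3 correlations
  expect_equal(sum(cat$channel != "cross"), 12 * 16)
  expect_equal(sum(cat$channel == "cross"), 9)
  for (s in c("mean", "variance", "power", "amp", "autocorr_lag1",
              "skewness", "kurtosis", "cv", "dominant_frequency",
              "spectral_entropy", "iqr", "sum", "sd")) {
    expect_true(s %in% cat$stat)
  }
  # high-g accelerometer features end in 'h'
  expect_true(all(grepl("h$", cat$name[cat$sensor == "acc_high"])))
  expect_false(any(grepl("_h$", cat$name[cat$sensor != "acc_high"])))
})

fake_window <- function(n = 64, rate = 100, seed = 14) {
  set.seed(seed)
  ex <- function() list(rate_hz = rate, x = rnorm(n), y = rnorm(n),
                        z = rnorm(n))
  structure(list(event = list(t_peak = 1), window_s = n / rate,
                 excerpts = list(acc_low = ex(), acc_high = ex(),
                                 gyro = ex())),
            class = "throw_window")
}

test_that("featurize_throw returns 201 finite values, deterministically", {
  w <- fake_window()
  fv <- featurize_throw(w)
  expect_length(fv, 201L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_catalogue()$name)
  expect_identical(fv, featurize_throw(w))
})

test_that("duplicated accelerometer data gives equal high/low features", {
  w <- fake_window()
  w$excerpts$acc_high <- w$excerpts$acc_low
  fv <- featurize_throw(w)
  cat <- feature_catalogue()
  low <- fv[cat$name[cat$sensor == "acc_low"]]
  high <- fv[cat$name[cat$sensor == "acc_high"]]
  expect_equal(unname(low), unname(high))
})

test_that("range sets split into 134 + 134 sharing the 67 gyro columns", {
  sets <- range_feature_sets()
  expect_length(sets$high_g, 134L)
  expect_length(sets$low_g, 134L)
  shared <- intersect(sets$high_g, sets$low_g)
  expect_length(shared, 67L)
  expect_true(all(startsWith(shared, "gyr_")))
  expect_length(union(sets$high_g, sets$low_g), 201L)

  fv <- featurize_throw(fake_window())
  fm <- cbind(data.frame(subject_id = "S01"), as.data.frame(t(fv)))
  halves <- split_range_sets(fm)
  expect_equal(ncol(halves$high_g), 135L)  # + subject_id
  gyr <- grep("^gyr_", names(halves$high_g), value = TRUE)
  expect_identical(halves$high_g[gyr], halves$low_g[gyr])
})
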