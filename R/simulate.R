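#' Default per-condition ball-velocity distributions
#'
#' Means and standard deviations (m/s) of radar-measured peak ball velocity
#' for each approach x wind-up condition in the emulated cohort.
#'
#' @return data.frame with columns `approach`, `windup`, `mean`, `sd`.
#' @export
velocity_distributions <- function() {
  data.frame(
    approach = rep(c("standing", "running", "jumping"), each = 2),
    windup = rep(c("circle", "whip"), times = 3),
    mean = c(20.7, 20.1, 22.0, 21.2, 21.4, 21.0),
    sd = c(2.6, 2.5, 2.4, 2.4, 2.5, 2.4),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic IMU study
#'
#' The simulator emulates the study conditions the pipeline is built for:
#' 17 subjects, 6 conditions (3 approaches x 2 wind-ups), 7-10 throws per
#' condition, per-condition velocity Normals from
#' [velocity_distributions()], and throw pulses whose gyroscope-y peak is a
#' linear function of throw intensity (`peak_gain_dps` deg/s per m/s, with a
#' multiplicative subject random effect), floored at `peak_floor_dps` so that
#' every generated throw exceeds the 1500 deg/s detection threshold — the
#' pipeline, like the field protocol it mirrors, only ever sees detectable
#' throws. The low-g accelerometer clips at +/-16 g during the throw burst
#' while the high-g channel does not, so high-g features retain the
#' velocity information the low-g channel saturates away.
#'
#' @param n_subjects Number of subjects.
#' @param throws_per_condition Length-2 integer range (inclusive) of throws
#'   per condition per subject.
#' @param velocity_params Per-condition Normal parameters, see
#'   [velocity_distributions()].
#' @param velocity_range_mps Truncation bounds for velocity draws, m/s.
#' @param velocity_noise_sd Sd (m/s) of the noise between the radar-measured
#'   velocity label and the intensity actually driving the signals; sets the
#'   irreducible regression error.
#' @param peak_gain_dps Gyroscope-y peak per unit intensity, deg/s per m/s.
#' @param gyro_throw_jitter_sd Sd of the per-throw multiplicative jitter on
#'   the gyroscope-y peak: wrist angular velocity is an imperfect proxy of
#'   ball speed, while the hand-deceleration burst on the accelerometer
#'   tracks it directly.
#' @param peak_floor_dps Lower floor on the gyroscope-y pulse peak, deg/s
#'   (must exceed the detection threshold).
#' @param acc_gain_g Accelerometer burst peak per unit intensity, g per m/s.
#' @param gyro_pulse_width_s,acc_burst_width_s Nominal durations of the
#'   gyroscope rotation pulse and the accelerometer deceleration burst, s.
#' @param pulse_width_jitter_sd Sd of the per-throw multiplicative jitter on
#'   both pulse widths: movement duration varies between throws, so the time
#'   a clipped channel spends at full scale is a poor velocity proxy while
#'   an unclipped peak amplitude remains a clean one.
#' @param subject_gain_sd Named sd of the multiplicative subject random
#'   effects on gyroscope and accelerometer gains.
#' @param noise_sd Named additive Gaussian noise sd per sensor (deg/s or g).
#' @param clip_low_g Low-g accelerometer full scale, g.
#' @param inter_throw_gap_s Seconds between consecutive throws (must exceed
#'   the largest analysis window).
#' @param lead_s Quiet seconds before the first and after the last throw.
#' @param rates Named nominal sampling rates, Hz.
#' @param timestamp_jitter_frac Timestamp jitter as a fraction of the sample
#'   period (emulates sampling-frequency fluctuation).
#' @param seed Seed; regeneration with the same seed is bit-identical.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 17,
                              throws_per_condition = c(7, 10),
                              velocity_params = velocity_distributions(),
                              velocity_range_mps = c(15, 30),
                              velocity_noise_sd = 0.9,
                              peak_gain_dps = 90,
                              gyro_throw_jitter_sd = 0.03,
                              peak_floor_dps = 1525,
                              acc_gain_g = 2.8,
                              gyro_pulse_width_s = 0.30,
                              acc_burst_width_s = 0.10,
                              pulse_width_jitter_sd = 0.15,
                              subject_gain_sd = c(gyro = 0.03, acc = 0.015),
                              noise_sd = c(gyro = 15, acc_low = 0.05,
                                           acc_high = 0.3),
                              clip_low_g = 16,
                              inter_throw_gap_s = 8,
                              lead_s = 4,
                              rates = c(acc_low = 1125, acc_high = 1600,
                                        gyro = 1125),
                              timestamp_jitter_frac = 0.1,
                              seed = 1) {
  stopifnot(
    n_subjects >= 1,
    length(throws_per_condition) == 2,
    throws_per_condition[1] >= 1,
    throws_per_condition[1] <= throws_per_condition[2],
    all(velocity_params$mean > 0), all(velocity_params$sd > 0),
    velocity_range_mps[1] > 0,
    peak_floor_dps > 1500,
    inter_throw_gap_s > 6,  # largest analysis window
    timestamp_jitter_frac >= 0, timestamp_jitter_frac < 0.5
  )
  structure(
    list(n_subjects = n_subjects,
         throws_per_condition = throws_per_condition,
         velocity_params = velocity_params,
         velocity_range_mps = velocity_range_mps,
         velocity_noise_sd = velocity_noise_sd,
         peak_gain_dps = peak_gain_dps,
         gyro_throw_jitter_sd = gyro_throw_jitter_sd,
         peak_floor_dps = peak_floor_dps,
         acc_gain_g = acc_gain_g,
         gyro_pulse_width_s = gyro_pulse_width_s,
         acc_burst_width_s = acc_burst_width_s,
         pulse_width_jitter_sd = pulse_width_jitter_sd,
         subject_gain_sd = subject_gain_sd,
         noise_sd = noise_sd, clip_low_g = clip_low_g,
         inter_throw_gap_s = inter_throw_gap_s, lead_s = lead_s,
         rates = rates, timestamp_jitter_frac = timestamp_jitter_frac,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Raised-cosine pulse: amp/2 * (1 + cos(2*pi*(t - tc)/w)) inside |t-tc| < w/2.
# Smooth, band-limited, integrable in closed form.
rc_pulse <- function(t, tc, w, amp) {
  out <- numeric(length(t))
  i <- which(abs(t - tc) < w / 2)
  out[i] <- amp * 0.5 * (1 + cos(2 * pi * (t[i] - tc) / w))
  out
}

# Jittered nominal-rate timestamp grid over [0, duration).
jitter_grid <- function(duration, rate, frac) {
  dt <- 1 / rate
  n <- floor(duration * rate)
  (seq_len(n) - 1L) * dt + stats::runif(n, -frac * dt, frac * dt)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Draw the multiplicative subject random effects (consumes RNG).
draw_subject_effects <- function(cfg) {
  list(
    gyro = rnorm_trunc(1, 1, cfg$subject_gain_sd[["gyro"]], 0.9, 1.1),
    acc = rnorm_trunc(1, 1, cfg$subject_gain_sd[["acc"]], 0.95, 1.05)
  )
}

# Build one subject's session from the current RNG state.
sim_session_impl <- function(cfg, subject_id, effects) {
  vp <- cfg$velocity_params
  n_cond <- vapply(seq_len(nrow(vp)), function(i) {
    if (cfg$throws_per_condition[1] == cfg$throws_per_condition[2]) {
      cfg$throws_per_condition[1]
    } else {
      sample(cfg$throws_per_condition[1]:cfg$throws_per_condition[2], 1)
    }
  }, numeric(1))
  truth <- do.call(rbind, lapply(seq_len(nrow(vp)), function(i) {
    data.frame(
      subject_id = subject_id,
      approach = vp$approach[i], windup = vp$windup[i],
      velocity = rnorm_trunc(n_cond[i], vp$mean[i], vp$sd[i],
                             cfg$velocity_range_mps[1],
                             cfg$velocity_range_mps[2]),
      stringsAsFactors = FALSE
    )
  }))
  truth <- truth[sample(nrow(truth)), , drop = FALSE]
  k <- nrow(truth)
  truth$t_event <- cfg$lead_s + (seq_len(k) - 1L) * cfg$inter_throw_gap_s +
    stats::runif(k, -0.3, 0.3)
  truth$intensity <- truth$velocity +
    stats::rnorm(k, 0, cfg$velocity_noise_sd)
  truth$gyro_jitter <- rnorm_trunc(k, 1, cfg$gyro_throw_jitter_sd, 0.9, 1.1)
  truth$width_jitter <- rnorm_trunc(k, 1, cfg$pulse_width_jitter_sd, 0.6, 1.4)
  rownames(truth) <- NULL
  duration <- truth$t_event[k] + cfg$lead_s

  t_g <- jitter_grid(duration, cfg$rates[["gyro"]], cfg$timestamp_jitter_frac)
  t_al <- jitter_grid(duration, cfg$rates[["acc_low"]],
                      cfg$timestamp_jitter_frac)
  t_ah <- jitter_grid(duration, cfg$rates[["acc_high"]],
                      cfg$timestamp_jitter_frac)

  gx <- numeric(length(t_g)); gy <- numeric(length(t_g))
  gz <- numeric(length(t_g))
  # underlying true acceleration (g), gravity baseline on z
  acc_axes <- function(t) {
    list(x = numeric(length(t)), y = numeric(length(t)),
         z = rep(1, length(t)))
  }
  al <- acc_axes(t_al)
  ah <- acc_axes(t_ah)

  add_throw_gyro <- function(te, u, windup, jit, wjit) {
    peak <- max(effects$gyro * jit * cfg$peak_gain_dps * u,
                cfg$peak_floor_dps)
    w <- cfg$gyro_pulse_width_s * wjit
    gy <<- gy + rc_pulse(t_g, te, w, peak)
    gz <<- gz + 0.25 * rc_pulse(t_g, te, w, peak)
    if (windup == "circle") {
      gx <<- gx + rc_pulse(t_g, te - 0.45, 0.60, 450 * effects$gyro)
    } else {
      gx <<- gx + rc_pulse(t_g, te - 0.25, 0.15, 800 * effects$gyro) -
        rc_pulse(t_g, te - 0.12, 0.15, 800 * effects$gyro)
    }
  }
  add_throw_acc <- function(a, t, te, u, approach, wjit) {
    burst <- rc_pulse(t, te, cfg$acc_burst_width_s * wjit,
                      effects$acc * cfg$acc_gain_g * u)
    a$x <- a$x + burst
    a$y <- a$y + 0.3 * burst
    if (approach == "running") {
      win <- t >= te - 1.5 & t <= te - 0.3
      a$z <- a$z + 1.5 * sin(2 * pi * 2.5 * (t - te)) * win
      a$x <- a$x + 0.8 * cos(2 * pi * 2.5 * (t - te)) * win
    } else if (approach == "jumping") {
      flight <- t >= te - 0.9 & t <= te - 0.5
      a$z <- a$z - 1 * flight  # free fall: accelerometer reads ~0 g
      land <- rc_pulse(t, te - 0.45, 0.06, 8)
      a$z <- a$z + land
      a$x <- a$x + 0.3 * land
    }
    a
  }
  for (i in seq_len(k)) {
    add_throw_gyro(truth$t_event[i], truth$intensity[i], truth$windup[i],
                   truth$gyro_jitter[i], truth$width_jitter[i])
    al <- add_throw_acc(al, t_al, truth$t_event[i], truth$intensity[i],
                        truth$approach[i], truth$width_jitter[i])
    ah <- add_throw_acc(ah, t_ah, truth$t_event[i], truth$intensity[i],
                        truth$approach[i], truth$width_jitter[i])
  }
  clip <- function(v, lim) pmin(pmax(v, -lim), lim)
  ns <- cfg$noise_sd
  sensors <- list(
    acc_low = list(
      t = t_al,
      x = clip(al$x, cfg$clip_low_g) + stats::rnorm(length(t_al), 0, ns[["acc_low"]]),
      y = clip(al$y, cfg$clip_low_g) + stats::rnorm(length(t_al), 0, ns[["acc_low"]]),
      z = clip(al$z, cfg$clip_low_g) + stats::rnorm(length(t_al), 0, ns[["acc_low"]])
    ),
    acc_high = list(
      t = t_ah,
      x = ah$x + stats::rnorm(length(t_ah), 0, ns[["acc_high"]]),
      y = ah$y + stats::rnorm(length(t_ah), 0, ns[["acc_high"]]),
      z = ah$z + stats::rnorm(length(t_ah), 0, ns[["acc_high"]])
    ),
    gyro = list(
      t = t_g,
      x = gx + stats::rnorm(length(t_g), 0, ns[["gyro"]]),
      y = gy + stats::rnorm(length(t_g), 0, ns[["gyro"]]),
      z = gz + stats::rnorm(length(t_g), 0, ns[["gyro"]])
    )
  )
  structure(
    list(subject_id = subject_id, sensors = sensors, truth = truth,
         config = cfg, subject_effects = effects),
    class = c("simulated_session", "raw_recording")
  )
}

#' Simulate one subject's multi-rate IMU session
#'
#' Generates a timestamped 9-DoF-style recording (low-g/high-g accelerometer
#' and gyroscope; magnetometer omitted as it carries no features) with
#' ground-truth throw times, condition labels, and radar-style velocity
#' labels. Readable by [to_streams()] without special-casing.
#'
#' @param cfg A [simulation_config()].
#' @param subject_id Subject label.
#' @return A `simulated_session` (also a `raw_recording`): `sensors`,
#'   `truth` (subject_id, approach, windup, velocity, t_event, intensity),
#'   `config`, `subject_effects`.
#' @export
simulate_session <- function(cfg = simulation_config(), subject_id = "S01") {
  set.seed(cfg$seed)
  sim_session_impl(cfg, subject_id, draw_subject_effects(cfg))
}

#' Simulate a full multi-subject study
#'
#' Independent per-subject sessions with subject-level random effects on the
#' signal gains, so leave-one-subject-out evaluation is non-trivial.
#'
#' @param cfg A [simulation_config()].
#' @return List with `sessions` (one `simulated_session` per subject) and
#'   `truth` (pooled ground-truth table).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  sessions <- lapply(ids, function(id) {
    sim_session_impl(cfg, id, draw_subject_effects(cfg))
  })
  names(sessions) <- ids
  truth <- do.call(rbind, lapply(sessions, function(s) s$truth))
  rownames(truth) <- NULL
  list(sessions = sessions, truth = truth)
}
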