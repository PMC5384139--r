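#' Simulation parameters for a synthetic TUG trial
#'
#' Bundle of kinematic and degradation parameters driving
#' [simulate_tug()]. Defaults describe a healthy older adult; use
#' [pd_profile()] for a Parkinsonian preset.
#'
#' @param distance Walkway length, m (5 or 10 in the standard protocol).
#' @param gait_speed Walking speed, m/s.
#' @param cadence Steps per second; gait oscillations are synthesized at the
#'   stride frequency `cadence / 2`.
#' @param stand_duration,sit_duration,turn_duration Postural transition and
#'   180-degree turn durations, s.
#' @param tremor_amplitude Amplitude (m/s^2) of a 5 Hz tremor band injected
#'   on distal acceleration channels.
#' @param shuffle_factor Multiplier in (0, 1] on the sacrum angular-velocity
#'   gait amplitude; small values emulate shuffling gait.
#' @param confounders Character subset of
#'   `c("pre_stand_sway", "pre_sit_bend", "seated_leg_motion")`.
#' @param noise_acc,noise_gyr Per-channel Gaussian noise std (m/s^2, rad/s).
#' @param noise_quat_deg Orientation jitter std in degrees.
#' @param seed Integer seed making the trial fully deterministic.
#' @return Object of class `sim_params` (a named list).
#' @export
sim_params <- function(distance = 5,
                       gait_speed = 1.4,
                       cadence = 2.0,
                       stand_duration = 1.3,
                       sit_duration = 1.5,
                       turn_duration = 1.2,
                       tremor_amplitude = 0,
                       shuffle_factor = 1,
                       confounders = character(0),
                       noise_acc = 0.2,
                       noise_gyr = 0.05,
                       noise_quat_deg = 0.05,
                       seed = 1L) {
  p <- list(distance = distance, gait_speed = gait_speed, cadence = cadence,
            stand_duration = stand_duration, sit_duration = sit_duration,
            turn_duration = turn_duration,
            tremor_amplitude = tremor_amplitude,
            shuffle_factor = shuffle_factor,
            confounders = confounders,
            noise_acc = noise_acc, noise_gyr = noise_gyr,
            noise_quat_deg = noise_quat_deg, seed = as.integer(seed))
  stopifnot(p$distance > 0, p$gait_speed > 0, p$cadence > 0,
            p$stand_duration > 0, p$sit_duration > 0, p$turn_duration > 0,
            p$shuffle_factor > 0, p$shuffle_factor <= 1,
            all(p$confounders %in% c("pre_stand_sway", "pre_sit_bend",
                                     "seated_leg_motion")))
  class(p) <- "sim_params"
  p
}

# fixed generator constants (amplitudes in m/s^2 and rad/s; see the methods
# vignette for the calibration rationale)
SIM_CONST <- list(
  fs = 60,
  pre_roll = 3.5, post_roll = 2.0,
  gap_stand_walk = 0.1, gap_turn_sit = 0.1,
  theta_seated = 88, theta_upright = 4,
  trunk_stand_amp = 2.0, trunk_sit_amp = 2.2, trunk_walk_amp = 0.2,
  sway_amp = 1.4, sway_dur = 1.4, sway_lead = 2.2,
  bend_amp = 1.5, bend_dur = 1.2, bend_lead = 3.2,
  thigh_walk_amp = 0.3,
  shin_gait_amp = 3.0,
  sacrum_gait_amp = 0.5, trunk_gait_wy_amp = 0.15,
  leg_motion_amp = 3.0, leg_motion_lead = 3.0, leg_motion_dur = 2.2,
  tremor_hz = 5, ramp = 0.3, gravity = 9.81
)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# raised-cosine windowed pulse: amp * sin(pi u)^2 on [center - dur/2, center + dur/2]
pulse_wave <- function(t, center, dur, amp) {
  u <- (t - (center - dur / 2)) / dur
  w <- numeric(length(t))
  in_win <- u >= 0 & u <= 1
  w[in_win] <- amp * sin(pi * u[in_win])^2
  w
}

# sinusoid at freq f gated to [t0, t1] with raised-cosine on/off ramps
gated_sine <- function(t, t0, t1, f, amp, ramp = SIM_CONST$ramp, phase = 0) {
  env <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  env[inside] <- 1
  up <- t >= t0 & t < t0 + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  down <- t > t1 - ramp & t <= t1
  env[down] <- 0.5 * (1 - cos(pi * (t1 - t[down]) / ramp))
  amp * env * sin(2 * pi * f * (t - t0) + phase)
}

logistic_fall <- function(t, t_start, dur, hi, lo) {
  # hi -> lo over [t_start, t_start + dur]; 10/dur slope constant puts
  # >99% of the drop inside the interval
  k <- 10 / dur
  lo + (hi - lo) / (1 + exp(k * (t - (t_start + dur / 2))))
}

quat_yaw_flexion <- function(psi, theta_deg) {
  # world-z yaw followed by flexion about the rotated x-axis
  half_psi <- psi / 2
  qz <- cbind(cos(half_psi), 0, 0, sin(half_psi))
  th <- theta_deg * pi / 360  # half angle in rad
  qx <- cbind(cos(th), sin(th), 0, 0)
  quat_multiply(qz, qx)
}

jitter_quat <- function(q, sd_deg) {
  n <- nrow(q)
  ang <- stats::rnorm(n, 0, sd_deg * pi / 180)
  ax <- matrix(stats::rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  dq <- cbind(cos(ang / 2), sin(ang / 2) * ax)
  quat_normalize(quat_multiply(q, dq))
}

smooth_noise <- function(n, sd) {
  # AR(1)-correlated low-amplitude wander for sites the detectors ignore
  e <- stats::rnorm(n, 0, sd)
  as.numeric(stats::filter(e, 0.95, method = "recursive")) * sqrt(1 - 0.95^2)
}

#' Simulate one TUG trial with exact ground truth
#'
#' Generates a full 17-site IMU recording of a scripted TUG: seated rest,
#' stand up, walk out, 180-degree turn, walk in, turn, brief stance, sit
#' down, seated rest. The signal model reproduces the kinematic signatures
#' the detectors key on:
#' \itemize{
#'   \item hip angle: seated plateau near 88 degrees, logistic drop to ~4
#'     degrees over `stand_duration`, logistic rise back over
#'     `sit_duration`, realized as consistent sacrum/thigh quaternions
#'     (yaw during turns applied to both, so the hip angle is unaffected);
#'   \item trunk a_z: raised-cosine pulses during both postural transitions;
#'   \item thigh a_y: gravity-component level shift `9.81 * cos(theta)`
#'     (positive time derivative while standing up, negative sitting down);
#'   \item shin a_y and sacrum/trunk omega_y: gait oscillations at the
#'     stride frequency during walk phases, the sacrum amplitude scaled by
#'     `shuffle_factor`;
#'   \item trunk/sacrum omega_y: half-sine yaw-rate pulses integrating to
#'     180 degrees during each turn.
#' }
#' Optional Parkinsonian confounders: a trunk sway pulse ~2 s before
#' standing up (`pre_stand_sway`), a forward-bend trunk pulse during the
#' approach to the chair (`pre_sit_bend`), and a seated shin oscillation
#' (`seated_leg_motion`). A 5 Hz tremor band rides on distal acceleration
#' channels when `tremor_amplitude > 0`. All channels carry Gaussian noise;
#' undetected sites carry correlated low-amplitude wander so the full
#' 17-site layout is exercised.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `recording` (a `tug_recording`), `truth` (a
#'   `tug_annotation` holding the six activity intervals and seven
#'   transition times, rater `"truth"`), `theta` (the programmed hip-angle
#'   trajectory, degrees) and `params`.
#' @export
simulate_tug <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  K <- SIM_CONST
  fs <- K$fs
  p <- params

  walk_dur <- p$distance / p$gait_speed
  t_sts <- K$pre_roll                                  # sit-to-stand
  t_w1s <- t_sts + p$stand_duration + K$gap_stand_walk # stand-to-walk out
  t_t1s <- t_w1s + walk_dur                            # walk out-to-turn
  t_t1e <- t_t1s + p$turn_duration                     # turn-to-walk in
  t_t2s <- t_t1e + walk_dur                            # walk in-to-turn
  t_t2e <- t_t2s + p$turn_duration                     # turn-to-stand
  t_s2s <- t_t2e + K$gap_turn_sit                      # stand-to-sit
  t_end <- t_s2s + p$sit_duration
  n <- as.integer(ceiling((t_end + K$post_roll) * fs)) + 1L
  t <- (seq_len(n) - 1) / fs

  # programmed hip-angle trajectory
  theta <- rep(K$theta_seated, n)
  theta <- ifelse(t < t_sts, K$theta_seated,
                  logistic_fall(t, t_sts, p$stand_duration,
                                K$theta_seated, K$theta_upright))
  rise <- t >= t_s2s - 1e-9
  theta[rise] <- K$theta_seated -
    (logistic_fall(t[rise], t_s2s, p$sit_duration,
                   K$theta_seated, K$theta_upright) - K$theta_upright)

  # yaw: two half-sine-rate turns of 180 degrees each, same direction
  yaw_ramp <- function(tt, t0, dur) {
    u <- pmin(pmax((tt - t0) / dur, 0), 1)
    pi * (1 - cos(pi * u)) / 2
  }
  psi <- yaw_ramp(t, t_t1s, p$turn_duration) + yaw_ramp(t, t_t2s, p$turn_duration)
  turn_rate_amp <- pi^2 / (2 * p$turn_duration)
  turn_rate <- turn_rate_amp *
    (pulse_half_sine(t, t_t1s, p$turn_duration) +
       pulse_half_sine(t, t_t2s, p$turn_duration))

  f_stride <- p$cadence / 2
  out <- with_seed(p$seed, {
    ph <- stats::runif(6, 0, 2 * pi)

    trunk_az <- pulse_wave(t, t_sts + p$stand_duration / 2, p$stand_duration, K$trunk_stand_amp) +
      pulse_wave(t, t_s2s + p$sit_duration / 2, p$sit_duration, K$trunk_sit_amp) +
      gated_sine(t, t_w1s, t_t1s, p$cadence, K$trunk_walk_amp, phase = ph[1]) +
      gated_sine(t, t_t1e, t_t2s, p$cadence, K$trunk_walk_amp, phase = ph[2])
    if ("pre_stand_sway" %in% p$confounders)
      trunk_az <- trunk_az + pulse_wave(t, t_sts - K$sway_lead, K$sway_dur, K$sway_amp)
    if ("pre_sit_bend" %in% p$confounders)
      trunk_az <- trunk_az + pulse_wave(t, t_s2s - K$bend_lead, K$bend_dur, K$bend_amp)

    thigh_ay <- K$gravity * cos(theta * pi / 180) +
      gated_sine(t, t_w1s, t_t1s, f_stride, K$thigh_walk_amp, phase = ph[3]) +
      gated_sine(t, t_t1e, t_t2s, f_stride, K$thigh_walk_amp, phase = ph[3])

    shin_ay <- K$gravity +
      gated_sine(t, t_w1s, t_t1s, f_stride, K$shin_gait_amp, phase = ph[4]) +
      gated_sine(t, t_t1e, t_t2s, f_stride, K$shin_gait_amp, phase = ph[4])
    if ("seated_leg_motion" %in% p$confounders)
      shin_ay <- shin_ay +
        gated_sine(t, t_sts - K$leg_motion_lead,
                   t_sts - K$leg_motion_lead + K$leg_motion_dur,
                   f_stride, K$leg_motion_amp, phase = ph[5])

    gait_wy <- function(amp, phase)
      gated_sine(t, t_w1s, t_t1s, f_stride, amp, phase = phase) +
      gated_sine(t, t_t1e, t_t2s, f_stride, amp, phase = phase)
    sacrum_wy <- turn_rate + gait_wy(K$sacrum_gait_amp * p$shuffle_factor, ph[6])
    trunk_wy <- turn_rate + gait_wy(K$trunk_gait_wy_amp, ph[6])

    tremor <- function() {
      if (p$tremor_amplitude <= 0) return(numeric(n))
      p$tremor_amplitude * sin(2 * pi * K$tremor_hz * t + stats::runif(1, 0, 2 * pi))
    }

    mk_site <- function(acc_means, gyr_means, quat = NULL, tremor_on = FALSE) {
      acc <- sapply(acc_means, function(m) m + stats::rnorm(n, 0, p$noise_acc))
      if (tremor_on) acc[, 2] <- acc[, 2] + tremor()
      gyr <- sapply(gyr_means, function(m) m + stats::rnorm(n, 0, p$noise_gyr))
      if (is.null(quat)) quat <- cbind(rep(1, n), 0, 0, 0)
      list(acc = acc, gyr = gyr, quat = jitter_quat(quat, p$noise_quat_deg))
    }
    zero <- numeric(n)
    wander <- function() smooth_noise(n, 0.15)

    q_sacrum <- quat_yaw_flexion(psi, rep(0, n))
    q_thigh <- quat_yaw_flexion(psi, theta)

    sites <- list(
      trunk = mk_site(list(wander(), K$gravity + wander(), trunk_az),
                      list(zero, trunk_wy, zero),
                      quat = quat_yaw_flexion(psi, rep(0, n))),
      sacrum = mk_site(list(wander(), K$gravity + wander(), wander()),
                       list(zero, sacrum_wy, zero), quat = q_sacrum),
      r_thigh = mk_site(list(wander(), thigh_ay, wander()),
                        list(zero, zero, zero), quat = q_thigh),
      l_thigh = mk_site(list(wander(), 0.97 * thigh_ay, wander()),
                        list(zero, zero, zero), quat = q_thigh),
      r_shin = mk_site(list(wander(), shin_ay, wander()),
                       list(zero, zero, zero), tremor_on = TRUE),
      l_shin = mk_site(list(wander(), K$gravity + 0.97 * (shin_ay - K$gravity), wander()),
                       list(zero, zero, zero), tremor_on = TRUE)
    )
    for (s in setdiff(TUG_SITES, names(sites))) {
      trem <- s %in% c("l_forearm", "r_forearm", "l_hand", "r_hand")
      sites[[s]] <- mk_site(list(wander(), K$gravity + wander(), wander()),
                            list(zero, zero, zero), tremor_on = trem)
    }
    sites
  })

  rec <- tug_recording(out, sample_rate = fs,
                       trial_id = sprintf("sim_%dm_seed%d", round(p$distance), p$seed))
  truth <- tug_annotation(
    events = data.frame(
      label = c("STAND_UP", "WALK", "TURN", "WALK", "TURN", "SIT_DOWN"),
      start = c(t_sts, t_w1s, t_t1s, t_t1e, t_t2s, t_s2s),
      end = c(t_sts + p$stand_duration, t_t1s, t_t1e, t_t2s, t_t2e, t_end)
    ),
    transitions = data.frame(
      label = TUG_TRANSITIONS,
      time = c(t_sts, t_w1s, t_t1s, t_t1e, t_t2s, t_t2e, t_s2s),
      rater = "truth"
    )
  )
  # WALK truth intervals: fix ends (constructed above with placeholder)
  truth$events$end[2] <- t_t1s
  truth$events$end[4] <- t_t2s
  list(recording = rec, truth = truth, theta = theta, params = p)
}

pulse_half_sine <- function(t, t0, dur) {
  u <- (t - t0) / dur
  w <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  w[inside] <- sin(pi * u[inside])
  w
}

#' Parkinsonian parameter preset
#'
#' Interpolates simulation parameters between a healthy preset
#' (severity 0: gait 1.4 m/s, no tremor, full sacrum gait amplitude, no
#' confounders) and an early-Parkinson preset (severity 1: slower gait,
#' `shuffle_factor` 0.3, 5 Hz tremor, all confounders enabled). Stand and
#' sit durations are drawn around means that reach 1.82 s and 2.10 s at
#' severity 1, with spreads of 160 and 180 ms.
#'
#' @param severity Number in [0, 1].
#' @param distance Walkway length, m.
#' @param seed Integer seed; controls both the parameter draws and the
#'   trial seed of the returned `sim_params`.
#' @return A [sim_params()] object.
#' @export
pd_profile <- function(severity = 1, distance = 5, seed = 1L) {
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    stop("severity must be in [0, 1]")
  s <- severity
  lerp <- function(a, b) a + s * (b - a)
  with_seed(seed, {
    stand <- max(0.8, stats::rnorm(1, lerp(1.3, 1.82), lerp(0.12, 0.16)))
    sit <- max(0.9, stats::rnorm(1, lerp(1.5, 2.10), lerp(0.12, 0.18)))
    gait <- max(0.6, stats::rnorm(1, lerp(1.40, 1.21), 0.06))
    cad <- max(1.2, stats::rnorm(1, lerp(2.0, 1.8), 0.10))
    turn <- max(0.8, stats::rnorm(1, lerp(1.2, 1.8), 0.08))
    sim_params(
      distance = distance, gait_speed = gait, cadence = cad,
      stand_duration = stand, sit_duration = sit, turn_duration = turn,
      tremor_amplitude = lerp(0, 0.5),
      shuffle_factor = lerp(1, 0.3),
      confounders = if (s >= 0.5)
        c("pre_stand_sway", "pre_sit_bend", "seated_leg_motion")
      else character(0),
      seed = seed
    )
  })
}

#' Simulate a cohort of TUG trials
#'
#' `n_subjects` subjects each perform `trials_per_task` trials of both task
#' lengths (5 m and 10 m). Subject-level kinematic parameters are drawn
#' once per subject (via [pd_profile()]) and reused across that subject's
#' trials; per-trial noise differs through trial seeds. Fully deterministic
#' given `seed`.
#'
#' @param n_subjects,trials_per_task Counts (>= 1).
#' @param seed Integer master seed.
#' @param severity Parkinson severity passed to [pd_profile()].
#' @return List of trials; each element is the [simulate_tug()] result
#'   augmented with `subject`, `task` (m) and `trial` indices.
#' @export
make_cohort <- function(n_subjects, trials_per_task, seed = 1L, severity = 1) {
  stopifnot(n_subjects >= 1, trials_per_task >= 1)
  seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, n_subjects * (1 + 2 * trials_per_task)),
    nrow = n_subjects))
  out <- list()
  for (i in seq_len(n_subjects)) {
    base <- pd_profile(severity, seed = seeds[i, 1])
    k <- 2L
    for (task in c(5, 10)) {
      for (tr in seq_len(trials_per_task)) {
        p <- base
        p$distance <- task
        p$seed <- seeds[i, k]; k <- k + 1L
        sim <- simulate_tug(p)
        sim$subject <- i; sim$task <- task; sim$trial <- tr
        out[[length(out) + 1L]] <- sim
      }
    }
  }
  out
}
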