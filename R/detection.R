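activity_event <- function(label, peak_time, evidence = list(),
                           start = NA_real_, end = NA_real_) {
  list(label = label, peak_time = peak_time, evidence = evidence,
       start = start, end = end)
}

events_df <- function(events) {
  if (length(events) == 0)
    return(data.frame(label = character(0), peak_time = numeric(0),
                      start = numeric(0), end = numeric(0)))
  data.frame(label = vapply(events, `[[`, "", "label"),
             peak_time = vapply(events, `[[`, 0, "peak_time"),
             start = vapply(events, `[[`, 0, "start"),
             end = vapply(events, `[[`, 0, "end"))
}

conditioned <- function(x, fs, f_low, f_high) {
  bandpass_filter(normalize_series(detrend_series(x)), fs, f_low, f_high)
}

theta_or_null <- function(rec, cfg) {
  qs <- rec$sites[[cfg$sacrum_site]]$quat
  qt <- rec$sites[[cfg$thigh_site]]$quat
  if (is.null(qs) || is.null(qt)) return(NULL)
  hip_angle(qs, qt)
}

# hip-angle crossing gate for one stand/sit candidate peak
hip_gate <- function(label, theta, fs, peak_time, cfg) {
  n <- length(theta)
  i <- round(peak_time * fs) + 1L
  w <- as.integer(round(cfg$gate_window * fs))
  before <- theta[max(1L, i - w):min(n, i)]
  after <- theta[max(1L, i):min(n, i + w)]
  if (label == "STAND_UP")
    max(before) >= cfg$seated_deg && min(after) <= cfg$upright_deg
  else
    min(before) <= cfg$upright_deg && max(after) >= cfg$seated_deg
}

#' Detect standing-up and sitting-down events
#'
#' Peaks of the conditioned (detrended, normalized, band-passed) trunk a_z
#' mark postural transitions; the sign of the time derivative of the
#' conditioned thigh a_y at the peak sample separates standing up
#' (derivative > 0: the thigh rotates under gravity toward vertical) from
#' sitting down (derivative < 0). The detection band-pass high cutoff is
#' 1.58 Hz in the original variant and 0.9 Hz in the modified variant.
#'
#' In the modified variant each candidate must additionally be confirmed by
#' a hip-angle crossing within `gate_window` of the peak: standing up
#' requires the hip angle to pass from above the seated threshold to below
#' the upright threshold (the reverse for sitting down). This gate rejects
#' trunk-sway and forward-bend movements that mimic the trunk a_z pulse.
#'
#' @param rec A `tug_recording` (must contain trunk and thigh sites; the
#'   modified variant also needs sacrum and thigh quaternions).
#' @param cfg A [tug_config()].
#' @return List of activity events (label, peak_time, evidence), time
#'   ordered.
#' @export
detect_stand_sit <- function(rec, cfg = tug_config()) {
  fs <- rec$sample_rate
  fc <- standsit_cutoff(cfg)
  az <- conditioned(rec_channel(rec, cfg$trunk_site, "az"), fs, cfg$low_cutoff, fc)
  ay <- conditioned(rec_channel(rec, cfg$thigh_site, "ay"), fs, cfg$low_cutoff, fc)
  day <- series_derivative(ay, fs)
  pk <- find_peaks(az, fs, height = cfg$peak_height,
                   min_separation = cfg$peak_min_sep)
  theta <- if (cfg$variant == "modified") {
    th <- theta_or_null(rec, cfg)
    if (is.null(th)) stop("modified variant requires sacrum and thigh quaternions")
    th
  } else NULL
  ev <- list()
  for (k in seq_len(nrow(pk))) {
    i <- round(pk$time[k] * fs) + 1L
    lab <- if (day[i] > 0) "STAND_UP" else "SIT_DOWN"
    if (!is.null(theta) && !hip_gate(lab, theta, fs, pk$time[k], cfg)) next
    ev[[length(ev) + 1L]] <- activity_event(
      lab, pk$time[k],
      evidence = list(trunk_az = pk$value[k], thigh_day = day[i]))
  }
  ev[order(vapply(ev, `[[`, 0, "peak_time"))]
}

#' Detect turning events
#'
#' Peaks of the absolute conditioned trunk omega_y above the normalized
#' peak threshold, direction-agnostic. Identical in both variants.
#'
#' @inheritParams detect_stand_sit
#' @return List of TURN activity events.
#' @export
detect_turns <- function(rec, cfg = tug_config()) {
  fs <- rec$sample_rate
  wy <- conditioned(rec_channel(rec, cfg$trunk_site, "wy"), fs,
                    cfg$low_cutoff, cfg$turn_cutoff)
  pk <- find_peaks(abs(wy), fs, height = cfg$peak_height,
                   min_separation = cfg$peak_min_sep)
  lapply(seq_len(nrow(pk)), function(k)
    activity_event("TURN", pk$time[k],
                   evidence = list(trunk_wy = pk$value[k])))
}

# gait envelope: moving RMS cascaded with two short moving-average passes.
# The Eq.-style adaptive threshold lies within about one histogram bin of the
# envelope maximum, so stride-rate rectification ripple must be far smaller
# than a bin width or bouts fragment; the double average suppresses it by
# ~two orders of magnitude across the 1.6-2 Hz step-frequency range.
gait_envelope <- function(x, fs, cfg) {
  env <- moving_rms(x, fs, cfg$env_window)
  moving_avg(moving_avg(env, fs, 0.5), fs, 0.5)
}

# envelope-threshold bout extraction shared by both walking variants.
# Hysteresis (Schmitt-trigger) thresholding: a bout must rise above the
# detection threshold at least once, but is sustained down to
# hysteresis * thr, so amplitude fluctuations of a few percent around the
# near-maximum adaptive threshold do not fragment a genuine bout.
# exclude: list of c(start, end) spans removed from bouts (turn claims)
walk_bouts <- function(env, fs, thr, upright_mask, cfg, exclude = list()) {
  excise <- function(m) {
    for (sp in exclude) {
      i0 <- max(1L, round(sp[1] * fs) + 1L)
      i1 <- min(length(m), round(sp[2] * fs) + 1L)
      if (i1 >= i0) m[i0:i1] <- FALSE
    }
    m
  }
  high <- env >= thr
  mask <- env >= cfg$hysteresis * thr
  if (!is.null(upright_mask)) {
    high <- high & upright_mask
    mask <- mask & upright_mask
  }
  high <- excise(high)
  mask <- excise(mask)
  runs <- function(m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    data.frame(start = ends - r$lengths + 1L, end = ends)[r$values, ,
                                                          drop = FALSE]
  }
  # bridge short FALSE gaps between TRUE runs, then re-excise
  gap_max <- cfg$gap_close * fs
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) && r$lengths[k] <= gap_max)
      mask[starts[k]:ends[k]] <- TRUE
  }
  mask <- excise(mask)
  rr <- runs(mask)
  keep <- which(rr$end - rr$start + 1L >= cfg$min_bout * fs &
                  vapply(seq_len(nrow(rr)), function(k)
                    any(high[rr$start[k]:rr$end[k]]), TRUE))
  lapply(keep, function(k) {
    seg <- rr$start[k]:rr$end[k]
    imax <- seg[which.max(env[seg])]
    activity_event("WALK", (imax - 1) / fs,
                   evidence = list(envelope = env[imax], threshold = thr),
                   start = (rr$start[k] - 1) / fs, end = (rr$end[k] - 1) / fs)
  })
}

#' Detect walking bouts
#'
#' Original variant: the moving-RMS envelope of the normalized, band-passed
#' sacrum omega_y must exceed a fixed normalized threshold. Modified
#' variant: the envelope of the band-passed shin a_y must exceed the
#' histogram [adaptive_threshold()] *and* the subject must be upright
#' (hip angle at or below the upright threshold) throughout; this
#' combination is robust to shuffling gait (which attenuates the sacrum
#' signal) and rejects seated leg movement. Envelope gaps shorter than
#' `gap_close` are bridged; bouts shorter than `min_bout` are dropped; each
#' bout is emitted as one WALK event at its envelope maximum.
#'
#' @inheritParams detect_stand_sit
#' @param exclude List of `c(start, end)` spans (s) excised from bouts
#'   (used by [detect_activities()] to hand turn spans to the walk
#'   detector).
#' @return List of WALK activity events with bout start/end times.
#' @export
detect_walking <- function(rec, cfg = tug_config(), exclude = list()) {
  fs <- rec$sample_rate
  if (cfg$variant == "modified") {
    x <- bandpass_filter(detrend_series(rec_channel(rec, cfg$shin_site, "ay")),
                         fs, cfg$walk_band[1], cfg$walk_band[2])
    env <- gait_envelope(x, fs, cfg)
    theta <- theta_or_null(rec, cfg)
    if (is.null(theta)) stop("modified variant requires sacrum and thigh quaternions")
    upright <- is_upright(pmin(pmax(theta, 0), 180), cfg$upright_deg)
    # the amplitude histogram is built from upright samples only, so that
    # seated leg movement cannot inflate bin_max above the gait plateau
    cand <- env[upright]
    if (length(cand) < cfg$n_bins || diff(range(cand)) <= 0) return(list())
    thr <- adaptive_threshold(cand, cfg$n_bins, cfg$alpha, cfg$threshold_strategy)
    walk_bouts(env, fs, thr, upright, cfg, exclude)
  } else {
    x <- bandpass_filter(normalize_series(detrend_series(
      rec_channel(rec, cfg$sacrum_site, "wy"))),
      fs, cfg$walk_band[1], cfg$walk_band[2])
    env <- gait_envelope(x, fs, cfg)
    walk_bouts(env, fs, cfg$walk_threshold_norm, NULL, cfg, exclude)
  }
}

#' Detect all TUG activities
#'
#' Union of the stand/sit, turn and walking detectors, time sorted.
#' Overlaps between walking and turning are resolved in favour of turning:
#' each turn claims the span `peak_time +/- turn_halfwidth` and walking
#' bouts are truncated at (split around) turn spans before the minimum-bout
#' rule is applied.
#'
#' @inheritParams detect_stand_sit
#' @return List of activity events sorted by peak time. Use
#'   [events_to_frame()] for a data-frame view.
#' @export
detect_activities <- function(rec, cfg = tug_config()) {
  ss <- detect_stand_sit(rec, cfg)
  tu <- detect_turns(rec, cfg)
  spans <- lapply(tu, function(e)
    c(e$peak_time - cfg$turn_halfwidth, e$peak_time + cfg$turn_halfwidth))
  wa <- detect_walking(rec, cfg, exclude = spans)
  ev <- c(ss, tu, wa)
  ev[order(vapply(ev, `[[`, 0, "peak_time"))]
}

#' Activity events as a data frame
#'
#' @param events List of activity events from the detectors.
#' @return `data.frame` with columns `label`, `peak_time`, `start`, `end`.
#' @export
events_to_frame <- function(events) events_df(events)
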