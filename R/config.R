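#' Transition taxonomy of a TUG trial
#'
#' The canonical seven transitions between the six activity instances of a
#' Timed Up and Go trial (stand up, walk out, turn, walk in, turn, sit
#' down), in order.
#' @export
TUG_TRANSITIONS <- c("SIT_TO_STAND", "STAND_TO_WALK_OUT", "WALK_OUT_TO_TURN",
                     "TURN_TO_WALK_IN", "WALK_IN_TO_TURN", "TURN_TO_STAND",
                     "STAND_TO_SIT")

#' Activity labels
#' @export
TUG_ACTIVITIES <- c("STAND_UP", "SIT_DOWN", "TURN", "WALK")

#' The 17-site IMU layout
#'
#' Sensor-site names of the full-body suit: head, trunk, sacrum and
#' left/right shoulder, upper arm, forearm, hand, thigh, shin, foot.
#' @export
TUG_SITES <- c("head", "trunk", "sacrum",
               paste0(rep(c("l_", "r_"), each = 7),
                      rep(c("shoulder", "upper_arm", "forearm", "hand",
                            "thigh", "shin", "foot"), 2)))

TUG_CHANNELS <- c("ax", "ay", "az", "wx", "wy", "wz")

# Per-transition segmentation channels with original and optimized high
# cutoffs (Hz). "hip/theta" is the hip-angle series treated as a channel.
# Transitions without a re-optimized value keep the original cutoff.
transition_channel_table <- function() {
  ch <- function(site, channel, org, opt = org)
    list(site = site, channel = channel, org = org, opt = opt)
  list(
    SIT_TO_STAND      = list(ch("trunk", "az", 1.57), ch("hip", "theta", 0.69)),
    STAND_TO_WALK_OUT = list(ch("trunk", "az", 2.44)),
    WALK_OUT_TO_TURN  = list(ch("trunk", "wy", 1.32), ch("sacrum", "wy", 0.98)),
    TURN_TO_WALK_IN   = list(ch("sacrum", "wy", 0.53, 3.0)),
    WALK_IN_TO_TURN   = list(ch("trunk", "wy", 1.00, 3.0), ch("sacrum", "wy", 0.59, 3.0)),
    TURN_TO_STAND     = list(ch("trunk", "wy", 0.81, 2.0), ch("sacrum", "wy", 1.00, 2.5)),
    STAND_TO_SIT      = list(ch("trunk", "az", 1.02))
  )
}

#' Detector configuration
#'
#' All tunable parameters of the detection and segmentation pipeline, with
#' defaults matching the published sensor/algorithm selection. Two switches
#' select behaviour families:
#' \describe{
#'   \item{`variant`}{`"original"` (healthy-adult detector set: trunk/thigh
#'     accelerations for postural transitions, sacrum angular velocity with a
#'     fixed normalized threshold for walking) or `"modified"`
#'     (Parkinson-adapted: hip-angle gating, shin acceleration with the
#'     histogram adaptive threshold, stand/sit detection cutoff lowered from
#'     1.58 to 0.9 Hz).}
#'   \item{`cutoffs`}{`"original"` or `"optimized"` per-transition band-pass
#'     high cutoffs for segmentation (the optimized set raises the cutoffs of
#'     the dynamic turn-related transitions into the 2-3 Hz range).}
#' }
#'
#' @param variant Detection variant, `"original"` or `"modified"`.
#' @param cutoffs Segmentation cutoff set, `"original"` or `"optimized"`.
#' @param sample_rate Expected sampling rate, Hz.
#' @param low_cutoff Band-pass low cutoff, Hz.
#' @param n_bins Histogram bins of the adaptive threshold.
#' @param alpha Adaptive-threshold relaxation factor.
#' @param threshold_strategy Bin-statistic interpretation for
#'   [adaptive_threshold()]: `"centers"` or `"edges"`.
#' @param upright_deg,seated_deg Hip-angle gate thresholds, degrees.
#' @param peak_height Peak threshold on normalized signals.
#' @param peak_min_sep Minimum peak separation, s.
#' @param gate_window Hip-angle crossing search window around a peak, s.
#' @param standsit_cutoff_original,standsit_cutoff_modified Detection
#'   band-pass high cutoff for stand/sit peaks, Hz, per variant.
#' @param turn_cutoff Detection band-pass high cutoff for turn peaks, Hz.
#' @param walk_band Length-2 band (Hz) for gait-oscillation filtering.
#' @param walk_threshold_norm Fixed normalized envelope threshold of the
#'   original walking detector.
#' @param env_window Moving-RMS envelope window, s.
#' @param min_bout Minimum walking-bout duration, s.
#' @param gap_close Maximum envelope gap bridged inside a bout, s.
#' @param hysteresis Sustain fraction of the bout threshold: a bout must
#'   exceed the full threshold at least once but persists while the
#'   envelope stays above `hysteresis * threshold`.
#' @param turn_halfwidth Half-span of a turn around its peak used to
#'   truncate walking bouts, s.
#' @param search_window Extremum search window per side in segmentation, s.
#' @param persistence Samples of one-sided persistence required of a local
#'   extremum in segmentation.
#' @param match_window Event-matching tolerance for evaluation, s.
#' @param sacrum_site,thigh_site,shin_site,trunk_site Site names used by the
#'   detectors.
#' @return An object of class `tug_config` (a named list).
#' @export
tug_config <- function(variant = c("modified", "original"),
                       cutoffs = c("original", "optimized"),
                       sample_rate = 60,
                       low_cutoff = 0.1,
                       n_bins = 20L,
                       alpha = 0.01,
                       threshold_strategy = "centers",
                       upright_deg = 30,
                       seated_deg = 60,
                       peak_height = 0.4,
                       peak_min_sep = 1.5,
                       gate_window = 2.5,
                       standsit_cutoff_original = 1.58,
                       standsit_cutoff_modified = 0.9,
                       turn_cutoff = 1.0,
                       walk_band = c(0.3, 3.0),
                       walk_threshold_norm = 0.08,
                       env_window = 0.75,
                       min_bout = 1.5,
                       gap_close = 0.5,
                       hysteresis = 0.8,
                       turn_halfwidth = 1.1,
                       search_window = 4,
                       persistence = 3L,
                       match_window = 1.0,
                       trunk_site = "trunk",
                       sacrum_site = "sacrum",
                       thigh_site = "r_thigh",
                       shin_site = "r_shin") {
  variant <- match.arg(variant)
  cutoffs <- match.arg(cutoffs)
  cfg <- list(
    variant = variant, cutoffs = cutoffs, sample_rate = sample_rate,
    low_cutoff = low_cutoff, n_bins = as.integer(n_bins), alpha = alpha,
    threshold_strategy = threshold_strategy,
    upright_deg = upright_deg, seated_deg = seated_deg,
    peak_height = peak_height, peak_min_sep = peak_min_sep,
    gate_window = gate_window,
    standsit_cutoff_original = standsit_cutoff_original,
    standsit_cutoff_modified = standsit_cutoff_modified,
    turn_cutoff = turn_cutoff, walk_band = walk_band,
    walk_threshold_norm = walk_threshold_norm, env_window = env_window,
    min_bout = min_bout, gap_close = gap_close, hysteresis = hysteresis,
    turn_halfwidth = turn_halfwidth,
    search_window = search_window, persistence = as.integer(persistence),
    match_window = match_window,
    trunk_site = trunk_site, sacrum_site = sacrum_site,
    thigh_site = thigh_site, shin_site = shin_site,
    transition_channels = transition_channel_table()
  )
  class(cfg) <- "tug_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ny <- cfg$sample_rate / 2
  cuts <- c(cfg$standsit_cutoff_original, cfg$standsit_cutoff_modified,
            cfg$turn_cutoff, cfg$walk_band[2],
            unlist(lapply(cfg$transition_channels,
                          function(tr) lapply(tr, function(ch) c(ch$org, ch$opt)))))
  if (!(cfg$low_cutoff > 0)) stop("low_cutoff must be > 0")
  if (any(cuts <= cfg$low_cutoff)) stop("every high cutoff must exceed low_cutoff")
  if (any(cuts >= ny))
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", max(cuts), ny))
  if (cfg$n_bins < 2L) stop("n_bins must be >= 2")
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must be in [0, 1]")
  if (!cfg$variant %in% c("original", "modified")) stop("unknown variant")
  if (!cfg$cutoffs %in% c("original", "optimized")) stop("unknown cutoff set")
  invisible(cfg)
}

standsit_cutoff <- function(cfg) {
  if (cfg$variant == "modified") cfg$standsit_cutoff_modified
  else cfg$standsit_cutoff_original
}

#' Segmentation cutoff for a transition channel
#'
#' Looks up the high cutoff (Hz) of a channel of a transition under the
#' configured cutoff set.
#'
#' @param cfg A `tug_config`.
#' @param transition Transition label (one of [TUG_TRANSITIONS]).
#' @param i Channel index within the transition's channel list.
#' @return Cutoff in Hz.
#' @export
transition_cutoff <- function(cfg, transition, i = 1L) {
  ch <- cfg$transition_channels[[transition]][[i]]
  if (cfg$cutoffs == "optimized") ch$opt else ch$org
}

#' Load a detector configuration from a YAML document
#'
#' Reads a YAML key/value document whose keys are the arguments of
#' [tug_config()]; omitted keys keep the published defaults, so an empty
#' document yields the original-variant defaults with the original cutoff
#' set. Unknown keys are an error.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @param ... Overrides applied after the file (same names).
#' @return A `tug_config`.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- utils::modifyList(vals, list(...))
  known <- names(formals(tug_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(tug_config, vals)
}

#' Write a detector configuration as YAML
#'
#' Serialises the scalar parameters of a `tug_config` (not the fixed
#' per-transition cutoff table, which is part of the method) so that
#' `load_config(write_config(cfg))` reproduces the configuration.
#'
#' @param cfg A `tug_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  keep <- setdiff(names(cfg), "transition_channels")
  yaml::write_yaml(cfg[keep], path)
  invisible(path)
}

#' @export
print.tug_config <- function(x, ...) {
  cat("TUG detector configuration\n")
  cat(sprintf("  variant: %s   segmentation cutoffs: %s\n", x$variant, x$cutoffs))
  cat(sprintf("  sample rate: %g Hz   band-pass low cutoff: %g Hz\n",
              x$sample_rate, x$low_cutoff))
  cat(sprintf("  stand/sit detection cutoff: %g Hz   turn cutoff: %g Hz\n",
              standsit_cutoff(x), x$turn_cutoff))
  cat(sprintf("  adaptive threshold: %d bins, alpha = %g (%s)\n",
              x$n_bins, x$alpha, x$threshold_strategy))
  cat(sprintf("  hip gate: upright <= %g deg, seated >= %g deg, window %g s\n",
              x$upright_deg, x$seated_deg, x$gate_window))
  invisible(x)
}
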