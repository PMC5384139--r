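#' Locate a transition candidate next to an activity peak
#'
#' Band-passes the raw series (low cutoff from the configuration, high
#' cutoff `f_cutoff` from the per-transition table) and walks away from the
#' activity peak on the requested side until the first persistent local
#' extremum: a local minimum if the filtered value at the peak is positive,
#' a local maximum otherwise. Persistence means the sample is the extreme
#' value of its `persistence`-sample neighbourhood on both sides, which
#' skips one-sample numerical ripples. If no extremum exists inside the
#' search window, the window edge is returned and flagged as a fallback.
#'
#' @param x Raw numeric series (it is detrended and filtered internally).
#' @param fs Sample rate, Hz.
#' @param peak_time Activity peak time, s (must lie inside the series).
#' @param side `"left"` or `"right"` of the peak.
#' @param f_cutoff Band-pass high cutoff, Hz.
#' @param cfg A [tug_config()] (search window, persistence, low cutoff).
#' @return List with `time` (s) and `fallback` (logical).
#' @export
locate_transition <- function(x, fs, peak_time, side = c("left", "right"),
                              f_cutoff, cfg = tug_config()) {
  side <- match.arg(side)
  n <- length(x)
  ip <- round(peak_time * fs) + 1L
  if (ip < 1L || ip > n) stop("peak_time outside the series")
  y <- bandpass_filter(detrend_series(x), fs, cfg$low_cutoff, f_cutoff)
  # detection and segmentation filter at different cutoffs, so the detected
  # peak sample need not sit on the dominant lobe of this series; re-anchor
  # to the largest absolute filtered value within 0.5 s before scanning
  ra <- as.integer(round(0.5 * fs))
  near <- max(1L, ip - ra):min(n, ip + ra)
  ip <- near[which.max(abs(y[near]))]
  want_min <- y[ip] > 0
  p <- cfg$persistence
  step <- if (side == "left") -1L else 1L
  limit <- ip + step * as.integer(round(cfg$search_window * fs))
  limit <- min(max(limit, 1L), n)
  j <- ip + step
  while (j != limit && j > 1L && j < n) {
    lo <- max(1L, j - p); hi <- min(n, j + p)
    nb <- y[lo:hi]
    if (want_min) {
      if (y[j] <= min(nb) && y[j] <= y[j - 1] && y[j] <= y[j + 1])
        return(list(time = (j - 1) / fs, fallback = FALSE))
    } else {
      if (y[j] >= max(nb) && y[j] >= y[j - 1] && y[j] >= y[j + 1])
        return(list(time = (j - 1) / fs, fallback = FALSE))
    }
    j <- j + step
  }
  list(time = (limit - 1) / fs, fallback = TRUE)
}

#' Fuse per-sensor candidate times
#'
#' The transition estimate is the arithmetic mean of the candidate times
#' marked on the individual sensor channels.
#'
#' @param times Non-empty numeric vector of candidate times, s.
#' @return Mean time, s.
#' @export
fuse_candidates <- function(times) {
  if (length(times) == 0) stop("fuse_candidates(): no candidate times")
  mean(times)
}

# which activity peak anchors each transition, and on which side the
# extremum is sought
transition_anchor <- function(label) {
  switch(label,
    SIT_TO_STAND      = list(event = "STAND_UP", which = 1L, side = "left"),
    STAND_TO_WALK_OUT = list(event = "STAND_UP", which = 1L, side = "right"),
    WALK_OUT_TO_TURN  = list(event = "TURN", which = 1L, side = "left"),
    TURN_TO_WALK_IN   = list(event = "TURN", which = 1L, side = "right"),
    WALK_IN_TO_TURN   = list(event = "TURN", which = 2L, side = "left"),
    TURN_TO_STAND     = list(event = "TURN", which = 2L, side = "right"),
    STAND_TO_SIT      = list(event = "SIT_DOWN", which = 1L, side = "left"),
    stop("unknown transition ", label))
}

transition_series <- function(rec, cfg, site, channel) {
  if (site == "hip" && channel == "theta") {
    # the hip angle is a step between postural plateaus; its band-passed
    # form is biphasic and has no pulse-like peak to anchor on. The hip
    # angular rate turns the step into a single pulse whose flanks mark the
    # transition onset/offset, so the extremum search runs on the rate.
    series_derivative(hip_angle_series(rec, cfg$sacrum_site, cfg$thigh_site),
                      rec$sample_rate)
  } else rec_channel(rec, site, channel)
}

#' Segment a detected TUG into its seven transitions
#'
#' Validates that the detected activities form the canonical TUG sequence
#' (STAND_UP, WALK, TURN, WALK, TURN, SIT_DOWN), then, for each of the
#' seven transitions, runs [locate_transition()] on every sensor channel
#' listed for that transition (with the original or re-optimized cutoff set
#' selected by `cfg$cutoffs`) and fuses the candidate times by their mean.
#' Fallback-flagged candidates are retained in the mean and surfaced in the
#' output.
#'
#' @param rec A `tug_recording`.
#' @param events Activity events from [detect_activities()].
#' @param cfg A [tug_config()].
#' @return Object of class `tug_segmentation`: list with `transitions`
#'   (data frame `label`, `time`, `fallback`), `candidates` (named list of
#'   per-channel data frames), `activities`, `trial_id`, `cutoffs`.
#' @export
segment_tug <- function(rec, events, cfg = tug_config()) {
  df <- events_df(events)
  canonical <- c("STAND_UP", "WALK", "TURN", "WALK", "TURN", "SIT_DOWN")
  if (!identical(df$label, canonical))
    stop("non-canonical activity sequence: [",
         paste(df$label, collapse = ", "),
         "] (expected [", paste(canonical, collapse = ", "), "])")
  fs <- rec$sample_rate
  peaks <- split(df$peak_time, df$label)
  res <- data.frame(label = TUG_TRANSITIONS, time = NA_real_, fallback = FALSE)
  cands <- list()
  for (k in seq_along(TUG_TRANSITIONS)) {
    lab <- TUG_TRANSITIONS[k]
    an <- transition_anchor(lab)
    peak_time <- sort(peaks[[an$event]])[an$which]
    chans <- cfg$transition_channels[[lab]]
    cdf <- data.frame(site = character(0), channel = character(0),
                      cutoff = numeric(0), time = numeric(0),
                      fallback = logical(0))
    for (i in seq_along(chans)) {
      ch <- chans[[i]]
      fc <- transition_cutoff(cfg, lab, i)
      x <- transition_series(rec, cfg, ch$site, ch$channel)
      if (ch$channel == "wy") x <- abs(x)  # turns are direction-agnostic
      loc <- locate_transition(x, fs, peak_time, an$side, fc, cfg)
      cdf[nrow(cdf) + 1L, ] <- list(ch$site, ch$channel, fc, loc$time, loc$fallback)
    }
    res$time[k] <- fuse_candidates(cdf$time)
    res$fallback[k] <- any(cdf$fallback)
    cands[[lab]] <- cdf
  }
  # adjacent transitions localized independently can invert across a very
  # short stance (e.g. turn-to-stand vs stand-to-sit); enforce the canonical
  # strict ordering by pushing a violating mark one sample past its
  # predecessor
  for (k in 2:nrow(res)) {
    if (res$time[k] <= res$time[k - 1]) res$time[k] <- res$time[k - 1] + 1 / fs
  }
  structure(list(transitions = res, candidates = cands,
                 activities = df, trial_id = rec$trial_id,
                 cutoffs = cfg$cutoffs, sample_rate = fs),
            class = "tug_segmentation")
}

#' @export
print.tug_segmentation <- function(x, ...) {
  cat(sprintf("TUG segmentation of '%s' (%s cutoffs)\n", x$trial_id, x$cutoffs))
  tr <- x$transitions
  for (k in seq_len(nrow(tr)))
    cat(sprintf("  %-18s %8.3f s%s\n", tr$label[k], tr$time[k],
                if (tr$fallback[k]) "  [fallback]" else ""))
  invisible(x)
}

#' @export
summary.tug_segmentation <- function(object, ...) {
  tr <- object$transitions
  cat(sprintf("TUG segmentation of '%s': %d transitions over %.2f s (%s cutoffs)\n",
              object$trial_id, nrow(tr), diff(range(tr$time)), object$cutoffs))
  cat(sprintf("  activities: %s\n", paste(object$activities$label, collapse = " -> ")))
  cat(sprintf("  candidates per transition: %s\n",
              paste(vapply(object$candidates, nrow, 0L), collapse = ", ")))
  invisible(object$transitions)
}

#' Plot a segmented TUG
#'
#' Draws the conditioned trunk a_z and trunk omega_y signals with the seven
#' fused transition times as vertical lines and activity peaks as points.
#'
#' @param x A `tug_segmentation`.
#' @param rec The `tug_recording` it came from.
#' @param cfg A [tug_config()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tug_segmentation <- function(x, rec, cfg = tug_config(), ...) {
  fs <- rec$sample_rate
  t <- (seq_len(rec$n_samples) - 1) / fs
  az <- conditioned(rec_channel(rec, cfg$trunk_site, "az"), fs,
                    cfg$low_cutoff, standsit_cutoff(cfg))
  wy <- conditioned(rec_channel(rec, cfg$trunk_site, "wy"), fs,
                    cfg$low_cutoff, cfg$turn_cutoff)
  graphics::plot(t, az, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "normalized signal",
                 ylim = c(-1.1, 1.1), ...)
  graphics::lines(t, wy, col = "darkorange")
  graphics::abline(v = x$transitions$time, lty = 2, col = "grey40")
  graphics::points(x$activities$peak_time, rep(1.05, nrow(x$activities)),
                   pch = 25, bg = "black")
  graphics::legend("bottomleft", legend = c("trunk a_z", "trunk w_y"),
                   col = c("steelblue", "darkorange"), lty = 1, bty = "n")
  invisible(x)
}

#' Write / read a segmentation as delimited text
#'
#' One row per transition: label, fused time (6 decimals, well below the
#' 1/60 s sampling resolution), fallback flag, and the per-sensor candidate
#' list serialized as `site_channel@cutoff:time` separated by `|`.
#'
#' @param seg A `tug_segmentation`.
#' @param path File path.
#' @return `write_segmentation()`: `path` invisibly; `read_segmentation()`:
#'   a `tug_segmentation` (without the activities table if absent).
#' @export
write_segmentation <- function(seg, path) {
  tr <- seg$transitions
  cand_str <- vapply(tr$label, function(lab) {
    cdf <- seg$candidates[[lab]]
    paste(sprintf("%s_%s@%g:%.6f%s", cdf$site, cdf$channel, cdf$cutoff,
                  cdf$time, ifelse(cdf$fallback, "!", "")),
          collapse = "|")
  }, "")
  df <- data.frame(label = tr$label, time_s = sprintf("%.6f", tr$time),
                   fallback = tr$fallback, candidates = cand_str)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tug_segmentation trial=%s cutoffs=%s sample_rate=%g",
                     seg$trial_id, seg$cutoffs, seg$sample_rate), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("segmentation file not found: ", path)
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("\\S+=\\S+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(path, skip = 1, colClasses = "character")
  cands <- list()
  for (k in seq_len(nrow(df))) {
    parts <- strsplit(df$candidates[k], "|", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^(.+)_([a-z]+)@([0-9.]+):([0-9.]+)(!?)$", parts))
    cands[[df$label[k]]] <- data.frame(
      site = vapply(m, `[`, "", 2), channel = vapply(m, `[`, "", 3),
      cutoff = as.numeric(vapply(m, `[`, "", 4)),
      time = as.numeric(vapply(m, `[`, "", 5)),
      fallback = vapply(m, `[`, "", 6) == "!")
  }
  structure(list(
    transitions = data.frame(label = df$label, time = as.numeric(df$time_s),
                             fallback = df$fallback == "TRUE"),
    candidates = cands, activities = NULL,
    trial_id = unname(meta["trial"]), cutoffs = unname(meta["cutoffs"]),
    sample_rate = as.numeric(meta["sample_rate"])),
    class = "tug_segmentation")
}
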