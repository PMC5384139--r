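#' Construct a multi-IMU TUG recording
#'
#' A recording is one TUG trial: per-site 3-axis acceleration (m/s^2),
#' 3-axis angular velocity (rad/s) and a unit orientation quaternion series,
#' all sampled at a common rate. Series lengths must agree across sites and
#' channels; quaternions are renormalized to unit norm on construction.
#'
#' @param sites Named list; each element a list with `acc` (n-by-3 matrix,
#'   columns ax/ay/az), `gyr` (n-by-3, wx/wy/wz) and `quat` (n-by-4,
#'   w/x/y/z). Site names must belong to [TUG_SITES].
#' @param sample_rate Sampling rate in Hz (> 0), default 60.
#' @param trial_id Identifier string.
#' @return An object of class `tug_recording`.
#' @export
tug_recording <- function(sites, sample_rate = 60, trial_id = "trial") {
  stopifnot(sample_rate > 0, length(sites) >= 1)
  bad <- setdiff(names(sites), TUG_SITES)
  if (length(bad)) stop("unknown site name(s): ", paste(bad, collapse = ", "))
  n <- nrow(sites[[1]]$acc)
  for (s in names(sites)) {
    st <- sites[[s]]
    lens <- c(nrow(st$acc), nrow(st$gyr), nrow(st$quat))
    if (any(lens != n))
      stop(sprintf("ragged series lengths at site '%s' (%s vs %d)",
                   s, paste(lens, collapse = "/"), n))
    for (m in c("acc", "gyr", "quat")) {
      if (!all(is.finite(st[[m]])))
        stop(sprintf("non-finite values in %s of site '%s'", m, s))
    }
    sites[[s]]$quat <- quat_normalize(st$quat)
    colnames(sites[[s]]$acc) <- c("ax", "ay", "az")
    colnames(sites[[s]]$gyr) <- c("wx", "wy", "wz")
    colnames(sites[[s]]$quat) <- c("qw", "qx", "qy", "qz")
  }
  structure(list(trial_id = trial_id, sample_rate = sample_rate,
                 n_samples = n, sites = sites),
            class = "tug_recording")
}

#' Extract one channel of a recording
#'
#' @param rec A `tug_recording`.
#' @param site Site name.
#' @param channel One of `ax, ay, az` (m/s^2) or `wx, wy, wz` (rad/s).
#' @return Numeric vector of length `rec$n_samples`.
#' @export
rec_channel <- function(rec, site, channel) {
  st <- rec$sites[[site]]
  if (is.null(st)) stop("recording has no site '", site, "'")
  if (channel %in% c("ax", "ay", "az")) st$acc[, channel]
  else if (channel %in% c("wx", "wy", "wz")) st$gyr[, channel]
  else stop("unknown channel '", channel, "'")
}

#' @export
print.tug_recording <- function(x, ...) {
  cat(sprintf("TUG recording '%s': %d sites, %d samples @ %g Hz (%.2f s)\n",
              x$trial_id, length(x$sites), x$n_samples, x$sample_rate,
              x$n_samples / x$sample_rate))
  cat("  sites:", paste(names(x$sites), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' The on-disk dialect is a UTF-8 comma-delimited file with one header row;
#' one column per site-channel named `<site>_<channel>` for the six inertial
#' channels and `<site>_q{w,x,y,z}` for the quaternion. Times are implicit:
#' sample i (0-based) occurs at `i / sample_rate` seconds.
#'
#' @param rec A `tug_recording`.
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `tug_recording` (quaternions renormalized, invariants
#'   enforced).
#' @export
write_recording <- function(rec, path) {
  cols <- list()
  for (s in names(rec$sites)) {
    st <- rec$sites[[s]]
    m <- cbind(st$acc, st$gyr, st$quat)
    colnames(m) <- paste0(s, "_", c(TUG_CHANNELS, "qw", "qx", "qy", "qz"))
    cols[[s]] <- m
  }
  df <- as.data.frame(do.call(cbind, unname(cols)))
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param sample_rate Sampling rate to attach (Hz), default 60.
#' @param trial_id Trial identifier; defaults to the file name.
#' @export
read_recording <- function(path, sample_rate = 60,
                           trial_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  parts <- regmatches(nm, regexpr("_(ax|ay|az|wx|wy|wz|qw|qx|qy|qz)$", nm))
  if (any(lengths(parts) == 0)) stop("unparseable column name(s): ",
                                     paste(nm[lengths(parts) == 0], collapse = ", "))
  site_of <- sub("_(ax|ay|az|wx|wy|wz|qw|qx|qy|qz)$", "", nm)
  chan_of <- sub("^.*_", "", nm)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]) || anyNA(df[[j]]) || !all(is.finite(df[[j]])))
      stop("non-finite or non-numeric values in column '", nm[j], "'")
  }
  sites <- list()
  for (s in unique(site_of)) {
    get <- function(ch) {
      col <- which(site_of == s & chan_of == ch)
      if (length(col) != 1) stop(sprintf("site '%s' lacks channel '%s'", s, ch))
      df[[col]]
    }
    sites[[s]] <- list(
      acc = cbind(ax = get("ax"), ay = get("ay"), az = get("az")),
      gyr = cbind(wx = get("wx"), wy = get("wy"), wz = get("wz")),
      quat = cbind(qw = get("qw"), qx = get("qx"), qy = get("qy"), qz = get("qz"))
    )
  }
  tug_recording(sites, sample_rate = sample_rate, trial_id = trial_id)
}

#' TUG annotations (reference events and transition times)
#'
#' Holds reference ("ground truth" or examiner-marked) activity intervals
#' and transition times for one trial: `events` is a data frame with
#' columns `label`, `start`, `end` (seconds); `transitions` has `label`,
#' `time`, `rater`.
#'
#' @param events Data frame (`label`, `start`, `end`).
#' @param transitions Data frame (`label`, `time`, `rater`).
#' @return Object of class `tug_annotation`.
#' @export
tug_annotation <- function(events = data.frame(label = character(0),
                                               start = numeric(0),
                                               end = numeric(0)),
                           transitions = data.frame(label = character(0),
                                                    time = numeric(0),
                                                    rater = character(0))) {
  stopifnot(all(c("label", "start", "end") %in% names(events)),
            all(c("label", "time", "rater") %in% names(transitions)))
  if (nrow(events) && any(events$start >= events$end))
    stop("annotation events must have start < end")
  structure(list(events = events[c("label", "start", "end")],
                 transitions = transitions[c("label", "time", "rater")]),
            class = "tug_annotation")
}

#' Write / read annotations as delimited text
#'
#' One CSV with a `type` column: event rows carry `label,start_s,end_s`,
#' transition rows carry `label,time_s,rater`. Times are serialized with 6
#' decimal places (well below the 1/60 s sampling resolution).
#'
#' @param ann A `tug_annotation`.
#' @param path File path.
#' @return `write_annotation()`: `path` invisibly; `read_annotation()`: a
#'   `tug_annotation`.
#' @export
write_annotation <- function(ann, path) {
  ev <- ann$events; tr <- ann$transitions
  df <- rbind(
    data.frame(type = rep("event", nrow(ev)), label = ev$label,
               start_s = sprintf("%.6f", ev$start),
               end_s = sprintf("%.6f", ev$end),
               time_s = "", rater = ""),
    data.frame(type = rep("transition", nrow(tr)), label = tr$label,
               start_s = "", end_s = "",
               time_s = sprintf("%.6f", tr$time), rater = tr$rater)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  ev <- df[df$type == "event", ]
  tr <- df[df$type == "transition", ]
  tug_annotation(
    events = data.frame(label = ev$label,
                        start = as.numeric(ev$start_s),
                        end = as.numeric(ev$end_s)),
    transitions = data.frame(label = tr$label,
                             time = as.numeric(tr$time_s),
                             rater = tr$rater)
  )
}

#' @export
print.tug_annotation <- function(x, ...) {
  cat(sprintf("TUG annotation: %d events, %d transition marks\n",
              nrow(x$events), nrow(x$transitions)))
  invisible(x)
}
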