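#' Match detected events against reference annotations
#'
#' Greedy one-to-one matching per activity label: a detection is a true
#' positive if an unmatched reference instance of the same label has its
#' interval containing the detection's peak, or its interval midpoint
#' within `window` seconds of the peak (nearest midpoint first). Unmatched
#' detections are false positives; unmatched reference instances are false
#' negatives. The negative class of label L is the set of reference
#' instances of *other* labels: a true negative is such an instance not
#' claimed (within the same tolerance) by any false detection of L.
#'
#' @param detected List of activity events (from the detectors).
#' @param truth A `tug_annotation` with reference event intervals.
#' @param window Matching tolerance, s (> 0), default 1.
#' @return Object of class `tug_confusion`: data frame with one row per
#'   label and columns `TP`, `FP`, `TN`, `FN`.
#' @export
match_events <- function(detected, truth, window = 1.0) {
  stopifnot(window > 0)
  det <- events_df(detected)
  ref <- truth$events
  labels <- TUG_ACTIVITIES
  out <- data.frame(label = labels, TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  fp_times <- list()
  for (L in labels) {
    d <- det[det$label == L, , drop = FALSE]
    r <- ref[ref$label == L, , drop = FALSE]
    mid <- (r$start + r$end) / 2
    matched_r <- rep(FALSE, nrow(r))
    tp <- 0L; fps <- numeric(0)
    for (k in order(d$peak_time)) {
      pt <- d$peak_time[k]
      ok <- which(!matched_r &
                    ((pt >= r$start & pt <= r$end) | abs(pt - mid) <= window))
      if (length(ok)) {
        matched_r[ok[which.min(abs(pt - mid[ok]))]] <- TRUE
        tp <- tp + 1L
      } else fps <- c(fps, pt)
    }
    out[out$label == L, c("TP", "FP", "FN")] <-
      list(tp, length(fps), sum(!matched_r))
    fp_times[[L]] <- fps
  }
  for (L in labels) {
    other <- ref[ref$label != L, , drop = FALSE]
    if (nrow(other) == 0) next
    mid <- (other$start + other$end) / 2
    claimed <- vapply(seq_len(nrow(other)), function(j) {
      any((fp_times[[L]] >= other$start[j] & fp_times[[L]] <= other$end[j]) |
            abs(fp_times[[L]] - mid[j]) <= window)
    }, TRUE)
    out[out$label == L, "TN"] <- sum(!claimed)
  }
  class(out) <- c("tug_confusion", class(out))
  out
}

#' Combine confusion counts across trials
#'
#' @param ... `tug_confusion` objects (or a single list of them).
#' @return A `tug_confusion` with summed counts.
#' @export
combine_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "tug_confusion")) cs <- cs[[1]]
  out <- cs[[1]]
  for (c2 in cs[-1])
    out[c("TP", "FP", "TN", "FN")] <- out[c("TP", "FP", "TN", "FN")] +
      c2[c("TP", "FP", "TN", "FN")]
  out
}

#' Sensitivity and specificity per activity
#'
#' `sensitivity = 100 * TP / (TP + FN)` (proportion of actual positives
#' detected) and `specificity = 100 * TN / (TN + FP)` (proportion of
#' negatives correctly not claimed). A rate whose denominator is zero is
#' reported as `NA` (undefined), not an error.
#'
#' @param counts A `tug_confusion` from [match_events()].
#' @return Data frame with `label`, `sensitivity`, `specificity` in
#'   percent.
#' @export
sensitivity_specificity <- function(counts) {
  sens <- ifelse(counts$TP + counts$FN > 0,
                 100 * counts$TP / (counts$TP + counts$FN), NA_real_)
  spec <- ifelse(counts$TN + counts$FP > 0,
                 100 * counts$TN / (counts$TN + counts$FP), NA_real_)
  data.frame(label = counts$label, sensitivity = sens, specificity = spec)
}

#' Transition-time differences against a reference
#'
#' Signed per-transition differences `T_sensor - T_reference` in
#' milliseconds, pooled across trials. The reference time of a transition
#' in a trial is the mean over raters of the annotated times.
#'
#' @param segs List of `tug_segmentation` objects (one per trial).
#' @param refs List of `tug_annotation` objects, parallel to `segs`.
#' @return Object of class `tug_delta_t`: data frame with one row per
#'   transition label: `mean_ms`, `sd_ms` (sample standard deviation), `n`,
#'   plus an attribute `"diffs"` holding the raw per-trial differences.
#' @export
delta_t <- function(segs, refs) {
  stopifnot(length(segs) == length(refs))
  diffs <- list()
  for (i in seq_along(segs)) {
    tr <- segs[[i]]$transitions
    ref <- refs[[i]]$transitions
    for (k in seq_len(nrow(tr))) {
      lab <- tr$label[k]
      rt <- ref$time[ref$label == lab]
      if (length(rt) == 0)
        stop("transition '", lab, "' absent from reference annotation ", i)
      diffs[[lab]] <- c(diffs[[lab]], (tr$time[k] - mean(rt)) * 1000)
    }
  }
  out <- data.frame(
    label = names(diffs),
    mean_ms = vapply(diffs, mean, 0),
    sd_ms = vapply(diffs, function(d) if (length(d) > 1) stats::sd(d) else 0, 0),
    n = vapply(diffs, length, 0L),
    row.names = NULL)
  attr(out, "diffs") <- diffs
  class(out) <- c("tug_delta_t", class(out))
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, computed
#' from the two-way ANOVA mean squares of a complete trials-by-raters
#' table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with `MSR` the between-rows (trials), `MSC` the between-columns
#' (raters) and `MSE` the residual mean square. A table with zero variance
#' everywhere (all raters identical on all trials) returns 1 by the
#' agreement limit.
#'
#' @param ratings Numeric matrix, trials in rows (n >= 2), raters in
#'   columns (k >= 2), no missing cells.
#' @return ICC(2,1) in [-1, 1].
#' @export
icc_2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("icc_2_1() requires a complete table")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("icc_2_1() needs >= 2 trials and >= 2 raters")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-15) return(1)
  (msr - mse) / denom
}

#' Evaluate detections and segmentations of a cohort
#'
#' Convenience wrapper producing the full evaluation report: pooled
#' confusion counts and sensitivity/specificity per activity, per-transition
#' time differences, and ICC(2,1) between the fused sensor times and the
#' reference times across trials.
#'
#' @param detections List of event lists (one per trial).
#' @param truths List of `tug_annotation` objects.
#' @param segs Optional list of `tug_segmentation` objects for the same
#'   trials.
#' @param window Matching tolerance for [match_events()], s.
#' @return Object of class `tug_eval`: list with `counts`, `rates`,
#'   `delta_t` (or NULL), `icc` (or NA).
#' @export
evaluate_cohort <- function(detections, truths, segs = NULL, window = 1.0) {
  stopifnot(length(detections) == length(truths))
  counts <- combine_confusion(lapply(seq_along(detections), function(i)
    match_events(detections[[i]], truths[[i]], window)))
  dt <- NULL; icc <- NA_real_
  if (!is.null(segs)) {
    dt <- delta_t(segs, truths)
    sensor <- vapply(segs, function(s) s$transitions$time[1], 0)
    reft <- vapply(truths, function(a)
      mean(a$transitions$time[a$transitions$label == TUG_TRANSITIONS[1]]), 0)
    if (length(sensor) >= 2) icc <- icc_2_1(cbind(sensor = sensor, reference = reft))
  }
  structure(list(counts = counts, rates = sensitivity_specificity(counts),
                 delta_t = dt, icc = icc),
            class = "tug_eval")
}

#' @export
print.tug_eval <- function(x, ...) {
  cat("TUG evaluation report\n")
  r <- x$rates
  for (k in seq_len(nrow(r)))
    cat(sprintf("  %-9s sens %5.1f%%  spec %5.1f%%\n",
                r$label[k], r$sensitivity[k], r$specificity[k]))
  if (!is.null(x$delta_t)) {
    cat("  transition-time differences (sensor - reference):\n")
    d <- x$delta_t
    for (k in seq_len(nrow(d)))
      cat(sprintf("    %-18s %7.0f +/- %5.0f ms  (n = %d)\n",
                  d$label[k], d$mean_ms[k], d$sd_ms[k], d$n[k]))
  }
  if (!is.na(x$icc)) cat(sprintf("  ICC(2,1) sensor vs reference: %.3f\n", x$icc))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Two CSV tables in one file: per-activity sensitivity/specificity
#' (percent, one decimal) and per-transition mean/sd time differences (ms).
#'
#' @param ev A `tug_eval`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(ev, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# activity rates", con)
  r <- ev$rates
  r$sensitivity <- round(r$sensitivity, 1)
  r$specificity <- round(r$specificity, 1)
  utils::write.csv(cbind(r, ev$counts[c("TP", "FP", "TN", "FN")]), con,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(ev$delta_t)) {
    writeLines("# transition time differences (ms)", con)
    utils::write.csv(as.data.frame(ev$delta_t), con,
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.na(ev$icc)) writeLines(sprintf("# icc_2_1,%.6f", ev$icc), con)
  invisible(path)
}
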