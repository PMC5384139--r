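# brute-force optimal one-to-one assignment: maximum number of
# detection-truth pairs of the same label within the matching rule
brute_match_count <- function(det, ref, label, window) {
  d <- det[det$label == label, , drop = FALSE]
  r <- ref[ref$label == label, , drop = FALSE]
  if (nrow(d) == 0 || nrow(r) == 0) return(0L)
  ok <- outer(seq_len(nrow(d)), seq_len(nrow(r)), Vectorize(function(i, j) {
    pt <- d$peak_time[i]
    (pt >= r$start[j] && pt <= r$end[j]) ||
      abs(pt - (r$start[j] + r$end[j]) / 2) <= window
  }))
  best <- 0L
  recurse <- function(i, used) {
    if (i > nrow(d)) { best <<- max(best, sum(used)); return(invisible()) }
    recurse(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE; recurse(i + 1L, used); used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nrow(r)))
  best
}

mk_truth <- function(df) tug_annotation(events = df)
mk_det <- function(labels, times) {
  lapply(seq_along(labels), function(k)
    list(label = labels[k], peak_time = times[k], evidence = list(),
         start = NA_real_, end = NA_real_))
}

test_that("event matching produces the expected confusion counts", {
  truth <- mk_truth(data.frame(
    label = c("STAND_UP", "WALK", "TURN", "WALK", "TURN", "SIT_DOWN"),
    start = c(3, 5, 10, 12, 17, 19), end = c(5, 10, 12, 17, 19, 21)))
  perfect <- mk_det(truth$events$label,
                    (truth$events$start + truth$events$end) / 2)
  cm <- match_events(perfect, truth)
  expect_equal(sum(cm$FP), 0)
  expect_equal(sum(cm$FN), 0)
  expect_equal(cm$TP[cm$label == "WALK"], 2)
  # every other-label instance is an undisputed true negative
  expect_equal(cm$TN[cm$label == "STAND_UP"], 5)

  # one extra spurious stand-up
  extra <- c(perfect, mk_det("STAND_UP", 15))
  cm2 <- match_events(extra, truth)
  expect_equal(cm2$FP[cm2$label == "STAND_UP"], 1)
  expect_equal(cm2$TP[cm2$label == "STAND_UP"], 1)
  # the spurious detection claims the truth instance it overlaps
  expect_lt(cm2$TN[cm2$label == "STAND_UP"], 5)
})

test_that("greedy matching attains the optimal assignment on small cases", {
  set.seed(13)
  for (rep in 1:25) {
    n_r <- sample(1:3, 1); n_d <- sample(0:3, 1)
    starts <- sort(runif(n_r, 0, 20))
    truth <- mk_truth(data.frame(label = "WALK", start = starts,
                                 end = starts + runif(n_r, 1, 3)))
    det <- mk_det(rep("WALK", n_d), runif(n_d, 0, 24))
    cm <- match_events(det, truth)
    expect_equal(cm$TP[cm$label == "WALK"],
                 brute_match_count(events_to_frame(det), truth$events,
                                   "WALK", 1.0))
  }
})

test_that("sensitivity and specificity follow their defining ratios", {
  c0 <- data.frame(label = c("STAND_UP", "SIT_DOWN", "TURN", "WALK"),
                   TP = c(72L, 33L, 10L, 0L), FP = c(0L, 0L, 1L, 0L),
                   TN = c(10L, 10L, 35L, 0L), FN = c(0L, 3L, 0L, 0L))
  class(c0) <- c("tug_confusion", class(c0))
  r <- sensitivity_specificity(c0)
  expect_equal(r$sensitivity[1], 100)
  expect_equal(r$sensitivity[2], 100 * 33 / 36, tolerance = 1e-9)
  expect_equal(round(r$sensitivity[2], 2), 91.67)
  expect_equal(round(r$specificity[3], 2), 97.22)
  # zero denominators are undefined, not errors
  expect_true(is.na(r$sensitivity[4]))
  expect_true(is.na(r$specificity[4]))
})

test_that("rates respond monotonically to added errors", {
  base <- data.frame(label = "WALK", TP = 8L, FP = 1L, TN = 9L, FN = 2L)
  class(base) <- c("tug_confusion", class(base))
  worse_fn <- base; worse_fn$FN <- 4L; worse_fn$TP <- 6L
  worse_fp <- base; worse_fp$FP <- 3L; worse_fp$TN <- 7L
  expect_lt(sensitivity_specificity(worse_fn)$sensitivity,
            sensitivity_specificity(base)$sensitivity)
  expect_lt(sensitivity_specificity(worse_fp)$specificity,
            sensitivity_specificity(base)$specificity)
})

mk_seg <- function(times) {
  structure(list(transitions = data.frame(label = TUG_TRANSITIONS,
                                          time = times, fallback = FALSE),
                 candidates = list(), activities = NULL,
                 trial_id = "t", cutoffs = "original", sample_rate = 60),
            class = "tug_segmentation")
}
mk_ref <- function(times, raters = "truth") {
  tug_annotation(transitions = data.frame(
    label = rep(TUG_TRANSITIONS, times = length(raters)),
    time = rep(times, times = length(raters)),
    rater = rep(raters, each = 7)))
}

test_that("transition-time differences have the documented sign and spread", {
  t0 <- c(3.5, 5.5, 9.5, 11.5, 15.5, 17.5, 18)
  expect_equal(delta_t(list(mk_seg(t0)), list(mk_ref(t0)))$mean_ms, rep(0, 7))

  segs <- replicate(5, mk_seg(t0 + 0.3), simplify = FALSE)
  refs <- replicate(5, list(mk_ref(t0)), simplify = TRUE)
  d <- delta_t(segs, refs)
  expect_equal(d$mean_ms, rep(300, 7), tolerance = 1e-9)
  expect_equal(d$sd_ms, rep(0, 7))
  expect_equal(d$n, rep(5L, 7))

  # sensor earlier than reference is negative
  d2 <- delta_t(list(mk_seg(t0 - 0.1)), list(mk_ref(t0)))
  expect_true(all(d2$mean_ms < 0))

  # multi-rater reference: per-trial reference is the rater mean
  ref2 <- mk_ref(t0, raters = c("A", "B"))
  ref2$transitions$time <- ref2$transitions$time +
    rep(c(-0.05, 0.05), each = 7)
  expect_equal(delta_t(list(mk_seg(t0)), list(ref2))$mean_ms, rep(0, 7),
               tolerance = 1e-9)

  bad <- mk_ref(t0)
  bad$transitions <- bad$transitions[-1, ]
  expect_error(delta_t(list(mk_seg(t0)), list(bad)), "absent")
})

test_that("ICC(2,1) matches an ANOVA mean-squares oracle", {
  expect_equal(icc_2_1(cbind(1:6, 1:6)), 1)
  # a pure offset between raters is penalized under absolute agreement
  expect_lt(icc_2_1(cbind(1:6, 1:6 + 2)), 1)
  expect_gt(icc_2_1(cbind(1:6, 1:6 + 2)), 0)

  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(12, mean = 10), nrow = 6, ncol = 2)
    # oracle: two-way ANOVA mean squares via stats::aov
    df <- data.frame(y = as.vector(x),
                     row = factor(rep(1:6, 2)),
                     col = factor(rep(1:2, each = 6)))
    ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- 6; k <- 2
    icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(icc_2_1(x), icc_oracle, tolerance = 1e-9)
  }

  # invariant under common shift and positive scaling
  x <- matrix(rnorm(18), 6, 3)
  expect_equal(icc_2_1(x + 5), icc_2_1(x), tolerance = 1e-9)
  expect_equal(icc_2_1(2.5 * x), icc_2_1(x), tolerance = 1e-9)

  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc_2_1(matrix(1:2, ncol = 1)), ">= 2")
})

test_that("cohort evaluation assembles counts, timing and agreement", {
  sims <- lapply(c(401L, 402L, 403L), function(sd)
    simulate_tug(pd_profile(1, seed = sd)))
  cfg <- tug_config()
  dets <- lapply(sims, function(s) detect_activities(s$recording, cfg))
  segs <- lapply(seq_along(sims), function(i)
    segment_tug(sims[[i]]$recording, dets[[i]], cfg))
  truths <- lapply(sims, `[[`, "truth")
  ev <- evaluate_cohort(dets, truths, segs)
  expect_s3_class(ev, "tug_eval")
  expect_true(all(ev$rates$sensitivity == 100))
  expect_true(all(ev$rates$specificity == 100))
  expect_equal(nrow(ev$delta_t), 7)
  expect_true(ev$icc >= -1 && ev$icc <= 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(ev, f)
  expect_true(any(grepl("STAND_UP", readLines(f))))
})
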