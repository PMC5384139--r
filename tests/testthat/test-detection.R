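truth_mid <- function(sim, label) {
  ev <- sim$truth$events
  rowMeans(cbind(ev$start, ev$end))[ev$label == label]
}

test_that("stand-up and sit-down are found with correct labels and timing", {
  sim <- clean_sim()
  ev <- events_to_frame(detect_stand_sit(sim$recording, tug_config()))
  expect_identical(ev$label, c("STAND_UP", "SIT_DOWN"))
  expect_lt(abs(ev$peak_time[1] - truth_mid(sim, "STAND_UP")), 0.25)
  expect_lt(abs(ev$peak_time[2] - truth_mid(sim, "SIT_DOWN")), 0.25)
})

test_that("the hip-angle gate removes sway/bend false positives", {
  sim <- pd_sim()  # pre_stand_sway and pre_sit_bend enabled
  orig <- events_to_frame(detect_stand_sit(sim$recording,
                                           tug_config(variant = "original")))
  mod <- events_to_frame(detect_stand_sit(sim$recording,
                                          tug_config(variant = "modified")))
  expect_gt(nrow(orig), 2)   # confounder peaks leak through
  expect_identical(mod$label, c("STAND_UP", "SIT_DOWN"))
  cm <- match_events(detect_activities(sim$recording, tug_config()), sim$truth)
  expect_equal(sum(cm$FP), 0)
  expect_equal(sum(cm$FN), 0)
})

test_that("turns are detected, direction-agnostically", {
  sim <- clean_sim()
  tu <- events_to_frame(detect_turns(sim$recording, tug_config()))
  expect_equal(nrow(tu), 2)
  mids <- truth_mid(sim, "TURN")
  expect_lt(abs(tu$peak_time[1] - mids[1]), 0.25)
  expect_lt(abs(tu$peak_time[2] - mids[2]), 0.25)

  # mirrored trial: negate every angular-velocity channel
  rec2 <- sim$recording
  for (s in names(rec2$sites)) rec2$sites[[s]]$gyr <- -rec2$sites[[s]]$gyr
  tu2 <- events_to_frame(detect_turns(rec2, tug_config()))
  expect_equal(tu2$peak_time, tu$peak_time)
})

test_that("walking bouts are recovered by both variants as designed", {
  p <- pd_profile(1, seed = 77L)
  p$distance <- 10
  p$confounders <- character(0)
  p$shuffle_factor <- 1
  sim <- simulate_tug(p)

  wm <- events_to_frame(detect_walking(sim$recording, tug_config(variant = "modified")))
  expect_equal(nrow(wm), 2)   # out and in
  expect_true(all(wm$start < wm$end))
  truth_w <- sim$truth$events[sim$truth$events$label == "WALK", ]
  expect_true(all(wm$peak_time > truth_w$start & wm$peak_time < truth_w$end))

  wo <- events_to_frame(detect_walking(sim$recording, tug_config(variant = "original")))
  expect_gte(nrow(wo), 1)     # full-amplitude sacrum signal is detectable
})

test_that("shuffling gait defeats the sacrum detector but not the shin detector", {
  p <- pd_profile(1, seed = 78L)
  p$confounders <- character(0)
  p$shuffle_factor <- 0.3
  sim <- simulate_tug(p)
  co <- match_events(detect_activities(sim$recording,
                                       tug_config(variant = "original")),
                     sim$truth)
  cm <- match_events(detect_activities(sim$recording,
                                       tug_config(variant = "modified")),
                     sim$truth)
  expect_gte(co$FN[co$label == "WALK"], 1)   # attenuated sacrum signal missed
  expect_equal(cm$FN[cm$label == "WALK"], 0)
  expect_equal(cm$TP[cm$label == "WALK"], 2)
})

test_that("seated leg movement is rejected by the upright gate", {
  p <- pd_profile(1, seed = 79L)
  p$confounders <- "seated_leg_motion"
  sim <- simulate_tug(p)
  wm <- events_to_frame(detect_walking(sim$recording, tug_config(variant = "modified")))
  t_stand <- sim$truth$events$start[1]
  expect_true(all(wm$start > t_stand))  # nothing before standing up
  cm <- match_events(detect_activities(sim$recording, tug_config()), sim$truth)
  expect_equal(cm$FP[cm$label == "WALK"], 0)
  expect_equal(cm$FN[cm$label == "WALK"], 0)
})

test_that("the combined detector emits the canonical sequence", {
  sim <- pd_sim()
  df <- events_to_frame(detect_activities(sim$recording, tug_config()))
  expect_identical(df$label, CANONICAL)
  expect_true(!is.unsorted(df$peak_time, strictly = TRUE))

  # walking bouts are truncated at turn boundaries
  turns <- df[df$label == "TURN", ]
  walks <- df[df$label == "WALK", ]
  cfg <- tug_config()
  for (k in seq_len(nrow(turns))) {
    lo <- turns$peak_time[k] - cfg$turn_halfwidth
    hi <- turns$peak_time[k] + cfg$turn_halfwidth
    expect_true(all(walks$end <= lo + 1 / 60 | walks$start >= hi - 1 / 60))
  }
})

test_that("an all-zero recording yields no events", {
  expect_length(detect_activities(zero_recording(), tug_config()), 0)
  expect_length(detect_activities(zero_recording(),
                                  tug_config(variant = "original")), 0)
})

test_that("detections are invariant to uniform channel scaling", {
  sim <- clean_sim()
  rec2 <- sim$recording
  for (s in names(rec2$sites)) {
    rec2$sites[[s]]$acc <- 5 * rec2$sites[[s]]$acc
    rec2$sites[[s]]$gyr <- 5 * rec2$sites[[s]]$gyr
  }
  for (v in c("original", "modified")) {
    a <- events_to_frame(detect_activities(sim$recording, tug_config(variant = v)))
    b <- events_to_frame(detect_activities(rec2, tug_config(variant = v)))
    expect_equal(a$label, b$label)
    expect_equal(a$peak_time, b$peak_time, tolerance = 1e-9)
  }
})

test_that("missing required sites raise errors", {
  sim <- clean_sim()
  rec <- sim$recording
  rec$sites$trunk <- NULL
  expect_error(detect_stand_sit(rec, tug_config()), "no site 'trunk'")
  expect_error(detect_turns(rec, tug_config()), "no site 'trunk'")
  rec2 <- sim$recording
  rec2$sites$r_shin <- NULL
  expect_error(detect_walking(rec2, tug_config()), "no site 'r_shin'")
})
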