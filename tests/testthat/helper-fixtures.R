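# shared fixtures, built once per test run

CANONICAL <- c("STAND_UP", "WALK", "TURN", "WALK", "TURN", "SIT_DOWN")

# one cached PD trial (confounders on) reused across test files
pd_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_tug(pd_profile(1, seed = 101L))
    cache
  }
})

# confounder-free trial
clean_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- pd_profile(1, seed = 202L)
      p$confounders <- character(0)
      cache <<- simulate_tug(p)
    }
    cache
  }
})

# minimal all-zero recording with the sites the detectors need
zero_recording <- function(n = 900, fs = 60) {
  z3 <- matrix(0, n, 3)
  qid <- cbind(rep(1, n), 0, 0, 0)
  site <- list(acc = z3, gyr = z3, quat = qid)
  tug_recording(list(trunk = site, sacrum = site,
                     r_thigh = site, r_shin = site),
                sample_rate = fs, trial_id = "zeros")
}

# rotation matrix from a unit quaternion (independent route for oracles)
rot_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# independent oracle: enumerate every persistent local extremum of the
# filtered series, then take the first one on the requested side
brute_extremum <- function(x, fs, peak_time, side, f_cutoff, cfg) {
  y <- bandpass_filter(detrend_series(x), fs, cfg$low_cutoff, f_cutoff)
  n <- length(y); p <- cfg$persistence
  ip <- round(peak_time * fs) + 1L
  near <- max(1, ip - round(0.5 * fs)):min(n, ip + round(0.5 * fs))
  ip <- near[which.max(abs(y[near]))]  # same re-anchoring as the package
  want_min <- y[ip] > 0
  is_ext <- vapply(2:(n - 1), function(j) {
    nb <- y[max(1, j - p):min(n, j + p)]
    if (want_min) y[j] <= min(nb) && y[j] <= y[j - 1] && y[j] <= y[j + 1]
    else y[j] >= max(nb) && y[j] >= y[j - 1] && y[j] >= y[j + 1]
  }, TRUE)
  idx <- (2:(n - 1))[is_ext]
  win <- round(cfg$search_window * fs)
  idx <- if (side == "left") rev(idx[idx < ip & idx >= ip - win])
         else idx[idx > ip & idx <= ip + win]
  if (length(idx) == 0) NA_real_ else (idx[1] - 1) / fs
}
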