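test_that("detrending removes constants, ramps and fitted lines", {
  expect_equal(detrend_series(c(5, 5, 5, 5)), rep(0, 4))
  expect_equal(detrend_series(0:59), rep(0, 60), tolerance = 1e-9)

  # sine + ramp: compare against a closed-form normal-equations line fit
  t <- seq(0, 10, by = 1 / 60)
  x <- sin(2 * pi * 0.7 * t) + 0.35 * t + 2
  X <- cbind(1, seq_along(x))
  beta <- solve(t(X) %*% X, t(X) %*% x)
  expect_equal(detrend_series(x), as.numeric(x - X %*% beta), tolerance = 1e-6)
  expect_lt(abs(mean(detrend_series(x))), 1e-9 * max(abs(x)))
  expect_error(detrend_series(1), "2 samples")
})

test_that("normalization scales by the peak magnitude and flags zero input", {
  expect_equal(normalize_series(c(0, 2, -4)), c(0, 0.5, -1))
  z <- normalize_series(numeric(10))
  expect_equal(as.numeric(z), rep(0, 10))
  expect_true(isTRUE(attr(z, "degenerate")))
  set.seed(1)
  x <- rnorm(100)
  expect_equal(max(abs(normalize_series(x))), 1)
  # idempotent on an already-normalized series
  expect_equal(normalize_series(normalize_series(x)), normalize_series(x))
})

test_that("band-pass filter is zero-phase with the designed gain", {
  fs <- 60
  t <- seq(0, 40, by = 1 / fs)   # long enough that the middle is steady state
  expect_lt(max(abs(bandpass_filter(rep(3, 1200), fs, 0.1, 2))), 1e-6)
  core <- 900:1500               # 15-25 s, clear of both edge transients

  # out-of-band 10 Hz sinusoid strongly attenuated, matching |H|^2
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, fs, 0.1, 2)
  amp <- max(abs(y10[core]))
  expect_lt(amp, 0.10)
  expect_equal(amp, bandpass_gain(fs, 0.1, 2, 10), tolerance = 0.02)

  # at f_high the measured amplitude ratio matches the transfer function
  xh <- sin(2 * pi * 2 * t)
  yh <- bandpass_filter(xh, fs, 0.1, 2)
  expect_equal(max(abs(yh[core])), bandpass_gain(fs, 0.1, 2, 2),
               tolerance = 0.02)

  # linearity
  set.seed(7)
  a <- rnorm(600); b <- rnorm(600)
  lhs <- bandpass_filter(2 * a - 3 * b, fs, 0.2, 5)
  rhs <- 2 * bandpass_filter(a, fs, 0.2, 5) - 3 * bandpass_filter(b, fs, 0.2, 5)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # no group delay: symmetric pulse peak unmoved
  pulse <- exp(-((seq_len(1200) - 600) / 30)^2)
  yp <- bandpass_filter(pulse, fs, 0.1, 5)
  expect_lte(abs(which.max(yp) - 600), 1)

  expect_error(bandpass_filter(rnorm(100), fs, 2, 1), "invalid band")
  expect_error(bandpass_filter(rnorm(100), fs, 0.1, 40), "invalid band")
})

test_that("time derivative matches analytic derivatives", {
  fs <- 60
  expect_equal(series_derivative(rep(2, 10), fs), rep(0, 10))
  ramp <- 3.5 * (0:299) / fs
  expect_equal(series_derivative(ramp, fs), rep(3.5, 300), tolerance = 1e-9)
  t <- (0:599) / fs
  x <- sin(2 * pi * 1 * t)
  d <- series_derivative(x, fs)
  expected <- 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(d - expected)[2:599]), 0.01 * 2 * pi)
  expect_error(series_derivative(c(1, 2), fs), "3 samples")
})

test_that("histogram threshold arithmetic is exact", {
  expect_identical(eq1_threshold(0.975, 0.025, 0.05, 0.01),
                   0.975 - (0.025 - 0.05 * 0.01))
  expect_equal(eq1_threshold(0.975, 0.025, 0.05, 0.01), 0.9505)
  expect_equal(eq1_threshold(0.8, 0.2, 0.05, 0), 0.6)
  expect_equal(eq1_threshold(0.5, 0.5, 0.04, 0.25), 0.04 * 0.25)
})

test_that("adaptive threshold matches an independent histogram oracle", {
  set.seed(42)
  x <- runif(5000)
  thr <- adaptive_threshold(x, 20, 0.01)
  # oracle: graphics::hist on |x| with identical equal-width breaks
  h <- hist(abs(x), breaks = seq(min(abs(x)), max(abs(x)), length.out = 21),
            plot = FALSE)
  occ <- which(h$counts > 0)
  w <- diff(h$breaks)[1]
  expect_equal(thr, eq1_threshold(h$mids[max(occ)], h$mids[min(occ)], w, 0.01),
               tolerance = 1e-12)
  expect_gte(thr, min(abs(x)))
  expect_lte(thr, max(abs(x)) + w)

  # scale equivariance
  expect_equal(adaptive_threshold(3.7 * x, 20, 0.01), 3.7 * thr,
               tolerance = 1e-9)
  expect_error(adaptive_threshold(rep(1, 100)), "degenerate")

  # edges strategy spans the full occupied range
  thr_e <- adaptive_threshold(x, 20, 0.01, strategy = "edges")
  expect_gt(thr_e, thr)
})

test_that("peak finding honours height, separation and tie rules", {
  fs <- 60
  t <- (0:899) / fs
  g <- function(c0, a = 1, s = 0.2) a * exp(-((t - c0) / s)^2)
  pk <- find_peaks(g(5), fs, height = 0.5, min_separation = 1)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$time - 5), 1 / fs)

  # two pulses 0.5 s apart, 1 s separation: only the taller survives
  two <- g(5, 0.8) + g(5.5, 1.0)
  pk2 <- find_peaks(two, fs, height = 0.3, min_separation = 1)
  expect_equal(nrow(pk2), 1)
  expect_lt(abs(pk2$time - 5.5), 0.15)

  expect_equal(nrow(find_peaks(g(5), fs, height = 2)), 0)

  # property: sorted times with pairwise gaps >= min_separation
  set.seed(11)
  for (k in 1:20) {
    x <- as.numeric(stats::filter(rnorm(600), rep(1 / 8, 8), sides = 2))
    x[is.na(x)] <- 0
    p <- find_peaks(x, fs, height = 0.1, min_separation = 0.5)
    expect_true(!is.unsorted(p$time, strictly = TRUE))
    if (nrow(p) > 1) expect_true(all(diff(p$time) >= 0.5 - 1e-12))
  }
})

test_that("moving RMS recovers the amplitude of a steady oscillation", {
  fs <- 60
  t <- (0:1199) / fs
  x <- 2 * sin(2 * pi * 1.5 * t)
  env <- moving_rms(x, fs, 0.75)
  core <- 200:1000
  expect_equal(mean(env[core]), 2 / sqrt(2), tolerance = 0.02)
})
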