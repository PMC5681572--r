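# Detection: filter behaviour, adaptive thresholds, and crossing detection
# against a naive scan oracle.

test_that("bandpass attenuates the stop band and preserves the pass band", {
  fs <- 6250
  t <- seq(0, 1, by = 1 / fs)
  slow <- sin(2 * pi * 10 * t)
  y <- bandpass(slow, 500, 3000, sampling_rate = fs)
  expect_lt(max(abs(y[2000:4000])), 0.01)
  mid <- sin(2 * pi * 1000 * t)
  y2 <- bandpass(mid, 500, 3000, sampling_rate = fs)
  expect_gt(max(abs(y2[2000:4000])), 0.95)
  set.seed(1)
  wn <- rnorm(fs)
  expect_lt(var(bandpass(wn, 500, 3000, sampling_rate = fs)), var(wn))
  expect_error(bandpass(wn, 500, 4000, sampling_rate = fs), "Nyquist")
})

test_that("threshold estimators behave on Gaussian noise and scale linearly", {
  set.seed(2)
  x <- rnorm(2e5)
  thr_sd <- estimate_threshold(x, 5, "plain_sd")
  expect_lt(abs(thr_sd - (-5)) / 5, 0.02)
  thr_rob <- estimate_threshold(x, 5, "robust_median")
  expect_lt(abs(thr_rob - thr_sd) / abs(thr_sd), 0.05)
  expect_equal(estimate_threshold(2 * x, 5, "plain_sd"), 2 * thr_sd)
  expect_equal(estimate_threshold(2 * x, 5, "robust_median"), 2 * thr_rob)
  expect_error(estimate_threshold(rep(1, 100), 5), "degenerate")
  expect_error(estimate_threshold(numeric(0)), "empty")
})

make_transient_recording <- function(n_events = 50, amp = 10, seed = 7,
                                     fs = 6250, dur_s = 4,
                                     onsets_ms = numeric()) {
  set.seed(seed)
  n <- fs * dur_s
  x <- matrix(rnorm(n * 12), n, 12)
  # grid sampling keeps transients >= 100 samples (16 ms) apart
  truth <- sort(sample(seq(1000, n - 1000, by = 100), n_events))
  kern <- amp * (-exp(-((-4:7) / 1.1)^2) + 0.45 * exp(-(((-4:7) - 3) / 1.8)^2))
  for (i in truth) x[i + (-4:7), 1] <- x[i + (-4:7), 1] + kern
  list(rec = laminar_recording(x, fs, stimulus_onsets_ms = onsets_ms),
       truth_samples = truth)
}

test_that("injected transients are recovered at the right samples", {
  fx <- make_transient_recording()
  ev <- detect_spikes(fx$rec, detection_params())
  ev1 <- ev[ev$hemisphere == "contra" & ev$layer == 1, ]
  expect_equal(nrow(ev1), 50)
  det_samples <- round(ev1$time_ms / 1000 * fx$rec$sampling_rate) + 1
  expect_true(all(abs(det_samples - fx$truth_samples) <= 1))
})

test_that("detection matches the naive sample-by-sample scan exactly", {
  fx <- make_transient_recording(n_events = 20, dur_s = 1, seed = 3)
  p <- detection_params()
  filt <- bandpass(fx$rec$samples[, 1], p$band_low, p$band_high,
                   fx$rec$sampling_rate, p$filter_order)
  thr <- estimate_threshold(filt, p$threshold_multiplier, p$noise_estimator)
  oracle <- naive_threshold_scan(filt, thr,
                                 p$dead_time_ms / 1000 * fx$rec$sampling_rate)
  ev <- detect_spikes(fx$rec, p)
  ev1 <- ev[ev$hemisphere == "contra" & ev$layer == 1, ]
  expect_equal(round(ev1$time_ms / 1000 * fx$rec$sampling_rate) + 1, oracle)
})

test_that("events in the post-stimulus artifact window are removed", {
  fs <- 6250
  set.seed(9)
  n <- fs  # 1 s
  x <- matrix(rnorm(n * 12), n, 12)
  kern <- 10 * (-exp(-((-4:7) / 1.1)^2))
  onset_ms <- 500
  # one transient 3 ms after the stimulus (inside 0-5 ms window), one at 20 ms
  for (dt in c(3, 20)) {
    i <- round((onset_ms + dt) / 1000 * fs) + 1
    x[i + (-4:7), 5] <- x[i + (-4:7), 5] + kern
  }
  rec <- laminar_recording(x, fs, stimulus_onsets_ms = onset_ms)
  ev <- detect_spikes(rec, detection_params())
  ev5 <- ev[ev$layer == 5 & ev$hemisphere == "contra", ]
  rel <- ev5$time_ms - onset_ms
  expect_false(any(rel >= 0 & rel <= 5))
  expect_true(any(abs(rel - 20) < 1))
})

test_that("event count is non-increasing in the threshold multiplier", {
  fx <- make_transient_recording(n_events = 30, amp = 6, dur_s = 2, seed = 11)
  counts <- vapply(c(3, 4, 5, 7, 9), function(m) {
    nrow(detect_spikes(fx$rec, detection_params(threshold_multiplier = m)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant to global signal scaling", {
  fx <- make_transient_recording(n_events = 15, dur_s = 1, seed = 13)
  ev1 <- detect_spikes(fx$rec, detection_params())
  rec2 <- fx$rec
  rec2$samples <- rec2$samples * 7.3
  ev2 <- detect_spikes(rec2, detection_params())
  expect_equal(ev1$time_ms, ev2$time_ms)
  expect_equal(ev1$layer, ev2$layer)
})

test_that("flat channels yield no events, empty recordings warn", {
  rec <- laminar_recording(matrix(0, 1000, 12), 6250)
  w <- capture_warnings(ev <- detect_spikes(rec, detection_params(),
                                            apply_bandpass = FALSE))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(nrow(ev), 0)
  rec0 <- laminar_recording(matrix(numeric(0), 0, 12), 6250)
  expect_warning(ev0 <- detect_spikes(rec0), "empty")
  expect_equal(nrow(ev0), 0)
})
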